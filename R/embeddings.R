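# Pluggable sequence/substrate embedding contract.
#
# Real pretrained language-model backends (protein language model for
# sequences, SMILES Transformer for substrates) are optional plugins
# loaded by name; the bundled mock backend derives per-token vectors from
# a seeded hash of (token, position), so embeddings are deterministic,
# distinct across inputs, and need no download. Both backends satisfy the
# same contract: a finite 1024-dimensional vector per input.

SEQ_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M",
                  "N", "P", "Q", "R", "S", "T", "V", "W", "Y", "X")

#' Create an embedding backend handle
#'
#' @param backend Backend name; only `"mock"` is bundled. Other names
#'   (e.g. pretrained model adapters) raise unless the corresponding
#'   optional plugin is installed.
#' @param seed Integer seed mixed into the mock backend's hashes.
#' @return An `embedder` handle.
#' @export
mock_embedder <- function(backend = "mock", seed = 1) {
  if (backend != "mock") {
    stop("embedding backend '", backend, "' is not installed; ",
         "the bundled backend is 'mock'", call. = FALSE)
  }
  out <- list(backend = backend, seed = as.integer(seed))
  class(out) <- "embedder"
  out
}

# deterministic per-token vector: hash (token, position, stream) to a seed
token_vector <- function(token, position, dim, embedder, stream) {
  h <- hash31(paste(stream, token, position, sep = "\r"))
  local_rnorm((h + embedder$seed * 7919) %% 2147483647, dim)
}

#' Embed a protein sequence
#'
#' Produces one 1024-dimensional vector per residue (from the backend)
#' and mean-pools over the sequence, mirroring the average-pooled
#' final-hidden-layer representation of pretrained protein language
#' models.
#'
#' @param sequence Amino-acid string over the 20-letter alphabet plus X.
#' @param embedder An [mock_embedder()] handle.
#' @return Numeric vector of length 1024.
#' @export
embed_sequence <- function(sequence, embedder = mock_embedder()) {
  if (!nzchar(sequence)) stop("empty sequence", call. = FALSE)
  chars <- strsplit(sequence, "")[[1]]
  bad <- !chars %in% SEQ_ALPHABET
  if (any(bad)) {
    stop("illegal residue character(s): ",
         paste(unique(chars[bad]), collapse = ", "), call. = FALSE)
  }
  per_res <- vapply(seq_along(chars), function(p) {
    token_vector(chars[p], p, 1024L, embedder, "seq")
  }, numeric(1024))
  rowMeans(per_res)
}

# SMILES tokenizer: bracket atoms, two-letter organics, ring-bond digits,
# bonds and branches
tokenize_smiles <- function(smiles) {
  if (!nzchar(smiles)) stop("empty SMILES", call. = FALSE)
  if (grepl(".", smiles, fixed = TRUE)) {
    stop("multi-fragment SMILES (contains '.') is excluded by the ",
         "curation filter", call. = FALSE)
  }
  pattern <- "\\[[^\\]]+\\]|Cl|Br|[BCNOPSFIbcnops]|[0-9]|%[0-9]{2}|[=#$/\\\\()+@:-]"
  m <- gregexpr(pattern, smiles)[[1]]
  tokens <- regmatches(smiles, gregexpr(pattern, smiles))[[1]]
  covered <- sum(attr(m, "match.length"))
  if (length(tokens) == 0 || covered != nchar(smiles)) {
    stop("unparsable SMILES: '", smiles, "'", call. = FALSE)
  }
  # basic syntax: balanced parentheses and brackets
  opens <- sum(tokens == "(")
  if (opens != sum(tokens == ")") ||
      grepl("\\[[^]]*\\[", smiles)) {
    stop("unparsable SMILES: unbalanced delimiters in '", smiles, "'",
         call. = FALSE)
  }
  tokens
}

#' Embed a substrate SMILES string
#'
#' Tokenizes the SMILES into symbols, maps each (symbol, position) to a
#' 256-dimensional vector, and concatenates mean-pool, max-pool,
#' first-symbol and last-position blocks into a 1024-dimensional
#' molecular fingerprint, emulating the 4 x 256 composition of
#' Transformer-based SMILES encoders.
#'
#' @param smiles Single-fragment SMILES string (no "." separator).
#' @param embedder An [mock_embedder()] handle.
#' @return Numeric vector of length 1024.
#' @export
embed_smiles <- function(smiles, embedder = mock_embedder()) {
  tokens <- tokenize_smiles(smiles)
  per_tok <- vapply(seq_along(tokens), function(p) {
    token_vector(tokens[p], p, 256L, embedder, "smi")
  }, numeric(256))
  c(rowMeans(per_tok),
    apply(per_tok, 1, max),
    per_tok[, 1],
    per_tok[, ncol(per_tok)])
}

gelu <- function(x) x * pnorm(x)
gelu_grad <- function(x) pnorm(x) + x * dnorm(x)

#' Initialize a residual MLP reducer
#'
#' Two-block residual multilayer perceptron mapping `in_dim` to
#' `out_dim`: out = W2 gelu(W1 x + b1) + b2 + P x, with a linear skip
#' projection P. Used to reduce pretrained embedding vectors to a
#' consistent fixed dimensionality.
#'
#' @param in_dim,out_dim Input and output widths (`in_dim >= out_dim`
#'   for reduction; equal widths give an identity-capable configuration).
#' @param hidden Hidden width (default `out_dim`).
#' @param seed Integer seed for the Glorot draw.
#' @return A `reducer` parameter list.
#' @export
init_reducer <- function(in_dim, out_dim, hidden = out_dim, seed = 1) {
  if (in_dim < out_dim) {
    stop("reducer requires in_dim >= out_dim", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  out <- list(W1 = glorot(in_dim, hidden), b1 = rep(0, hidden),
              W2 = glorot(hidden, out_dim), b2 = rep(0, out_dim),
              P = glorot(in_dim, out_dim),
              in_dim = in_dim, out_dim = out_dim, hidden = hidden)
  class(out) <- "reducer"
  out
}

#' Apply a reducer to embedding vectors
#'
#' @param x Numeric vector of length `in_dim` or a matrix with `in_dim`
#'   columns (one row per embedding).
#' @param reducer An [init_reducer()] parameter list.
#' @return Reduced vector/matrix with `out_dim` columns.
#' @export
reduce_dim <- function(x, reducer) {
  single <- is.null(dim(x))
  if (single) x <- matrix(x, 1)
  if (ncol(x) != reducer$in_dim) {
    stop("input width ", ncol(x), " does not match reducer in_dim ",
         reducer$in_dim, call. = FALSE)
  }
  hpre <- sweep(x %*% reducer$W1, 2, reducer$b1, "+")
  out <- sweep(gelu(hpre) %*% reducer$W2, 2, reducer$b2, "+") +
    x %*% reducer$P
  if (single) drop(out) else out
}

# MSE loss of reducer + linear head w,b and its analytic gradients
reducer_loss_grad <- function(reducer, head, X, y) {
  n <- nrow(X)
  hpre <- sweep(X %*% reducer$W1, 2, reducer$b1, "+")
  hact <- gelu(hpre)
  z <- sweep(hact %*% reducer$W2, 2, reducer$b2, "+") + X %*% reducer$P
  yhat <- drop(z %*% head$w) + head$b
  resid <- yhat - y
  loss <- mean(resid^2)
  dyhat <- 2 * resid / n                       # n
  dz <- outer(dyhat, drop(head$w))             # n x out
  grads <- list(
    W1 = t(X) %*% ((dz %*% t(reducer$W2)) * gelu_grad(hpre)),
    b1 = colSums((dz %*% t(reducer$W2)) * gelu_grad(hpre)),
    W2 = t(hact) %*% dz,
    b2 = colSums(dz),
    P = t(X) %*% dz,
    w = drop(t(z) %*% dyhat),
    b = sum(dyhat)
  )
  list(loss = loss, grads = grads, yhat = yhat)
}

#' Train a reducer end-to-end with a provisional linear head
#'
#' Gradient-descent training of the residual MLP reducer under a
#' supervised mean-squared-error loss, using a provisional linear
#' regression head on the reduced features. After training, the reduced
#' features are frozen and handed to the tree-ensemble head (see
#' [fit_kinetics()]).
#'
#' @param X Matrix of input embeddings (n x in_dim).
#' @param y Numeric targets (length n).
#' @param out_dim Reduced dimensionality.
#' @param epochs Full-batch gradient steps.
#' @param lr Learning rate.
#' @param seed Seed for weight initialization.
#' @return A trained `reducer` (with the head and loss trace attached as
#'   attributes).
#' @export
train_reducer <- function(X, y, out_dim, epochs = 200, lr = 1e-2, seed = 1) {
  reducer <- init_reducer(ncol(X), out_dim, seed = seed)
  head <- list(w = rep(0, out_dim), b = mean(y))
  trace <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    lg <- reducer_loss_grad(reducer, head, X, y)
    trace[ep] <- lg$loss
    for (nm in c("W1", "b1", "W2", "b2", "P")) {
      reducer[[nm]] <- reducer[[nm]] - lr * lg$grads[[nm]]
    }
    head$w <- head$w - lr * lg$grads$w
    head$b <- head$b - lr * lg$grads$b
  }
  attr(reducer, "head") <- head
  attr(reducer, "loss_trace") <- trace
  reducer
}
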