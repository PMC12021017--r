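# Edge-augmented multi-head graph-Transformer encoder.
#
# Attention over the neighbors j of node i uses logits
#   <W_Q h_i, W_K h_j + W_E e_ij> / sqrt(d),
# softmax-normalized over N(i); per-head messages are
#   alpha_ij (W_V h_j + W_E' e_ij),
# concatenated across heads and projected back to the embedding width.
# Each layer is residual with post-layer-norm and a position-wise
# feed-forward block. Node embeddings are mean-pooled into a graph
# embedding; all attention tensors are recorded for profile extraction.

glorot <- function(n_in, n_out) {
  lim <- sqrt(6 / (n_in + n_out))
  matrix(runif(n_in * n_out, -lim, lim), n_in, n_out)
}

#' Initialize encoder parameters
#'
#' Glorot-uniform weights for an input projection, `n_layers`
#' edge-augmented attention layers with `n_heads` heads of width
#' `d_head`, and position-wise feed-forward blocks. All randomness is
#' consumed from a single seed so initialization is reproducible.
#'
#' @param node_dim Raw node feature dimension (from [featurize()]).
#' @param edge_dim Raw edge feature dimension.
#' @param dim Embedding width F (default 128).
#' @param n_layers,n_heads,d_head,ffn_dim Stack shape; defaults 3 layers,
#'   4 heads of width 32, feed-forward hidden 256.
#' @param seed Integer seed for the weight draw.
#' @return An `encoder_params` list.
#' @export
init_encoder_params <- function(node_dim, edge_dim, dim = 128,
                                n_layers = 3, n_heads = 4, d_head = 32,
                                ffn_dim = 256, seed = 1) {
  stopifnot(n_layers >= 1, n_heads >= 1, d_head >= 1)
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  layers <- lapply(seq_len(n_layers), function(l) {
    heads <- lapply(seq_len(n_heads), function(h) {
      list(W_Q = glorot(dim, d_head),
           W_K = glorot(dim, d_head),
           W_V = glorot(dim, d_head),
           W_E = glorot(edge_dim, d_head))
    })
    list(heads = heads,
         W_O = glorot(n_heads * d_head, dim),
         ln1_gamma = rep(1, dim), ln1_beta = rep(0, dim),
         ffn_W1 = glorot(dim, ffn_dim), ffn_b1 = rep(0, ffn_dim),
         ffn_W2 = glorot(ffn_dim, dim), ffn_b2 = rep(0, dim),
         ln2_gamma = rep(1, dim), ln2_beta = rep(0, dim))
  })
  out <- list(W_in = glorot(node_dim, dim), b_in = rep(0, dim),
              layers = layers,
              dim = dim, n_layers = n_layers, n_heads = n_heads,
              d_head = d_head, node_dim = node_dim, edge_dim = edge_dim,
              seed = seed)
  class(out) <- "encoder_params"
  out
}

# add self-loops (zero edge features) for nodes without outgoing edges so
# the per-node softmax is always defined
augment_isolated <- function(edges, edge_features, n_nodes) {
  isolated <- setdiff(seq_len(n_nodes), unique(edges$i))
  if (length(isolated) > 0) {
    edges <- dplyr::bind_rows(
      edges,
      tibble::tibble(i = isolated, j = isolated, dist = 0)
    )
    edge_features <- rbind(
      edge_features,
      matrix(0, length(isolated), ncol(edge_features))
    )
  }
  list(edges = edges, edge_features = edge_features)
}

#' Edge-augmented attention weights for one head
#'
#' Computes the per-edge logits <W_Q h_i, W_K h_j + W_E e_ij> / sqrt(d)
#' and softmax-normalizes them over the neighbors of each source node,
#' so the weights of every node's outgoing edges sum to 1.
#'
#' @param h Node embedding matrix (n x F).
#' @param e Edge feature matrix (E x F_e).
#' @param edges Tibble with columns `i`, `j` (edge k connects i\[k\] to
#'   j\[k\]).
#' @param head List with matrices `W_Q`, `W_K`, `W_E` (and `W_V`).
#' @return Numeric vector of length E of positive weights.
#' @export
attention_scores <- function(h, e, edges, head) {
  d <- ncol(head$W_Q)
  if (ncol(h) != nrow(head$W_Q) || ncol(e) != nrow(head$W_E)) {
    stop("shape mismatch between embeddings and head parameters",
         call. = FALSE)
  }
  q <- h %*% head$W_Q                       # n x d
  kmat <- h %*% head$W_K                    # n x d
  emat <- e %*% head$W_E                    # E x d
  logits <- rowSums(q[edges$i, , drop = FALSE] *
                      (kmat[edges$j, , drop = FALSE] + emat)) / sqrt(d)
  alpha <- numeric(length(logits))
  for (i in unique(edges$i)) {
    sel <- which(edges$i == i)
    z <- logits[sel] - max(logits[sel])
    alpha[sel] <- exp(z) / sum(exp(z))
  }
  alpha
}

#' Aggregate neighbor messages under attention weights
#'
#' Per head, sums alpha_ij (W_V h_j + W_E e_ij) over the neighbors of
#' each node, concatenates the head outputs and projects with W_O back
#' to the embedding width.
#'
#' @param h,e,edges As in [attention_scores()].
#' @param alpha Matrix (E x n_heads) of attention weights, rows grouped
#'   by source node summing to 1 per head.
#' @param layer Layer parameter list (fields `heads`, `W_O`).
#' @return Updated node embedding matrix (n x F).
#' @export
attention_aggregate <- function(h, e, edges, alpha, layer) {
  n <- nrow(h)
  sums <- tapply(alpha[, 1], edges$i, sum)
  if (any(abs(sums - 1) > 1e-6)) {
    stop("attention weights are not normalized per source node",
         call. = FALSE)
  }
  per_head <- lapply(seq_along(layer$heads), function(hd) {
    head <- layer$heads[[hd]]
    msg <- (h %*% head$W_V)[edges$j, , drop = FALSE] + e %*% head$W_E
    wmsg <- msg * alpha[, hd]
    out <- matrix(0, n, ncol(msg))
    agg <- rowsum(wmsg, group = edges$i)
    out[as.integer(rownames(agg)), ] <- agg
    out
  })
  do.call(cbind, per_head) %*% layer$W_O
}

layer_norm <- function(x, gamma, beta, eps = 1e-6) {
  mu <- rowMeans(x)
  sdv <- sqrt(rowMeans((x - mu)^2) + eps)
  ((x - mu) / sdv) * rep(gamma, each = nrow(x)) +
    rep(beta, each = nrow(x))
}

relu <- function(x) pmax(x, 0)

#' One encoder layer
#'
#' Multi-head edge-augmented attention with a residual connection and
#' post-layer-norm, followed by a residual position-wise feed-forward
#' block (also post-layer-norm). Deterministic given the weights.
#'
#' @param h Node embeddings (n x F).
#' @param e Edge features.
#' @param edges Edge tibble (`i`, `j`).
#' @param layer Layer parameters from [init_encoder_params()].
#' @return List with `h` (updated embeddings) and `alpha`
#'   (E x n_heads attention weights).
#' @export
transformer_layer <- function(h, e, edges, layer) {
  alpha <- vapply(layer$heads, function(head) {
    attention_scores(h, e, edges, head)
  }, numeric(nrow(edges)))
  if (!is.matrix(alpha)) alpha <- matrix(alpha, nrow = nrow(edges))
  attn <- attention_aggregate(h, e, edges, alpha, layer)
  h1 <- layer_norm(h + attn, layer$ln1_gamma, layer$ln1_beta)
  ffn <- relu(sweep(h1 %*% layer$ffn_W1, 2, layer$ffn_b1, "+")) %*%
    layer$ffn_W2
  ffn <- sweep(ffn, 2, layer$ffn_b2, "+")
  h2 <- layer_norm(h1 + ffn, layer$ln2_gamma, layer$ln2_beta)
  list(h = h2, alpha = alpha)
}

#' Encode a residue graph
#'
#' Projects the raw node features to the embedding width, applies the
#' layer stack, records every layer's attention weights, and mean-pools
#' the final node embeddings into a single graph embedding. Nodes
#' without outgoing edges receive a self-loop with zero edge features so
#' attention is defined everywhere.
#'
#' @param graph A `residue_graph` from [featurize()].
#' @param params An [init_encoder_params()] object (created from the
#'   graph's dimensions when omitted).
#' @param seed Seed used when `params` is omitted.
#' @return An `encoder_output`: list with `node_embeddings` (n x F),
#'   `graph_embedding` (length F), `attentions` (list per layer of
#'   E x n_heads matrices) and the (possibly self-loop-augmented)
#'   `edges`.
#' @export
encode_graph <- function(graph, params = NULL, seed = 1) {
  stopifnot(inherits(graph, "residue_graph"))
  n <- nrow(graph$node_features)
  if (n < 1) stop("empty graph", call. = FALSE)
  if (is.null(params)) {
    params <- init_encoder_params(node_dim = ncol(graph$node_features),
                                  edge_dim = ncol(graph$edge_features),
                                  seed = seed)
  }
  aug <- augment_isolated(graph$edges, graph$edge_features, n)
  h <- sweep(graph$node_features %*% params$W_in, 2, params$b_in, "+")
  attentions <- vector("list", params$n_layers)
  for (l in seq_len(params$n_layers)) {
    step <- transformer_layer(h, aug$edge_features, aug$edges,
                              params$layers[[l]])
    h <- step$h
    attentions[[l]] <- step$alpha
  }
  out <- list(node_embeddings = h,
              graph_embedding = colMeans(h),
              attentions = attentions,
              edges = aug$edges,
              params = params)
  class(out) <- "encoder_output"
  out
}

#' @export
print.encoder_output <- function(x, ...) {
  cat("<encoder_output>", nrow(x$node_embeddings), "nodes, embedding dim",
      length(x$graph_embedding), ",", length(x$attentions), "layers\n")
  invisible(x)
}

#' Residue-level attention profile
#'
#' For each layer, averages the attention weights over heads; the
#' per-edge averages are accumulated onto the target node of each
#' directed edge (incoming attention) and summed across layers; the
#' per-node totals are normalized to sum to 1.
#'
#' @param output An `encoder_output` from [encode_graph()].
#' @return Tibble with columns `residue` (node index) and `weight`
#'   (nonnegative, summing to 1), class `attention_profile`.
#' @export
attention_profile <- function(output) {
  if (is.null(output$attentions) || length(output$attentions) == 0) {
    stop("encoder output carries no recorded attentions", call. = FALSE)
  }
  n <- nrow(output$node_embeddings)
  total <- numeric(n)
  for (alpha in output$attentions) {
    mean_heads <- rowMeans(alpha)
    acc <- rowsum(mean_heads, group = output$edges$j)
    total[as.integer(rownames(acc))] <-
      total[as.integer(rownames(acc))] + acc[, 1]
  }
  prof <- tibble::tibble(residue = seq_len(n), weight = total / sum(total))
  class(prof) <- c("attention_profile", class(prof))
  prof
}

#' Plot an attention profile
#'
#' Line plot of normalized attention weight against residue position,
#' with optional vertical markers at known mutation sites.
#'
#' @param object An `attention_profile`.
#' @param mutation_sites Optional integer positions to mark.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.attention_profile <- function(object, mutation_sites = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$residue,
                                            y = .data$weight)) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::labs(x = "Residue position", y = "Normalized attention weight")
  if (!is.null(mutation_sites)) {
    p <- p + ggplot2::geom_vline(xintercept = mutation_sites,
                                 linetype = "dashed", color = "firebrick")
  }
  p
}
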