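# Shared helpers: brute-force oracles kept independent of the package's
# internal code paths, plus small random instance generators.

# all-pairs brute-force contact graph: threshold, sort by distance with
# ascending-index tie-break, cap at max_neighbors
brute_force_graph <- function(coords, radius, max_neighbors) {
  n <- nrow(coords)
  is_ <- integer(0); js <- integer(0)
  for (i in seq_len(n)) {
    d <- sqrt(colSums((t(coords) - coords[i, ])^2))
    cand <- setdiff(which(d <= radius), i)
    if (length(cand) == 0) next
    ord <- cand[order(round(d[cand], 6), cand)]
    ord <- ord[seq_len(min(length(ord), max_neighbors))]
    is_ <- c(is_, rep(i, length(ord)))
    js <- c(js, ord)
  }
  cbind(i = is_, j = js)
}

# dense masked attention oracle for one head: full n x n logit matrix,
# -Inf on non-edges, row softmax restricted to each node's neighbors
dense_attention_oracle <- function(h, e, edges, head) {
  n <- nrow(h)
  d <- ncol(head$W_Q)
  q <- h %*% head$W_Q
  km <- h %*% head$W_K
  em <- e %*% head$W_E
  logits <- matrix(-Inf, n, n)
  for (k in seq_len(nrow(edges))) {
    i <- edges$i[k]; j <- edges$j[k]
    logits[i, j] <- sum(q[i, ] * (km[j, ] + em[k, ])) / sqrt(d)
  }
  alpha_dense <- t(apply(logits, 1, function(row) {
    if (all(is.infinite(row))) return(rep(0, length(row)))
    z <- exp(row - max(row[is.finite(row)]))
    z[is.infinite(row)] <- 0
    z / sum(z)
  }))
  vapply(seq_len(nrow(edges)), function(k) {
    alpha_dense[edges$i[k], edges$j[k]]
  }, numeric(1))
}

# dense aggregation oracle across all heads of one layer
dense_aggregate_oracle <- function(h, e, edges, alpha, layer) {
  n <- nrow(h)
  per_head <- lapply(seq_along(layer$heads), function(hd) {
    head <- layer$heads[[hd]]
    out <- matrix(0, n, ncol(head$W_V))
    for (k in seq_len(nrow(edges))) {
      i <- edges$i[k]; j <- edges$j[k]
      out[i, ] <- out[i, ] + alpha[k, hd] *
        (drop(h[j, ] %*% head$W_V) + drop(e[k, ] %*% head$W_E))
    }
    out
  })
  do.call(cbind, per_head) %*% layer$W_O
}

# random small graph instance with features, for attention oracle tests
random_attention_instance <- function(n, seed, dim = 8, edge_dim = 5) {
  set.seed(seed)
  edges_i <- integer(0); edges_j <- integer(0)
  for (i in seq_len(n)) {
    k <- sample(1:min(3, n - 1), 1)
    edges_i <- c(edges_i, rep(i, k))
    edges_j <- c(edges_j, sample(setdiff(seq_len(n), i), k))
  }
  keep <- !duplicated(paste(edges_i, edges_j))
  list(
    h = matrix(rnorm(n * dim), n, dim),
    e = matrix(rnorm(sum(keep) * edge_dim), sum(keep), edge_dim),
    edges = tibble::tibble(i = edges_i[keep], j = edges_j[keep])
  )
}

small_layer_params <- function(dim, edge_dim, n_heads = 2, d_head = 4,
                               seed = 1) {
  params <- init_encoder_params(node_dim = dim, edge_dim = edge_dim,
                                dim = dim, n_layers = 1,
                                n_heads = n_heads, d_head = d_head,
                                ffn_dim = 2 * dim, seed = seed)
  params$layers[[1]]
}

# independent metric formulas for the oracle comparison
oracle_metrics <- function(yt, yp) {
  n <- length(yt)
  list(
    r2 = 1 - sum((yt - yp)^2) / sum((yt - mean(yt))^2),
    pcc = stats::cor(yt, yp),
    rmse = sqrt(sum((yt - yp)^2) / n),
    mae = sum(abs(yt - yp)) / n
  )
}
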