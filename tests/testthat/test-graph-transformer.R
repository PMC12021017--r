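test_that("attention weights normalize and match hand cases", {
  inst <- random_attention_instance(5, seed = 1)
  layer <- small_layer_params(8, 5, seed = 2)
  head <- layer$heads[[1]]

  alpha <- attention_scores(inst$h, inst$e, inst$edges, head)
  sums <- tapply(alpha, inst$edges$i, sum)
  expect_true(all(abs(sums - 1) < 1e-6))

  # identical neighbors and edge features -> uniform weights
  h_const <- matrix(1, 4, 8)
  edges_star <- tibble::tibble(i = rep(1, 3), j = 2:4)
  e_const <- matrix(0.5, 3, 5)
  alpha_u <- attention_scores(h_const, e_const, edges_star, head)
  expect_equal(alpha_u, rep(1 / 3, 3), tolerance = 1e-9)

  # single neighbor -> weight 1
  one <- attention_scores(inst$h, inst$e[1, , drop = FALSE],
                          tibble::tibble(i = 1, j = 2), head)
  expect_equal(one, 1)

  expect_error(attention_scores(inst$h[, 1:3], inst$e, inst$edges, head),
               "shape mismatch")
})

test_that("attention matches the dense-masked brute-force oracle", {
  for (s in 1:20) {
    n <- sample(4:10, 1)
    inst <- random_attention_instance(n, seed = s)
    layer <- small_layer_params(8, 5, seed = s + 100)
    alpha <- vapply(layer$heads, function(hd) {
      attention_scores(inst$h, inst$e, inst$edges, hd)
    }, numeric(nrow(inst$edges)))
    for (hd in seq_along(layer$heads)) {
      oracle <- dense_attention_oracle(inst$h, inst$e, inst$edges,
                                       layer$heads[[hd]])
      expect_lt(max(abs(alpha[, hd] - oracle)), 1e-6)
    }
    agg <- attention_aggregate(inst$h, inst$e, inst$edges, alpha, layer)
    expect_lt(max(abs(agg - dense_aggregate_oracle(inst$h, inst$e,
                                                   inst$edges, alpha,
                                                   layer))), 1e-6)
  }
})

test_that("aggregation endpoints behave as convex combinations", {
  layer <- small_layer_params(6, 4, n_heads = 1, seed = 3)
  head <- layer$heads[[1]]
  set.seed(4)
  h <- matrix(rnorm(12), 2, 6)
  e <- matrix(rnorm(4), 1, 4)
  edges <- tibble::tibble(i = 1, j = 2)
  alpha <- matrix(1, 1, 1)
  agg <- attention_aggregate(h, e, edges, alpha, layer)
  manual <- (drop(h[2, ] %*% head$W_V) + drop(e[1, ] %*% head$W_E)) %*%
    layer$W_O
  expect_equal(agg[1, ], drop(manual), tolerance = 1e-10)

  # zero edge weights + identical neighbors: output independent of alpha
  layer0 <- layer
  layer0$heads[[1]]$W_E[] <- 0
  h_same <- rbind(h[1, ], h[2, ], h[2, ])
  edges2 <- tibble::tibble(i = c(1, 1), j = c(2, 3))
  e2 <- matrix(rnorm(8), 2, 4)
  a1 <- matrix(c(0.3, 0.7), 2, 1)
  a2 <- matrix(c(0.9, 0.1), 2, 1)
  expect_equal(attention_aggregate(h_same, e2, edges2, a1, layer0)[1, ],
               attention_aggregate(h_same, e2, edges2, a2, layer0)[1, ],
               tolerance = 1e-10)

  expect_error(attention_aggregate(h, e, edges, matrix(0.5, 1, 1), layer),
               "not normalized")
})

test_that("transformer layers are deterministic and permutation-equivariant", {
  h <- make_helix_fixture(8, "helix")
  g <- featurize(h)
  params <- init_encoder_params(ncol(g$node_features),
                                ncol(g$edge_features), dim = 16,
                                n_layers = 2, n_heads = 2, d_head = 4,
                                ffn_dim = 32, seed = 5)
  out1 <- encode_graph(g, params)
  out2 <- encode_graph(g, params)
  expect_identical(out1$node_embeddings, out2$node_embeddings)

  # permute node storage order; relabel edges consistently
  perm <- c(3, 1, 4, 2, 8, 6, 5, 7)
  inv <- order(perm)
  g_perm <- g
  g_perm$node_features <- g$node_features[perm, ]
  g_perm$residue_ids <- g$residue_ids[perm]
  g_perm$edges <- tibble::tibble(i = inv[g$edges$i], j = inv[g$edges$j],
                                 dist = g$edges$dist)
  out_perm <- encode_graph(g_perm, params)
  expect_lt(max(abs(out_perm$node_embeddings -
                      out1$node_embeddings[perm, ])), 1e-8)
  expect_lt(max(abs(out_perm$graph_embedding - out1$graph_embedding)), 1e-8)

  # per-layer, per-head softmax sums are 1
  for (alpha in out1$attentions) {
    for (hd in seq_len(ncol(alpha))) {
      sums <- tapply(alpha[, hd], out1$edges$i, sum)
      expect_true(all(abs(sums - 1) < 1e-6))
    }
  }
})

test_that("encoding is rigid-motion invariant end-to-end", {
  h <- make_helix_fixture(9, "strand")
  g <- featurize(h)
  params <- init_encoder_params(ncol(g$node_features),
                                ncol(g$edge_features), dim = 16,
                                n_layers = 2, n_heads = 2, d_head = 4,
                                ffn_dim = 32, seed = 6)
  base <- encode_graph(g, params)
  for (s in 1:5) {
    rm_ <- random_rigid_motion(s + 40)
    moved <- encode_graph(featurize(transform_structure(h, rm_$R, rm_$t)),
                          params)
    expect_lt(max(abs(moved$graph_embedding - base$graph_embedding)), 1e-5)
  }
})

test_that("single-node graphs pool to the node embedding via a self-loop", {
  g1 <- featurize(make_helix_fixture(2, "helix"))
  # distance beyond any radius: make nodes isolated
  g1$edges <- g1$edges[0, ]
  g1$edge_features <- g1$edge_features[0, , drop = FALSE]
  params <- init_encoder_params(ncol(g1$node_features),
                                ncol(g1$edge_features), dim = 8,
                                n_layers = 1, n_heads = 1, d_head = 4,
                                ffn_dim = 16, seed = 7)
  out <- encode_graph(g1, params)
  expect_equal(nrow(out$edges), 2)      # one self-loop per isolated node
  expect_true(all(out$edges$i == out$edges$j))
  expect_equal(out$graph_embedding, colMeans(out$node_embeddings))
})

test_that("attention profile normalizes and localizes concentrated mass", {
  # uniform attention on a 4-cycle: uniform profile
  g <- featurize(make_helix_fixture(6, "helix"))
  params <- init_encoder_params(ncol(g$node_features),
                                ncol(g$edge_features), dim = 8,
                                n_layers = 1, n_heads = 1, d_head = 4,
                                ffn_dim = 16, seed = 8)
  out <- encode_graph(g, params)
  prof <- attention_profile(out)
  expect_equal(sum(prof$weight), 1, tolerance = 1e-9)
  expect_true(all(prof$weight >= 0))

  # crafted concentration: every node attends only to node 5
  n <- 6
  edges <- tibble::tibble(i = setdiff(1:n, 5), j = 5, dist = 1)
  fake <- out
  fake$edges <- edges
  fake$attentions <- list(matrix(1, nrow(edges), 1))
  fake$node_embeddings <- matrix(0, n, 8)
  prof2 <- attention_profile(fake)
  expect_equal(which.max(prof2$weight), 5)
  expect_equal(prof2$weight[5], 1)

  out$attentions <- list()
  expect_error(attention_profile(out), "no recorded attentions")
})

test_that("uniform attention on a regular graph yields a uniform profile", {
  # directed 4-cycle, equal logits by construction (constant h, zero e)
  n <- 4
  edges <- tibble::tibble(i = 1:4, j = c(2, 3, 4, 1), dist = 1)
  fake <- list(node_embeddings = matrix(0, n, 4),
               attentions = list(matrix(1, 4, 2)),
               edges = edges)
  class(fake) <- "encoder_output"
  prof <- attention_profile(fake)
  expect_equal(prof$weight, rep(1 / n, n))
})
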