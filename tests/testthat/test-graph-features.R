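test_that("rbf_encode matches its closed form and decays in the tail", {
  params <- rbf_params(centers = c(0, 2, 4, 6), width = 2)
  enc <- rbf_encode(2, params)
  expect_equal(enc[1, 2], 1.0)                       # d = mu_k
  expect_equal(enc[1, 3], exp(-1))                   # d = mu_k + sigma
  expect_true(all(enc > 0 & enc <= 1))
  # beyond the largest center every component decreases with d
  far <- rbf_encode(c(7, 8, 9), params)
  expect_true(all(diff(far) < 0))
  expect_error(rbf_encode(-1, params), "nonnegative")
  expect_error(rbf_params(centers = c(3, 1)), "increasing")
})

test_that("graph construction equals the brute-force all-pairs oracle", {
  cfg <- graph_config(radius = 10, max_neighbors = 20)
  # collinear example: all pairs within 10 A
  coords <- rbind(c(0, 0, 0), c(3.8, 0, 0), c(7.6, 0, 0))
  g <- build_residue_graph(coords, cfg)
  expect_equal(nrow(g), 6)

  # beyond cutoff: empty
  far <- rbind(c(0, 0, 0), c(12, 0, 0))
  expect_equal(nrow(build_residue_graph(far, cfg)), 0)

  # degree cap: 30 nodes around node 1
  set.seed(11)
  cluster <- rbind(c(0, 0, 0),
                   matrix(rnorm(29 * 3, sd = 2), 29, 3))
  g <- build_residue_graph(cluster, cfg)
  deg0 <- sum(g$i == 1)
  expect_equal(deg0, 20)
  oracle <- brute_force_graph(cluster, 10, 20)
  expect_equal(as.matrix(g[, c("i", "j")]),
               oracle, ignore_attr = TRUE)

  # random instances, n <= 50
  for (s in 1:25) {
    set.seed(s)
    n <- sample(5:50, 1)
    coords <- matrix(rnorm(n * 3, sd = 6), n, 3)
    g <- build_residue_graph(coords, cfg)
    expect_equal(as.matrix(g[, c("i", "j")]),
                 brute_force_graph(coords, 10, 20), ignore_attr = TRUE)
    expect_true(all(g$dist <= 10))
    expect_true(all(table(g$i) <= 20))
  }
  expect_error(build_residue_graph(rbind(c(0, 0, 0), c(NA, 0, 0)), cfg),
               "non-finite")
})

test_that("dihedral features hit fixture targets and encode termini as zero", {
  h <- make_helix_fixture(10, "helix")
  feats <- dihedral_features(h)
  # interior residues: phi within 2 degrees of -57, psi of -47
  for (i in 3:8) {
    phi <- atan2(feats[i, 1], feats[i, 2]) * 180 / pi
    psi <- atan2(feats[i, 3], feats[i, 4]) * 180 / pi
    expect_lt(abs(phi - (-57)), 2)
    expect_lt(abs(psi - (-47)), 2)
  }
  expect_true(all(feats >= -1 & feats <= 1))

  two <- make_helix_fixture(2, "strand")
  f2 <- dihedral_features(two)
  expect_equal(unname(f2[1, 1:2]), c(0, 0))   # first residue phi undefined
  expect_equal(unname(f2[2, 3:4]), c(0, 0))   # last residue psi undefined

  rm_ <- random_rigid_motion(5)
  moved <- dihedral_features(transform_structure(h, rm_$R, rm_$t))
  expect_lt(max(abs(moved - feats)), 1e-9)
})

test_that("secondary structure assignment matches the fixture construction", {
  h <- make_helix_fixture(10, "helix")
  ss <- secondary_structure_onehot(h)
  expect_true(all(rowSums(ss) == 1))
  expect_true(all(ss[3:8, 1] == 1))  # interior helix state

  s <- make_helix_fixture(10, "strand")
  ss2 <- secondary_structure_onehot(s)
  expect_true(all(ss2[3:8, 2] == 1))  # interior strand state
  expect_true(all(rowSums(ss2) == 1))

  # external assignments pass through
  ext <- secondary_structure_onehot(h, n_states = 8,
                                    assignments = rep(c(1, 8), 5))
  expect_equal(dim(ext), c(10, 8))
  expect_true(all(rowSums(ext) == 1))
})

test_that("accessible surface area is normalized, occlusion-sensitive and invariant", {
  iso <- make_helix_fixture(2, "strand")
  asa_iso <- accessible_surface_area(iso)
  expect_true(all(asa_iso >= 0.8))   # no occluders beyond the chain itself

  # residue buried in a long helix is less exposed than in the dimer
  long <- make_helix_fixture(15, "helix")
  asa_long <- accessible_surface_area(long)
  expect_lt(asa_long[8], asa_iso[1])
  expect_true(all(asa_long >= 0 & asa_long <= 1))

  rm_ <- random_rigid_motion(9)
  moved <- accessible_surface_area(transform_structure(long, rm_$R, rm_$t))
  expect_lt(max(abs(moved - asa_long)), 1e-6)
})

test_that("local frames are orthonormal, equivariant and chirality-sensitive", {
  h <- make_helix_fixture(6, "helix")
  for (i in 1:6) {
    fr <- local_frame(h$coords_N[i, ], h$coords_CA[i, ], h$coords_C[i, ])
    expect_lt(max(abs(t(fr$O) %*% fr$O - diag(3))), 1e-9)
    expect_equal(det(fr$O), 1, tolerance = 1e-9)
  }
  fr <- local_frame(h$coords_N[2, ], h$coords_CA[2, ], h$coords_C[2, ])
  rm_ <- random_rigid_motion(3)
  fr_rot <- local_frame(drop(rm_$R %*% h$coords_N[2, ]),
                        drop(rm_$R %*% h$coords_CA[2, ]),
                        drop(rm_$R %*% h$coords_C[2, ]))
  expect_lt(max(abs(fr_rot$O - rm_$R %*% fr$O)), 1e-9)
  fr_shift <- local_frame(h$coords_N[2, ] + 5, h$coords_CA[2, ] + 5,
                          h$coords_C[2, ] + 5)
  expect_lt(max(abs(fr_shift$O - fr$O)), 1e-12)
  expect_error(local_frame(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)), "degenerate")

  dirs <- sidechain_direction(h)
  expect_true(all(abs(sqrt(rowSums(dirs^2)) - 1) < 1e-6))
  moved <- sidechain_direction(transform_structure(h, rm_$R, rm_$t))
  expect_lt(max(abs(moved - dirs)), 1e-9)
  # mirror image flips the frame-projected direction
  mirror <- h
  for (a in c("N", "CA", "C", "O", "CB")) {
    f <- paste0("coords_", a)
    mirror[[f]][, 3] <- -mirror[[f]][, 3]
  }
  expect_gt(max(abs(sidechain_direction(mirror) - dirs)), 1e-3)
})

test_that("quaternion round trip with canonical sign", {
  expect_equal(rotation_to_quaternion(diag(3)), c(1, 0, 0, 0))
  rot_z180 <- matrix(c(-1, 0, 0, 0, -1, 0, 0, 0, 1), 3, 3)
  expect_equal(rotation_to_quaternion(rot_z180), c(0, 0, 0, 1))
  for (s in 1:30) {
    R <- random_rigid_motion(s)$R
    q <- rotation_to_quaternion(R)
    expect_equal(sum(q^2), 1, tolerance = 1e-9)
    expect_true(q[1] >= 0)
    expect_lt(max(abs(quaternion_to_rotation(q) - R)), 1e-6)
    # sign canonicalization is stable: q of the reconstructed R agrees
    expect_lt(max(abs(rotation_to_quaternion(quaternion_to_rotation(q)) - q)),
              1e-6)
  }
  expect_error(rotation_to_quaternion(matrix(1, 3, 3)), "not a rotation")
})

test_that("positional encoding matches the sinusoidal formula", {
  pe0 <- positional_encoding(0, dim = 8)
  expect_equal(drop(pe0), rep(c(0, 1), 4))
  pe_pos <- positional_encoding(3, dim = 8)
  pe_neg <- positional_encoding(-3, dim = 8)
  sin_idx <- c(1, 3, 5, 7); cos_idx <- sin_idx + 1
  expect_equal(pe_pos[1, sin_idx], -pe_neg[1, sin_idx])
  expect_equal(pe_pos[1, cos_idx], pe_neg[1, cos_idx])
  # direct formula evaluation
  k <- 0:3
  expect_equal(drop(positional_encoding(1, 8))[sin_idx],
               sin(1 / 10000^(2 * k / 8)))
  expect_error(positional_encoding(1, dim = 5), "even")
})

test_that("featurize output is invariant, consistently shaped and asymmetric", {
  h <- make_helix_fixture(10, "helix")
  g <- featurize(h)
  expect_equal(nrow(g$node_features), 10)
  expect_equal(ncol(g$edge_features), 16 + 16 + 3 + 4)
  quat_cols <- g$layout$edge$quaternion
  qnorm <- sqrt(rowSums(g$edge_features[, quat_cols]^2))
  expect_true(all(abs(qnorm - 1) < 1e-6))

  rm_ <- random_rigid_motion(21)
  g2 <- featurize(transform_structure(h, rm_$R, rm_$t))
  expect_lt(max(abs(g$node_features - g2$node_features)), 1e-6)
  expect_lt(max(abs(g$edge_features - g2$edge_features)), 1e-6)

  # i->j vs j->i: PE sin-parity, identical RBF, differing orientation
  k_ij <- which(g$edges$i == 2 & g$edges$j == 3)
  k_ji <- which(g$edges$i == 3 & g$edges$j == 2)
  pe_cols <- g$layout$edge$pe
  sin_cols <- pe_cols[seq(1, length(pe_cols), by = 2)]
  cos_cols <- pe_cols[seq(2, length(pe_cols), by = 2)]
  expect_equal(g$edge_features[k_ij, sin_cols],
               -g$edge_features[k_ji, sin_cols])
  expect_equal(g$edge_features[k_ij, cos_cols],
               g$edge_features[k_ji, cos_cols])
  expect_equal(g$edge_features[k_ij, g$layout$edge$rbf],
               g$edge_features[k_ji, g$layout$edge$rbf])
  expect_gt(max(abs(g$edge_features[k_ij, g$layout$edge$direction] -
                      g$edge_features[k_ji, g$layout$edge$direction])), 1e-6)

  # minimal graph: 2 residues within radius give 2 directed edges
  g_min <- featurize(make_helix_fixture(2, "helix"))
  expect_equal(nrow(g_min$edges), 2)
})
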