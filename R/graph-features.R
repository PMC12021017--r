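# Residue-graph featurization: RBF distance encoding, backbone dihedrals,
# secondary-structure one-hot, Shrake-Rupley accessible surface area,
# local frames, relative-orientation quaternions and sinusoidal positional
# encodings. All features are invariant under rigid motions of the input
# structure.

#' Radial-basis-function parameters
#'
#' @param centers Strictly increasing Gaussian center positions (Angstrom).
#'   The default is 16 centers evenly spaced on 0-20 Angstrom, spanning
#'   the 10 Angstrom contact cutoff with room for the tail.
#' @param width Gaussian width sigma (Angstrom); defaults to the center
#'   spacing.
#' @return An `rbf_params` list.
#' @export
rbf_params <- function(centers = seq(0, 20, length.out = 16),
                       width = NULL) {
  if (length(centers) < 1 || any(diff(centers) <= 0)) {
    stop("centers must be strictly increasing", call. = FALSE)
  }
  if (is.null(width)) {
    width <- if (length(centers) > 1) centers[2] - centers[1] else 1
  }
  if (width <= 0) stop("width must be positive", call. = FALSE)
  structure(list(centers = centers, width = width), class = "rbf_params")
}

#' Gaussian radial-basis-function distance encoding
#'
#' Encodes a distance d as the vector exp(-((d - mu_k) / sigma)^2) over a
#' bank of centers mu_k, giving a smooth, locality-sensitive
#' representation; every component lies in (0, 1].
#'
#' @param d Nonnegative distance(s) in Angstrom.
#' @param params An [rbf_params()] bank.
#' @return Numeric matrix, one row per distance, one column per center.
#' @export
rbf_encode <- function(d, params = rbf_params()) {
  if (any(d < 0)) stop("distances must be nonnegative", call. = FALSE)
  outer(d, params$centers, function(x, mu) exp(-((x - mu) / params$width)^2))
}

#' Residue-graph configuration
#'
#' @param radius Contact cutoff on CA-CA distance (Angstrom, default 10).
#' @param max_neighbors Maximum out-degree per residue (default 20): when
#'   more residues lie within the radius only the closest are kept.
#' @param pe_dim Length of the sinusoidal positional encoding (even).
#' @param rbf An [rbf_params()] bank.
#' @param ss_states Secondary-structure alphabet size (3: helix, strand,
#'   coil).
#' @return A `graph_config` list.
#' @export
graph_config <- function(radius = 10, max_neighbors = 20, pe_dim = 16,
                         rbf = rbf_params(), ss_states = 3) {
  if (radius <= 0) stop("radius must be positive", call. = FALSE)
  if (max_neighbors < 1) stop("max_neighbors must be >= 1", call. = FALSE)
  if (pe_dim %% 2 != 0) stop("pe_dim must be even", call. = FALSE)
  structure(list(radius = radius, max_neighbors = max_neighbors,
                 pe_dim = pe_dim, rbf = rbf, ss_states = ss_states),
            class = "graph_config")
}

#' Build the directed residue contact graph
#'
#' Connects residue i to residue j when their CA-CA distance is at most
#' `radius`; when more than `max_neighbors` residues qualify, only the
#' nearest are kept. Neighbors are sorted by ascending distance, ties
#' broken by ascending residue index, so the edge list is deterministic.
#'
#' @param coords_ca Numeric n x 3 matrix of CA coordinates.
#' @param config A [graph_config()].
#' @return Tibble with columns `i`, `j` (1-based node indices) and
#'   `dist` (Angstrom); no self-edges.
#' @export
build_residue_graph <- function(coords_ca, config = graph_config()) {
  if (!all(is.finite(coords_ca))) {
    stop("non-finite CA coordinate", call. = FALSE)
  }
  n <- nrow(coords_ca)
  if (n < 2) stop("need at least 2 residues", call. = FALSE)
  dm <- as.matrix(stats::dist(coords_ca))
  is_ <- integer(0); js <- integer(0); ds <- numeric(0)
  for (i in seq_len(n)) {
    cand <- setdiff(which(dm[i, ] <= config$radius), i)
    if (length(cand) == 0) next
    # round before ordering so equal-distance ties resolve identically
    # under floating-point jitter (e.g. after a rigid motion)
    ord <- order(round(dm[i, cand], 6), cand)
    cand <- cand[ord][seq_len(min(length(cand), config$max_neighbors))]
    is_ <- c(is_, rep(i, length(cand)))
    js <- c(js, cand)
    ds <- c(ds, dm[i, cand])
  }
  tibble::tibble(i = is_, j = js, dist = ds)
}

# torsion angle (radians) for points p1-p2-p3-p4, standard sign convention
torsion_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  if (vnorm(n1) < 1e-8 || vnorm(n2) < 1e-8) return(NA_real_)
  m1 <- cross3(n1, unit(b2))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  atan2(y, x)
}

# per-residue phi, psi, omega in radians; NA where undefined (termini or
# degenerate geometry)
backbone_torsions <- function(structure) {
  n <- length(structure)
  N <- structure$coords_N; CA <- structure$coords_CA; C <- structure$coords_C
  phi <- psi <- omega <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (i > 1) {
      phi[i] <- torsion_angle(C[i - 1, ], N[i, ], CA[i, ], C[i, ])
      omega[i] <- torsion_angle(CA[i - 1, ], C[i - 1, ], N[i, ], CA[i, ])
    }
    if (i < n) {
      psi[i] <- torsion_angle(N[i, ], CA[i, ], C[i, ], N[i + 1, ])
    }
  }
  cbind(phi = phi, psi = psi, omega = omega)
}

#' Backbone dihedral features
#'
#' Encodes the phi, psi and omega torsions of every residue as
#' (sin, cos) pairs. Angles undefined at the chain termini (phi/omega of
#' the first residue, psi of the last) are encoded as (0, 0); degenerate
#' (collinear) atom quadruples are encoded the same way with a warning.
#'
#' @param structure A [backbone_structure()] of length >= 2.
#' @return Numeric n x 6 matrix with columns sin/cos of phi, psi, omega.
#' @export
dihedral_features <- function(structure) {
  if (length(structure) < 2) stop("need at least 2 residues", call. = FALSE)
  tor <- backbone_torsions(structure)
  n <- nrow(tor)
  # interior NAs indicate degenerate geometry, not termini
  interior_na <- is.na(tor)
  interior_na[1, c("phi", "omega")] <- FALSE
  interior_na[n, "psi"] <- FALSE
  if (any(interior_na)) {
    warning("degenerate backbone geometry: ", sum(interior_na),
            " undefined interior torsion(s) encoded as (0, 0)", call. = FALSE)
  }
  out <- matrix(0, n, 6)
  colnames(out) <- c("sin_phi", "cos_phi", "sin_psi", "cos_psi",
                     "sin_omega", "cos_omega")
  for (k in 1:3) {
    ok <- !is.na(tor[, k])
    out[ok, 2 * k - 1] <- sin(tor[ok, k])
    out[ok, 2 * k] <- cos(tor[ok, k])
  }
  out
}

#' Secondary-structure one-hot encoding
#'
#' Assigns each residue to helix, strand or coil from its phi/psi
#' Ramachandran region (helix: phi in [-100, -30], psi in [-80, -5]
#' degrees; strand: phi in [-180, -100], psi in [85, 180] or
#' [-180, -170] degrees; otherwise coil; termini with undefined phi or
#' psi default to coil) and one-hot encodes the assignment.
#'
#' @param structure A [backbone_structure()].
#' @param n_states Alphabet size; only the built-in 3-state scheme is
#'   computed internally. Pre-computed assignments with a different
#'   alphabet can be supplied via `assignments`.
#' @param assignments Optional integer vector of external state
#'   assignments (1-based), overriding the internal rule.
#' @return Numeric n x n_states one-hot matrix; each row sums to 1.
#' @export
secondary_structure_onehot <- function(structure, n_states = 3,
                                       assignments = NULL) {
  n <- length(structure)
  if (is.null(assignments)) {
    if (n_states != 3) {
      stop("internal assignment supports n_states = 3 only; supply ",
           "`assignments` for other alphabets", call. = FALSE)
    }
    if (n < 2) {
      states <- rep(3L, n)  # single residue: coil
    } else {
      tor <- backbone_torsions(structure) * 180 / pi
      states <- rep(3L, n)
      phi <- tor[, "phi"]; psi <- tor[, "psi"]
      defined <- !is.na(phi) & !is.na(psi)
      helix <- defined & phi >= -100 & phi <= -30 & psi >= -80 & psi <= -5
      strand <- defined & phi >= -180 & phi <= -100 &
        ((psi >= 85 & psi <= 180) | (psi >= -180 & psi <= -170))
      states[helix] <- 1L
      states[strand] <- 2L
    }
  } else {
    states <- as.integer(assignments)
    if (length(states) != n || any(states < 1 | states > n_states)) {
      stop("assignments must be 1..n_states for every residue", call. = FALSE)
    }
  }
  out <- matrix(0, n, n_states)
  out[cbind(seq_len(n), states)] <- 1
  colnames(out) <- if (n_states == 3) c("helix", "strand", "coil") else NULL
  out
}

# deterministic Fibonacci sphere points (unit vectors)
fibonacci_sphere <- function(n_points) {
  i <- seq_len(n_points) - 0.5
  phi <- acos(1 - 2 * i / n_points)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

# van der Waals radii (Angstrom) of the five stored atoms
VDW_RADII <- c(N = 1.55, CA = 1.70, C = 1.70, O = 1.52, CB = 1.70)

# Tien et al. theoretical maximum accessible surface areas (Angstrom^2)
MAX_ASA <- c(ALA = 129.0, ARG = 274.0, ASN = 195.0, ASP = 193.0,
             CYS = 167.0, GLN = 225.0, GLU = 223.0, GLY = 104.0,
             HIS = 224.0, ILE = 197.0, LEU = 201.0, LYS = 236.0,
             MET = 224.0, PHE = 240.0, PRO = 159.0, SER = 155.0,
             THR = 172.0, TRP = 285.0, TYR = 263.0, VAL = 174.0)

#' Normalized accessible surface area
#'
#' Shrake-Rupley numeric solvent-accessible surface area over the five
#' stored atoms of every residue (probe radius 1.4 Angstrom, 100 fixed
#' Fibonacci sphere points per atom), summed per residue, normalized by
#' the Tien et al. theoretical per-residue maximum and clipped to
#' [0, 1]. The sphere points of each atom are oriented by the owning
#' residue's local frame, so they co-rotate with the structure and the
#' result is rigid-motion invariant (not just approximately so).
#'
#' @param structure A [backbone_structure()].
#' @param probe_radius Solvent probe radius (Angstrom).
#' @param n_points Sphere points per atom.
#' @return Numeric vector of per-residue values in [0, 1].
#' @export
accessible_surface_area <- function(structure, probe_radius = 1.4,
                                    n_points = 100) {
  n <- length(structure)
  atoms <- c("N", "CA", "C", "O", "CB")
  coords <- do.call(rbind, lapply(atoms, function(a) {
    structure[[paste0("coords_", a)]]
  }))
  radii <- rep(unname(VDW_RADII[atoms]), each = n) + probe_radius
  res_of <- rep(seq_len(n), times = length(atoms))
  sphere <- fibonacci_sphere(n_points)
  frames <- local_frames(structure)
  n_atoms <- nrow(coords)
  area <- numeric(n_atoms)
  # pairwise distances once; only nearby atoms can occlude
  dm <- as.matrix(stats::dist(coords))
  for (a in seq_len(n_atoms)) {
    oriented <- sphere %*% t(frames[res_of[a], , ])
    pts <- sweep(oriented * radii[a], 2, coords[a, ], "+")
    occluders <- which(dm[a, ] < radii[a] + radii & seq_len(n_atoms) != a)
    acc <- rep(TRUE, n_points)
    for (b in occluders) {
      d2 <- rowSums(sweep(pts, 2, coords[b, ])^2)
      acc <- acc & d2 > radii[b]^2
      if (!any(acc)) break
    }
    area[a] <- 4 * pi * radii[a]^2 * sum(acc) / n_points
  }
  res_area <- vapply(seq_len(n), function(i) sum(area[res_of == i]),
                     numeric(1))
  maxa <- MAX_ASA[structure$residue_names]
  maxa[is.na(maxa)] <- mean(MAX_ASA)
  pmin(pmax(res_area / maxa, 0), 1)
}

#' Per-residue local coordinate frame
#'
#' Builds the orthonormal direction matrix of a residue from its N, CA
#' and C atoms: u = (ca - n)/|.|, v = (ca - c)/|.|, b = (u - v)/|u - v|,
#' nvec = (u x v)/|u x v|, O = [b, nvec, b x nvec]. O is orthonormal with
#' det +1, rotates with the structure and is translation invariant.
#'
#' @param n,ca,c Length-3 coordinates of the backbone N, CA, C atoms.
#' @return List with `origin` (the CA position) and `O` (3x3 direction
#'   matrix), class `local_frame`.
#' @export
local_frame <- function(n, ca, c) {
  u <- unit(ca - n)
  v <- unit(ca - c)
  uv <- u - v
  cr <- cross3(u, v)
  if (vnorm(uv) < 1e-8 || vnorm(cr) < 1e-8) {
    stop("degenerate geometry: cannot build local frame (collinear atoms)",
         call. = FALSE)
  }
  b <- unit(uv)
  nvec <- unit(cr)
  O <- cbind(b, nvec, cross3(b, nvec))
  colnames(O) <- NULL
  structure(list(origin = ca, O = O), class = "local_frame")
}

# all frames of a structure as an n x 3 x 3 array
local_frames <- function(structure) {
  n <- length(structure)
  arr <- array(NA_real_, c(n, 3, 3))
  for (i in seq_len(n)) {
    fr <- local_frame(structure$coords_N[i, ], structure$coords_CA[i, ],
                      structure$coords_C[i, ])
    arr[i, , ] <- fr$O
  }
  arr
}

#' Side-chain direction in the residue local frame
#'
#' The unit vector from CA to CB, expressed in the residue's local frame
#' (O^T d). Rigid-motion invariant because the frame co-rotates; flips
#' under mirror images because the frame is chirality-sensitive.
#'
#' @param structure A [backbone_structure()].
#' @return Numeric n x 3 matrix of unit vectors.
#' @export
sidechain_direction <- function(structure) {
  n <- length(structure)
  frames <- local_frames(structure)
  out <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    d <- structure$coords_CB[i, ] - structure$coords_CA[i, ]
    if (vnorm(d) < 1e-8) {
      stop("degenerate geometry: CB coincides with CA at residue ", i,
           call. = FALSE)
    }
    out[i, ] <- t(frames[i, , ]) %*% unit(d)
  }
  out
}

#' Convert a rotation matrix to a canonical unit quaternion
#'
#' Shepperd's method with the sign canonicalized so that w >= 0 (and,
#' when w = 0, the first nonzero of x, y, z is positive), making the
#' representation deterministic: q and -q encode the same rotation.
#'
#' @param R 3x3 rotation matrix (orthonormal within 1e-4, det +1).
#' @return Unit quaternion as c(w, x, y, z).
#' @export
rotation_to_quaternion <- function(R) {
  if (max(abs(t(R) %*% R - diag(3))) > 1e-4 || det(R) < 0.9) {
    stop("input is not a rotation matrix", call. = FALSE)
  }
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s,
           (R[3, 2] - R[2, 3]) / s,
           (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else if (R[1, 1] > R[2, 2] && R[1, 1] > R[3, 3]) {
    s <- sqrt(1 + R[1, 1] - R[2, 2] - R[3, 3]) * 2
    q <- c((R[3, 2] - R[2, 3]) / s, 0.25 * s,
           (R[1, 2] + R[2, 1]) / s, (R[1, 3] + R[3, 1]) / s)
  } else if (R[2, 2] > R[3, 3]) {
    s <- sqrt(1 + R[2, 2] - R[1, 1] - R[3, 3]) * 2
    q <- c((R[1, 3] - R[3, 1]) / s, (R[1, 2] + R[2, 1]) / s,
           0.25 * s, (R[2, 3] + R[3, 2]) / s)
  } else {
    s <- sqrt(1 + R[3, 3] - R[1, 1] - R[2, 2]) * 2
    q <- c((R[2, 1] - R[1, 2]) / s, (R[1, 3] + R[3, 1]) / s,
           (R[2, 3] + R[3, 2]) / s, 0.25 * s)
  }
  q <- q / vnorm(q)
  # canonical sign
  nz <- which(abs(q) > 1e-12)
  if (length(nz) > 0 && q[nz[1]] < 0) q <- -q
  q
}

#' Convert a unit quaternion back to a rotation matrix
#'
#' @param q Unit quaternion c(w, x, y, z).
#' @return 3x3 rotation matrix.
#' @export
quaternion_to_rotation <- function(q) {
  q <- q / vnorm(q)
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

#' Sinusoidal positional encoding of a sequence-index offset
#'
#' The Transformer encoding of an integer offset o: component 2k is
#' sin(o / 10000^(2k/dim)) and component 2k+1 is cos of the same
#' argument (k = 0 .. dim/2 - 1).
#'
#' @param offset Signed integer offset(s) (i - j).
#' @param dim Even encoding length.
#' @return Numeric matrix, one row per offset, values in [-1, 1].
#' @export
positional_encoding <- function(offset, dim = 16) {
  if (dim %% 2 != 0) stop("dim must be even", call. = FALSE)
  k <- seq_len(dim / 2) - 1
  freq <- 1 / 10000^(2 * k / dim)
  out <- matrix(NA_real_, length(offset), dim)
  ang <- outer(offset, freq)
  out[, 2 * k + 1] <- sin(ang)
  out[, 2 * k + 2] <- cos(ang)
  out
}

#' Featurize a backbone structure into a residue graph
#'
#' Builds the directed contact graph ([build_residue_graph()]) and
#' attaches per-node features (secondary-structure one-hot, dihedral
#' sin/cos, normalized accessible surface area, side-chain direction in
#' the local frame) and per-edge features: the sinusoidal positional
#' encoding of the sequence offset i - j, the RBF encoding of the CA-CA
#' distance, the unit inter-residue direction projected into the source
#' residue's local frame, and the canonical quaternion of the relative
#' orientation O_i^T O_j. All features are rigid-motion invariant.
#'
#' @param structure A [backbone_structure()] of length >= 2.
#' @param config A [graph_config()].
#' @return A `residue_graph`: list with `node_features` (n x 13),
#'   `edges` (tibble i, j, dist), `edge_features` (E x
#'   (pe_dim + n_rbf + 3 + 4)), `sequence`, `config` and a `layout`
#'   attribute naming the feature blocks and their column spans.
#' @export
featurize <- function(structure, config = graph_config()) {
  stopifnot(inherits(structure, "backbone_structure"))
  node_features <- cbind(
    secondary_structure_onehot(structure, config$ss_states),
    dihedral_features(structure),
    asa = accessible_surface_area(structure),
    sidechain_direction(structure)
  )
  edges <- build_residue_graph(structure$coords_CA, config)
  frames <- local_frames(structure)
  ids <- structure$residue_ids
  n_e <- nrow(edges)
  pe <- positional_encoding(ids[edges$i] - ids[edges$j], config$pe_dim)
  rbf <- rbf_encode(edges$dist, config$rbf)
  dirs <- matrix(NA_real_, n_e, 3)
  quats <- matrix(NA_real_, n_e, 4)
  for (k in seq_len(n_e)) {
    i <- edges$i[k]; j <- edges$j[k]
    Oi <- frames[i, , ]
    u <- unit(structure$coords_CA[j, ] - structure$coords_CA[i, ])
    dirs[k, ] <- t(Oi) %*% u
    quats[k, ] <- rotation_to_quaternion(t(Oi) %*% frames[j, , ])
  }
  edge_features <- cbind(pe, rbf, dirs, quats)
  layout <- list(
    node = list(ss = 1:config$ss_states,
                dihedral = config$ss_states + 1:6,
                asa = config$ss_states + 7,
                sidechain = config$ss_states + 7 + 1:3),
    edge = list(pe = seq_len(config$pe_dim),
                rbf = config$pe_dim + seq_along(config$rbf$centers),
                direction = config$pe_dim + length(config$rbf$centers) + 1:3,
                quaternion = config$pe_dim + length(config$rbf$centers) + 3 + 1:4)
  )
  out <- list(node_features = node_features,
              edges = edges,
              edge_features = edge_features,
              sequence = structure$sequence,
              residue_ids = ids,
              config = config,
              layout = layout)
  class(out) <- "residue_graph"
  out
}

#' @export
print.residue_graph <- function(x, ...) {
  cat("<residue_graph>", nrow(x$node_features), "nodes,",
      nrow(x$edges), "directed edges\n")
  cat("  node feature dim:", ncol(x$node_features),
      " edge feature dim:", ncol(x$edge_features), "\n")
  invisible(x)
}
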