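# Backbone structure container and PDB I/O.
#
# A backbone_structure stores, per residue, the five key atoms used by the
# graph featurization (N, CA, C, O, CB) plus the sequence. CB is
# reconstructed at an ideal tetrahedral position when absent (always for
# glycine) and flagged as virtual.

#' Construct a backbone structure object
#'
#' @param residue_ids Integer vector of 1-based sequence positions,
#'   strictly increasing.
#' @param residue_names Character vector of 3-letter residue codes.
#' @param coords_N,coords_CA,coords_C,coords_O,coords_CB Numeric n x 3
#'   matrices of atom coordinates in Angstrom.
#' @param chain_id Single chain identifier.
#' @param cb_is_virtual Logical vector: TRUE where CB was reconstructed
#'   rather than read from the file.
#' @return An object of class `backbone_structure`.
#' @export
backbone_structure <- function(residue_ids, residue_names,
                               coords_N, coords_CA, coords_C,
                               coords_O, coords_CB,
                               chain_id = "A",
                               cb_is_virtual = NULL) {
  n <- length(residue_ids)
  if (n < 1) stop("a backbone structure needs at least one residue", call. = FALSE)
  mats <- list(N = coords_N, CA = coords_CA, C = coords_C,
               O = coords_O, CB = coords_CB)
  for (nm in names(mats)) {
    m <- mats[[nm]]
    if (!is.matrix(m) || nrow(m) != n || ncol(m) != 3) {
      stop("coords_", nm, " must be an n x 3 matrix", call. = FALSE)
    }
    if (!all(is.finite(m))) {
      stop("coords_", nm, " contains non-finite values", call. = FALSE)
    }
  }
  if (length(residue_names) != n) {
    stop("residue_names length mismatch", call. = FALSE)
  }
  if (n > 1 && any(diff(residue_ids) <= 0)) {
    stop("residue_ids must be strictly increasing", call. = FALSE)
  }
  if (is.null(cb_is_virtual)) cb_is_virtual <- rep(FALSE, n)
  structure(
    list(residue_ids = as.integer(residue_ids),
         residue_names = residue_names,
         coords_N = coords_N, coords_CA = coords_CA, coords_C = coords_C,
         coords_O = coords_O, coords_CB = coords_CB,
         chain_id = chain_id,
         cb_is_virtual = cb_is_virtual,
         sequence = paste(aa_three_to_one(residue_names), collapse = "")),
    class = "backbone_structure"
  )
}

#' @export
length.backbone_structure <- function(x) length(x$residue_ids)

#' @export
print.backbone_structure <- function(x, ...) {
  cat("<backbone_structure> chain", x$chain_id, "with",
      length(x), "residues\n")
  cat("  sequence:", x$sequence, "\n")
  invisible(x)
}

#' Ideal virtual C-beta position
#'
#' Places a C-beta atom at the ideal tetrahedral position implied by the
#' backbone N, CA and C atoms, using the standard ideal-geometry linear
#' combination: with b = ca - n, c2 = c - ca, a = b x c2,
#' cb = -0.58273431 a + 0.56802827 b - 0.54067466 c2 + ca.
#' The construction is equivariant under rigid motions.
#'
#' @param n,ca,c Length-3 numeric coordinates of the backbone N, CA and C
#'   atoms (Angstrom).
#' @return Length-3 numeric coordinate of the virtual C-beta.
#' @export
virtual_cbeta <- function(n, ca, c) {
  b <- ca - n
  c2 <- c - ca
  a <- cross3(b, c2)
  if (vnorm(a) < 1e-8) {
    stop("degenerate geometry: N, CA, C are collinear", call. = FALSE)
  }
  -0.58273431 * a + 0.56802827 * b - 0.54067466 * c2 + ca
}

# Ideal carbonyl O when the file lacks one: along the C=O direction
# approximated in the N-CA-C plane, opposite the backbone bisector.
fallback_oxygen <- function(n, ca, c) {
  d1 <- unit(c - ca)
  perp <- c - ca - sum((c - ca) * unit(ca - n)) * unit(ca - n)
  dir <- if (vnorm(perp) > 1e-8) unit(d1 + 0.5 * unit(perp)) else d1
  c + 1.229 * dir
}

#' Read a backbone structure from PDB text or file
#'
#' Parses ATOM records (via bio3d), resolves alternate locations by
#' highest occupancy (ties by altloc label order), drops residues missing
#' any of N, CA or C with a warning, reconstructs missing C-beta atoms at
#' the ideal tetrahedral position ([virtual_cbeta()]), and renumbers
#' residues into strictly increasing 1-based ids when the file's
#' numbering (e.g. insertion codes) is not already strictly increasing.
#' Hetero residues and waters are ignored.
#'
#' @param pdb Either a path to a PDB file or PDB-format text (a single
#'   string with newlines, or a character vector of lines).
#' @param chain Chain identifier; defaults to the first chain that
#'   appears in the file.
#' @return A [backbone_structure()].
#' @export
read_structure <- function(pdb, chain = NULL) {
  if (length(pdb) > 1 || grepl("\n", pdb[1], fixed = TRUE)) {
    lines <- if (length(pdb) > 1) pdb else strsplit(pdb, "\n", fixed = TRUE)[[1]]
    path <- tempfile(fileext = ".pdb")
    writeLines(lines, path)
    on.exit(unlink(path))
  } else {
    path <- pdb
    if (!file.exists(path)) {
      stop("PDB input is neither existing file nor PDB text: ", path,
           call. = FALSE)
    }
  }
  parsed <- tryCatch(
    # keep all altlocs: occupancy-based resolution happens below
    suppressWarnings(bio3d::read.pdb(path, verbose = FALSE,
                                     rm.alt = FALSE)),
    error = function(e) {
      stop("PDB parse failure: ", conditionMessage(e), call. = FALSE)
    }
  )
  at <- parsed$atom
  at <- at[at$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0) stop("PDB parse failure: no ATOM records found", call. = FALSE)

  chains <- unique(at$chain)
  if (is.null(chain)) chain <- chains[1]
  if (!chain %in% chains) {
    stop("chain '", chain, "' not present; available chains: ",
         paste(chains, collapse = ", "), call. = FALSE)
  }
  at <- at[at$chain == chain, , drop = FALSE]
  at <- at[at$resid %in% AA3 | at$resid == "GLY", , drop = FALSE]
  if (nrow(at) == 0) {
    stop("chain '", chain, "' has no standard amino-acid ATOM records",
         call. = FALSE)
  }

  # altloc resolution: within (residue, atom name) keep highest occupancy,
  # ties broken by altloc label order
  at$insert[is.na(at$insert)] <- ""
  at$alt[is.na(at$alt)] <- ""
  at$o[is.na(at$o)] <- 1
  at$.file_order <- seq_len(nrow(at))
  reskey <- paste(at$resno, at$insert, sep = "|")
  atomkey <- paste(reskey, at$elety, sep = "|")
  ord <- order(atomkey, -at$o, at$alt)
  at <- at[ord, , drop = FALSE]
  at <- at[!duplicated(paste(reskey[ord], at$elety, sep = "|")), , drop = FALSE]
  at <- at[order(at$.file_order), , drop = FALSE]  # restore file order

  reskeys <- unique(paste(at$resno, at$insert, sep = "|"))

  rows <- lapply(reskeys, function(k) {
    sub <- at[paste(at$resno, at$insert, sep = "|") == k, , drop = FALSE]
    getxyz <- function(name) {
      i <- which(sub$elety == name)
      if (length(i) == 0) return(NULL)
      as.numeric(sub[i[1], c("x", "y", "z")])
    }
    list(resno = sub$resno[1], resid = sub$resid[1],
         N = getxyz("N"), CA = getxyz("CA"), C = getxyz("C"),
         O = getxyz("O"), CB = getxyz("CB"))
  })

  complete <- vapply(rows, function(r) {
    !is.null(r$N) && !is.null(r$CA) && !is.null(r$C)
  }, logical(1))
  if (any(!complete)) {
    dropped <- vapply(rows[!complete], function(r) r$resno, numeric(1))
    warning("dropped ", sum(!complete),
            " residue(s) missing N/CA/C backbone atoms: ",
            paste(dropped, collapse = ", "), call. = FALSE)
    rows <- rows[complete]
  }
  if (length(rows) == 0) {
    stop("no residue in chain '", chain, "' has a complete N/CA/C backbone",
         call. = FALSE)
  }

  n <- length(rows)
  mk <- function(field, filler = NULL) {
    t(vapply(rows, function(r) {
      v <- r[[field]]
      if (is.null(v)) filler(r) else v
    }, numeric(3)))
  }
  coords_N <- mk("N")
  coords_CA <- mk("CA")
  coords_C <- mk("C")
  coords_O <- mk("O", function(r) fallback_oxygen(r$N, r$CA, r$C))
  cb_virtual <- vapply(rows, function(r) is.null(r$CB), logical(1))
  coords_CB <- mk("CB", function(r) virtual_cbeta(r$N, r$CA, r$C))

  ids <- vapply(rows, function(r) as.integer(r$resno), integer(1))
  if (any(diff(ids) <= 0) || any(ids < 1)) ids <- seq_len(n)
  backbone_structure(
    residue_ids = ids,
    residue_names = vapply(rows, function(r) r$resid, character(1)),
    coords_N = coords_N, coords_CA = coords_CA, coords_C = coords_C,
    coords_O = coords_O, coords_CB = coords_CB,
    chain_id = chain,
    cb_is_virtual = cb_virtual
  )
}

#' Serialize a backbone structure to PDB text
#'
#' Writes N, CA, C and O for every residue and CB for residues whose CB
#' is not virtual (virtual C-beta positions are reconstructed on read).
#' Round-trips through [read_structure()] to within PDB coordinate
#' precision (1e-3 Angstrom).
#'
#' @param structure A [backbone_structure()].
#' @param file Optional path; when given the text is also written there.
#' @return PDB text as a single string (invisibly when `file` is given).
#' @export
write_structure <- function(structure, file = NULL) {
  stopifnot(inherits(structure, "backbone_structure"))
  n <- length(structure)
  atoms <- c("N", "CA", "C", "O", "CB")
  xyz <- c(); elety <- c(); resno <- c(); resid <- c()
  for (i in seq_len(n)) {
    keep <- if (structure$cb_is_virtual[i]) atoms[1:4] else atoms
    for (a in keep) {
      xyz <- c(xyz, structure[[paste0("coords_", a)]][i, ])
      elety <- c(elety, a)
      resno <- c(resno, structure$residue_ids[i])
      resid <- c(resid, structure$residue_names[i])
    }
  }
  path <- if (is.null(file)) tempfile(fileext = ".pdb") else file
  bio3d::write.pdb(file = path, xyz = xyz, elety = elety, resno = resno,
                   resid = resid, chain = rep(structure$chain_id, length(elety)),
                   eleno = seq_along(elety))
  text <- paste(readLines(path), collapse = "\n")
  if (is.null(file)) {
    unlink(path)
    text
  } else {
    invisible(text)
  }
}

# NeRF atom placement: position D given A-B-C, bond |CD|, angle B-C-D,
# torsion A-B-C-D (radians).
place_atom <- function(a, b, cc, bond, angle, torsion) {
  b2 <- unit(cc - b)
  nrm <- unit(cross3(unit(b - a), b2))
  m <- cross3(nrm, b2)
  d2 <- bond * c(-cos(angle),
                 sin(angle) * cos(torsion),
                 -sin(angle) * sin(torsion))
  cc + d2[1] * b2 + d2[2] * m + d2[3] * nrm
}

#' Ideal-geometry synthetic backbone
#'
#' Builds a deterministic poly-alanine backbone with ideal bond lengths
#' (N-CA 1.458, CA-C 1.525, C-N 1.329 Angstrom) and the canonical
#' dihedral angles of an alpha-helix (phi -57, psi -47 degrees) or an
#' extended strand (phi -139, psi +135 degrees); omega is 180 degrees.
#'
#' @param n_residues Number of residues (>= 2).
#' @param style `"helix"` or `"strand"`.
#' @return A [backbone_structure()].
#' @export
make_helix_fixture <- function(n_residues, style = c("helix", "strand")) {
  style <- match.arg(style)
  if (n_residues < 2) stop("n_residues must be >= 2", call. = FALSE)
  ang <- if (style == "helix") c(phi = -57, psi = -47) else c(phi = -139, psi = 135)
  phi <- ang["phi"] * pi / 180
  psi <- ang["psi"] * pi / 180
  omega <- pi
  # ideal backbone bond angles (degrees): N-CA-C 111.2, CA-C-N 116.2, C-N-CA 121.7
  a_NCAC <- 111.2 * pi / 180
  a_CACN <- 116.2 * pi / 180
  a_CNCA <- 121.7 * pi / 180

  N <- matrix(0, n_residues, 3)
  CA <- matrix(0, n_residues, 3)
  C <- matrix(0, n_residues, 3)
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(1.458, 0, 0)
  C[1, ] <- CA[1, ] + 1.525 * c(-cos(a_NCAC), sin(a_NCAC), 0)
  for (i in seq_len(n_residues - 1)) {
    N[i + 1, ] <- place_atom(N[i, ], CA[i, ], C[i, ], 1.329, a_CACN, psi)
    CA[i + 1, ] <- place_atom(CA[i, ], C[i, ], N[i + 1, ], 1.458, a_CNCA, omega)
    C[i + 1, ] <- place_atom(C[i, ], N[i + 1, ], CA[i + 1, ], 1.525, a_NCAC, phi)
  }
  O <- matrix(0, n_residues, 3)
  for (i in seq_len(n_residues)) {
    if (i < n_residues) {
      # carbonyl O opposite the next N across the peptide plane
      O[i, ] <- place_atom(N[i, ], CA[i, ], C[i, ], 1.229, 120.8 * pi / 180,
                           psi + pi)
    } else {
      O[i, ] <- place_atom(N[i, ], CA[i, ], C[i, ], 1.229, 120.8 * pi / 180,
                           psi)
    }
  }
  CB <- t(vapply(seq_len(n_residues), function(i) {
    virtual_cbeta(N[i, ], CA[i, ], C[i, ])
  }, numeric(3)))
  backbone_structure(
    residue_ids = seq_len(n_residues),
    residue_names = rep("ALA", n_residues),
    coords_N = N, coords_CA = CA, coords_C = C, coords_O = O, coords_CB = CB,
    chain_id = "A",
    cb_is_virtual = rep(FALSE, n_residues)
  )
}

#' Apply a rigid motion to a backbone structure
#'
#' @param structure A [backbone_structure()].
#' @param R 3x3 rotation matrix.
#' @param t Length-3 translation vector.
#' @return The transformed [backbone_structure()].
#' @export
transform_structure <- function(structure, R, t = c(0, 0, 0)) {
  stopifnot(inherits(structure, "backbone_structure"))
  out <- structure
  for (a in c("N", "CA", "C", "O", "CB")) {
    f <- paste0("coords_", a)
    out[[f]] <- sweep(structure[[f]] %*% t(R), 2, -t)
  }
  out
}

#' Parse point-mutation notation
#'
#' Parses strings like `"A39H"` (wild-type Ala at position 39 mutated to
#' His) into a tibble of mutation specifications.
#'
#' @param x Character vector of mutations in `<wild><position><mutant>`
#'   notation; positions are 1-based on the wild-type sequence.
#' @return Tibble with columns `wild_aa`, `position`, `mutant_aa`.
#' @export
parse_mutations <- function(x) {
  x <- trimws(x)
  x <- x[nzchar(x)]
  if (length(x) == 0) {
    return(tibble::tibble(wild_aa = character(), position = integer(),
                          mutant_aa = character()))
  }
  ok <- grepl("^[A-Z][0-9]+[A-Z]$", x)
  if (any(!ok)) {
    stop("malformed mutation spec(s): ", paste(x[!ok], collapse = ", "),
         call. = FALSE)
  }
  wild <- substr(x, 1, 1)
  mut <- substr(x, nchar(x), nchar(x))
  pos <- as.integer(substr(x, 2, nchar(x) - 1))
  alphabet <- names(AA3_FROM_1)
  bad <- !(wild %in% alphabet) | !(mut %in% alphabet)
  if (any(bad)) {
    stop("mutation uses non-standard amino acid: ",
         paste(x[bad], collapse = ", "), call. = FALSE)
  }
  if (any(wild == mut)) {
    stop("mutation does not change the residue: ",
         paste(x[wild == mut], collapse = ", "), call. = FALSE)
  }
  if (any(pos < 1)) stop("mutation positions must be >= 1", call. = FALSE)
  tibble::tibble(wild_aa = wild, position = pos, mutant_aa = mut)
}

#' Apply point mutations to a sequence
#'
#' @param sequence Amino-acid string (1-letter codes).
#' @param mutations Character vector in `"A39H"` notation, or a tibble as
#'   returned by [parse_mutations()].
#' @return The mutated sequence; same length as the input, differing
#'   exactly at the mutated positions.
#' @export
apply_mutations <- function(sequence, mutations) {
  if (is.character(mutations)) mutations <- parse_mutations(mutations)
  if (nrow(mutations) == 0) return(sequence)
  if (anyDuplicated(mutations$position)) {
    stop("duplicate mutation positions: ",
         paste(unique(mutations$position[duplicated(mutations$position)]),
               collapse = ", "), call. = FALSE)
  }
  chars <- strsplit(sequence, "")[[1]]
  if (any(mutations$position > length(chars))) {
    stop("mutation position beyond sequence length ", length(chars),
         call. = FALSE)
  }
  found <- chars[mutations$position]
  bad <- found != mutations$wild_aa
  if (any(bad)) {
    i <- which(bad)[1]
    stop("mutation consistency error at position ", mutations$position[i],
         ": expected ", mutations$wild_aa[i], ", found ", found[i],
         call. = FALSE)
  }
  chars[mutations$position] <- mutations$mutant_aa
  paste(chars, collapse = "")
}
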