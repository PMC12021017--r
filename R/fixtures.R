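# Deterministic fixture generation: toy PDB texts, FASTA maps and raw
# kinetic CSV tables with planted duplicates and invalid rows. The
# manifest records, by construction, exactly what the curation pipeline
# must produce, so tests can compare pipeline output against ground
# truth.

#' Generate a deterministic fixture bundle
#'
#' Creates `n_enzymes` synthetic enzymes (random sequences on ideal
#' helix/strand backbones, serialized to PDB text) and a raw kinetic
#' record table with `n_records` valid base rows (unique identity keys,
#' a share of them mutants with consistent mutation strings) plus
#' planted rows: duplicate-key rows with differing values (the manifest
#' records each group's expected maximum), rows with multi-fragment
#' (".") SMILES, and rows with non-positive values.
#'
#' @param seed Integer seed; identical seeds give identical bundles.
#' @param n_enzymes Enzyme pool size (>= 2).
#' @param n_records Valid base rows (>= n_enzymes).
#' @param parameter `"kcat"` or `"Km"`.
#' @return A `fixture_bundle`: list with `pdb_texts` (enzyme_id -> PDB
#'   text), `fasta` (enzyme_id -> sequence), `raw_csv` (the raw record
#'   tibble, shuffled) and `manifest` (expected post-curation counts and
#'   per-duplicate-group maxima).
#' @export
make_bundle <- function(seed = 1, n_enzymes = 6, n_records = 60,
                        parameter = c("kcat", "Km")) {
  parameter <- match.arg(parameter)
  if (n_enzymes < 2) stop("n_enzymes must be >= 2", call. = FALSE)
  if (n_records < n_enzymes) {
    stop("n_records must be >= n_enzymes", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)

  enzyme_ids <- sprintf("ENZ%02d", seq_len(n_enzymes))
  lens <- sample(18:30, n_enzymes, replace = TRUE)
  styles <- sample(c("helix", "strand"), n_enzymes, replace = TRUE)
  # last EC field indexes the enzyme so identity keys cannot collide
  ecs <- sprintf("%d.%d.%d.%d", sample(1:6, n_enzymes, replace = TRUE),
                 sample(1:20, n_enzymes, replace = TRUE),
                 sample(1:20, n_enzymes, replace = TRUE),
                 seq_len(n_enzymes))
  organisms <- sample(c("Escherichia coli", "Saccharomyces cerevisiae",
                        "Homo sapiens", "Bacillus subtilis"),
                      n_enzymes, replace = TRUE)
  sequences <- vapply(lens, random_sequence, character(1))

  pdb_texts <- list()
  for (i in seq_len(n_enzymes)) {
    strc <- make_helix_fixture(lens[i], styles[i])
    strc$residue_names <- aa_one_to_three(strsplit(sequences[i], "")[[1]])
    strc$sequence <- sequences[i]
    strc$cb_is_virtual <- strc$residue_names == "GLY"
    pdb_texts[[enzyme_ids[i]]] <- write_structure(strc)
  }

  # substrate pool large enough for unique enzyme x substrate base keys
  n_sub <- ceiling(n_records / n_enzymes) + 2
  substrates <- unique(random_smiles(3 * n_sub))[seq_len(n_sub)]
  sub_names <- sprintf("substrate-%02d", seq_along(substrates))

  grid <- expand.grid(ez = seq_len(n_enzymes), su = seq_along(substrates))
  base_idx <- grid[sample.int(nrow(grid), n_records), ]

  mutant_share <- 0.25
  is_mutant <- runif(n_records) < mutant_share
  mutations <- character(n_records)
  seq_out <- sequences[base_idx$ez]
  for (r in which(is_mutant)) {
    sq <- sequences[base_idx$ez[r]]
    pos <- sample.int(nchar(sq), 1)
    wild <- substr(sq, pos, pos)
    mut <- sample(setdiff(SEQ_ALPHABET[1:20], wild), 1)
    mutations[r] <- paste0(wild, pos, mut)
    seq_out[r] <- apply_mutations(sq, mutations[r])
  }

  base <- tibble::tibble(
    enzyme_id = enzyme_ids[base_idx$ez],
    ec_number = ecs[base_idx$ez],
    organism = organisms[base_idx$ez],
    substrate = sub_names[base_idx$su],
    smiles = substrates[base_idx$su],
    cid = sprintf("CID%05d", sample.int(99999, n_records)),
    sequence = seq_out,
    uniprot_id = sprintf("P%05d", base_idx$ez),
    enzyme_type = ifelse(is_mutant, "mutant", "wild-type"),
    mutations = mutations,
    value = round(10^rnorm(n_records, 0, 1), 6),
    unit = if (parameter == "kcat") "s^-1" else "mM",
    parameter = parameter,
    pdb_id = sprintf("%04X", base_idx$ez),
    resolution = ifelse(runif(n_records) < 0.5,
                        round(runif(n_records, 1.2, 3.8), 2), NA)
  )

  # planted duplicate-key rows (2 extras each for k groups)
  k_dup <- max(2L, round(n_records / 8))
  dup_src <- sample.int(n_records, k_dup)
  dups <- base[rep(dup_src, each = 2), , drop = FALSE]
  dups$value <- round(dups$value * rep(runif(2 * k_dup, 0.2, 3)), 6)
  dups$cid <- sprintf("CID%05d", sample.int(99999, nrow(dups)))

  # planted invalid rows
  m_dot <- max(2L, round(n_records / 10))
  p_zero <- max(2L, round(n_records / 10))
  bad_smiles <- base[sample.int(n_records, m_dot, replace = TRUE), ]
  bad_smiles$smiles <- paste0(bad_smiles$smiles, ".O")
  bad_value <- base[sample.int(n_records, p_zero, replace = TRUE), ]
  bad_value$value <- 0

  raw <- dplyr::bind_rows(base, dups, bad_smiles, bad_value)
  raw <- raw[sample.int(nrow(raw)), , drop = FALSE]

  # expected dedup outcome, computed from the planted rows by construction
  valid <- dplyr::bind_rows(base, dups)
  grp_max <- tapply(valid$value, dedup_key(valid), max)
  expected <- tibble::tibble(key = names(grp_max),
                             expected_max = as.numeric(grp_max))
  manifest <- list(
    n_raw = nrow(raw),
    n_base = n_records,
    n_dup_extra = nrow(dups),
    n_invalid_smiles = m_dot,
    n_nonpositive = p_zero,
    n_after_clean = n_records + nrow(dups),
    n_unique_keys = n_records,
    expected_dedup = expected,
    parameter = parameter,
    seed = seed
  )
  out <- list(pdb_texts = pdb_texts,
              fasta = as.list(setNames(sequences, enzyme_ids)),
              raw_csv = raw,
              manifest = manifest)
  class(out) <- "fixture_bundle"
  out
}

#' @export
print.fixture_bundle <- function(x, ...) {
  cat("<fixture_bundle>", length(x$pdb_texts), "enzymes,",
      nrow(x$raw_csv), "raw records (",
      x$manifest$n_unique_keys, "unique keys )\n")
  invisible(x)
}

#' Write a fixture bundle to disk
#'
#' Writes the PDB texts, a FASTA file and the raw CSV under `dir`.
#'
#' @param bundle A [make_bundle()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (id in names(bundle$pdb_texts)) {
    writeLines(bundle$pdb_texts[[id]], file.path(dir, paste0(id, ".pdb")))
  }
  fasta <- unlist(lapply(names(bundle$fasta), function(id) {
    c(paste0(">", id), bundle$fasta[[id]])
  }))
  writeLines(fasta, file.path(dir, "sequences.fasta"))
  utils::write.csv(bundle$raw_csv, file.path(dir, "raw_records.csv"),
                   row.names = FALSE)
  invisible(dir)
}
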