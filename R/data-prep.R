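# Curation pipeline for kinetic records: validity filtering,
# deduplication with maximum-value retention, unit normalization and
# log10 transform, global-alignment identity, PDB chain selection,
# resolution filtering, seeded splitting and similarity binning.
#
# Records travel as tibbles with columns: ec_number, organism, substrate,
# smiles, cid, sequence, uniprot_id, enzyme_type ("wild-type"/"mutant"),
# mutations (";"-separated "A39H" notation), value, unit, parameter
# ("kcat"/"Km"), pdb_id, resolution.

RECORD_KEY_COLS <- c("ec_number", "organism", "substrate", "smiles",
                     "sequence", "enzyme_type", "value", "parameter")

canonical_mutations <- function(mutations) {
  vapply(mutations, function(m) {
    if (is.na(m) || !nzchar(trimws(m))) return("")
    parts <- trimws(strsplit(m, "[;,]")[[1]])
    parts <- parts[nzchar(parts)]
    paste(sort(unique(toupper(parts))), collapse = ";")
  }, character(1), USE.NAMES = FALSE)
}

#' Filter raw kinetic records down to valid entries
#'
#' Keeps only complete entries with valid values: drops rows with
#' missing key fields, non-positive kinetic values, multi-fragment
#' SMILES (containing "."), or mutant rows without mutation
#' information. Drop counts per reason are recorded in the
#' `drop_counts` attribute and reported via a message.
#'
#' @param raw Tibble/data.frame of raw records with at least the columns
#'   ec_number, organism, substrate, smiles, sequence, enzyme_type,
#'   value, parameter.
#' @return Tibble of retained records (a `mutations` column is
#'   normalized to canonical ";"-separated form).
#' @export
clean_records <- function(raw) {
  missing_cols <- setdiff(RECORD_KEY_COLS, names(raw))
  if (length(missing_cols) > 0) {
    stop("raw records lack mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  raw <- tibble::as_tibble(raw)
  if (!"mutations" %in% names(raw)) raw$mutations <- ""
  raw$mutations[is.na(raw$mutations)] <- ""
  raw$mutations <- canonical_mutations(raw$mutations)

  key_missing <- Reduce(`|`, lapply(
    c("ec_number", "organism", "substrate", "smiles", "sequence",
      "enzyme_type", "parameter"),
    function(cl) is.na(raw[[cl]]) | !nzchar(trimws(as.character(raw[[cl]])))
  ))
  key_missing <- key_missing | is.na(raw$value)
  nonpositive <- !key_missing & raw$value <= 0
  dotted <- !key_missing & !nonpositive &
    grepl(".", raw$smiles, fixed = TRUE)
  bad_mutant <- !key_missing & !nonpositive & !dotted &
    raw$enzyme_type == "mutant" & !nzchar(raw$mutations)

  drop_counts <- c(missing_field = sum(key_missing),
                   nonpositive_value = sum(nonpositive),
                   multifragment_smiles = sum(dotted),
                   mutant_without_mutations = sum(bad_mutant))
  keep <- !(key_missing | nonpositive | dotted | bad_mutant)
  message("clean_records: dropped ", sum(!keep), "/", nrow(raw),
          " rows (missing field ", drop_counts[["missing_field"]],
          ", value <= 0 ", drop_counts[["nonpositive_value"]],
          ", '.' in SMILES ", drop_counts[["multifragment_smiles"]],
          ", mutant w/o mutations ",
          drop_counts[["mutant_without_mutations"]], ")")
  out <- raw[keep, , drop = FALSE]
  attr(out, "drop_counts") <- drop_counts
  out
}

dedup_key <- function(records) {
  paste(records$ec_number, records$substrate, records$enzyme_type,
        records$mutations, records$organism, sep = "\r")
}

#' Deduplicate records, keeping the maximum value per identity key
#'
#' Groups records by (EC number, substrate, enzyme type + canonical
#' mutation set, organism) and keeps, per group, one record carrying the
#' group's maximum kinetic value. Output order is deterministic (sorted
#' by key).
#'
#' @param records Cleaned record tibble.
#' @return Deduplicated tibble with one row per identity key.
#' @export
deduplicate <- function(records) {
  if (nrow(records) == 0) return(records)
  records$mutations <- canonical_mutations(records$mutations)
  key <- dedup_key(records)
  keep <- unlist(lapply(split(seq_len(nrow(records)), key), function(idx) {
    idx[which.max(records$value[idx])]
  }), use.names = FALSE)
  out <- records[keep, , drop = FALSE]
  out[order(dedup_key(out)), , drop = FALSE]
}

# canonical-unit conversion factors
UNIT_FACTORS <- list(
  kcat = c("s^-1" = 1, "1/s" = 1, "s-1" = 1,
           "min^-1" = 1 / 60, "1/min" = 1 / 60,
           "h^-1" = 1 / 3600, "1/h" = 1 / 3600),
  Km = c("mM" = 1, "M" = 1000, "uM" = 1e-3, "µM" = 1e-3, "nM" = 1e-6)
)

#' Convert a kinetic value to log10 scale
#'
#' Normalizes the unit to the canonical one (kcat to 1/s, Km to mM) and
#' takes log10.
#'
#' @param value Positive kinetic value(s).
#' @param parameter `"kcat"` or `"Km"`.
#' @param unit Unit string; defaults to the canonical unit.
#' @return log10 of the unit-normalized value.
#' @export
to_log_scale <- function(value, parameter = c("kcat", "Km"), unit = NULL) {
  parameter <- match.arg(parameter)
  if (any(!is.finite(value)) || any(value <= 0)) {
    stop("kinetic values must be positive to take log10", call. = FALSE)
  }
  factors <- UNIT_FACTORS[[parameter]]
  if (is.null(unit)) unit <- names(factors)[1]
  f <- factors[unit]
  if (any(is.na(f))) {
    stop("unknown unit(s) for ", parameter, ": ",
         paste(unique(unit[is.na(f)]), collapse = ", "), call. = FALSE)
  }
  log10(value * unname(f))
}

#' Global-alignment percentage identity between two sequences
#'
#' Needleman-Wunsch global alignment (BLOSUM62, gap opening 10, gap
#' extension 0.5); identity is the number of matched positions divided
#' by the alignment length (gaps count against identity), times 100.
#'
#' @param seq_a,seq_b Non-empty amino-acid strings.
#' @return Percentage identity in [0, 100]; symmetric in its arguments.
#' @export
pairwise_identity <- function(seq_a, seq_b) {
  if (!nzchar(seq_a) || !nzchar(seq_b)) {
    stop("sequences must be non-empty", call. = FALSE)
  }
  aln <- Biostrings::pairwiseAlignment(
    seq_a, seq_b, type = "global",
    substitutionMatrix = blosum62_matrix(),
    gapOpening = 10, gapExtension = 0.5
  )
  width <- nchar(as.character(Biostrings::alignedPattern(aln)))
  100 * Biostrings::nmatch(aln) / width
}

blosum62_env <- new.env()
blosum62_matrix <- function() {
  if (is.null(blosum62_env$m)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    blosum62_env$m <- e$BLOSUM62
  }
  blosum62_env$m
}

#' Select the PDB chain matching a target sequence
#'
#' Computes global-alignment identity between the target sequence and
#' every candidate chain, and returns the best candidate when its
#' identity exceeds 90% (ties broken lexicographically by pdb_id, then
#' chain); otherwise returns NULL and the caller falls back to a
#' predicted structure.
#'
#' @param target_seq Target (UniProt) sequence.
#' @param candidates Tibble with columns `pdb_id`, `chain`, `sequence`.
#' @param threshold Identity threshold (percent, strict; default 90).
#' @return One-row tibble (pdb_id, chain, identity) or NULL.
#' @export
select_pdb <- function(target_seq, candidates, threshold = 90) {
  if (nrow(candidates) == 0) return(NULL)
  if (any(!nzchar(candidates$sequence))) {
    stop("candidate sequences must be non-empty", call. = FALSE)
  }
  ident <- vapply(candidates$sequence, function(s) {
    pairwise_identity(target_seq, s)
  }, numeric(1), USE.NAMES = FALSE)
  ord <- order(-ident, candidates$pdb_id, candidates$chain)
  best <- ord[1]
  if (ident[best] <= threshold) return(NULL)
  tibble::tibble(pdb_id = candidates$pdb_id[best],
                 chain = candidates$chain[best],
                 identity = ident[best])
}

#' Filter records by experimental structure resolution
#'
#' Drops records whose experimental structure resolution exceeds
#' `max_resolution` (Angstrom). Records without a resolution (predicted
#' structures) pass.
#'
#' @param records Record tibble with an optional `resolution` column.
#' @param max_resolution Cutoff in Angstrom (default 3.0).
#' @return Filtered tibble.
#' @export
filter_resolution <- function(records, max_resolution = 3.0) {
  if (!"resolution" %in% names(records)) return(records)
  keep <- is.na(records$resolution) | records$resolution <= max_resolution
  records[keep, , drop = FALSE]
}

#' Seeded train/validation/test split
#'
#' Uniform seeded shuffle followed by a contiguous 80/10/10 cut; sizes
#' are floored and remainders assigned to train, then validation.
#'
#' @param records Record tibble (>= 10 rows).
#' @param seed Integer seed.
#' @param fractions Named fractions (train, val, test) summing to 1.
#' @return Tibble with columns `row` (input row index) and `split`
#'   (factor train/val/test); the seed is attached as an attribute.
#' @export
split_dataset <- function(records, seed,
                          fractions = c(train = 0.8, val = 0.1, test = 0.1)) {
  n <- nrow(records)
  if (n < 10) stop("need at least 10 records to split", call. = FALSE)
  sizes <- floor(fractions * n)
  rem <- n - sum(sizes)
  for (nm in c("train", "val", "test")) {
    if (rem == 0) break
    sizes[nm] <- sizes[nm] + 1
    rem <- rem - 1
  }
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  perm <- sample.int(n)
  split <- rep(c("train", "val", "test"), times = sizes[c("train", "val", "test")])
  out <- tibble::tibble(row = perm,
                        split = factor(split, levels = c("train", "val", "test")))
  out <- out[order(out$row), , drop = FALSE]
  attr(out, "seed") <- seed
  out
}

SIMILARITY_BIN_LEVELS <- c("0-40%", "40-80%", "80-99%", "99-100%")

#' Bin test sequences by maximum identity to the training set
#'
#' For each test sequence, computes the maximum [pairwise_identity()]
#' against all training sequences and bins it into [0,40), [40,80),
#' [80,99), [99,100] percent.
#'
#' @param test_seqs,train_seqs Character vectors of sequences.
#' @return Tibble with columns `sequence`, `max_identity` and `bin`
#'   (factor with the four similarity levels).
#' @export
similarity_bins <- function(test_seqs, train_seqs) {
  if (length(train_seqs) == 0) {
    stop("training set is empty", call. = FALSE)
  }
  max_id <- vapply(test_seqs, function(ts) {
    max(vapply(train_seqs, function(tr) pairwise_identity(ts, tr),
               numeric(1)))
  }, numeric(1), USE.NAMES = FALSE)
  bin <- cut(max_id, breaks = c(0, 40, 80, 99, 100.000001),
             labels = SIMILARITY_BIN_LEVELS,
             right = FALSE, include.lowest = TRUE)
  tibble::tibble(sequence = test_seqs, max_identity = max_id, bin = bin)
}

#' Label preferred vs alternative substrates for promiscuous enzymes
#'
#' Within each enzyme group (EC number, organism, enzyme type +
#' mutations) measured against two or more substrates, the substrate
#' with the maximum kcat (or minimum Km) is labelled `preferred`, the
#' rest `alternative`. Ties resolve to the lexicographically smallest
#' substrate name. Singleton groups are skipped with a warning.
#'
#' @param records Record tibble; all rows must share one `parameter`.
#' @return Input tibble restricted to groups of size >= 2, with an added
#'   `substrate_label` column.
#' @export
preferred_substrate <- function(records) {
  param <- unique(records$parameter)
  if (length(param) != 1) {
    stop("records mix parameters; label one parameter at a time",
         call. = FALSE)
  }
  grp <- paste(records$ec_number, records$organism, records$enzyme_type,
               canonical_mutations(records$mutations), sep = "\r")
  idx_by_grp <- split(seq_len(nrow(records)), grp)
  singleton <- vapply(idx_by_grp, function(idx) {
    length(unique(records$substrate[idx])) < 2
  }, logical(1))
  if (any(singleton)) {
    warning(sum(singleton), " enzyme group(s) with a single substrate ",
            "skipped", call. = FALSE)
  }
  keep_rows <- unlist(idx_by_grp[!singleton], use.names = FALSE)
  out <- records[keep_rows, , drop = FALSE]
  grp <- grp[keep_rows]
  label <- rep("alternative", nrow(out))
  for (idx in split(seq_len(nrow(out)), grp)) {
    vals <- out$value[idx]
    score <- if (param == "Km") -vals else vals
    best <- max(score)
    cand <- idx[score == best]
    winner <- cand[order(out$substrate[cand])][1]
    label[winner] <- "preferred"
  }
  out$substrate_label <- label
  out
}
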