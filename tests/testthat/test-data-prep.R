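make_raw <- function(...) {
  defaults <- list(ec_number = "1.1.1.1", organism = "Escherichia coli",
                   substrate = "glucose", smiles = "CCO",
                   sequence = "MKVLA", enzyme_type = "wild-type",
                   mutations = "", value = 1.5, unit = "s^-1",
                   parameter = "kcat")
  rows <- list(...)
  dplyr::bind_rows(lapply(rows, function(r) {
    tibble::as_tibble(utils::modifyList(defaults, r))
  }))
}

test_that("clean_records drops exactly the invalid rows", {
  raw <- make_raw(
    list(),                                  # valid
    list(value = 0),                         # non-positive
    list(smiles = "CC.O"),                   # multi-fragment
    list(ec_number = NA_character_),         # missing key field
    list(enzyme_type = "mutant", mutations = "K2R"),  # valid mutant
    list(enzyme_type = "mutant")             # mutant without mutations
  )
  expect_message(cleaned <- clean_records(raw), "dropped 4/6")
  expect_equal(nrow(cleaned), 2)
  counts <- attr(cleaned, "drop_counts")
  expect_equal(unname(counts["nonpositive_value"]), 1)
  expect_equal(unname(counts["multifragment_smiles"]), 1)
  expect_equal(unname(counts["missing_field"]), 1)
  expect_equal(unname(counts["mutant_without_mutations"]), 1)
  expect_error(clean_records(raw[, -1]), "mandatory column")
})

test_that("deduplicate keeps the max value per identity key", {
  raw <- make_raw(
    list(value = 1.0), list(value = 5.0), list(value = 3.0),
    list(value = 2.0, organism = "Homo sapiens"),
    list(value = 9.9, enzyme_type = "mutant", mutations = "K2R"),
    list(value = 0.1, enzyme_type = "mutant", mutations = "L4A")
  )
  out <- deduplicate(raw)
  # 3 same-key rows collapse to the max; distinct organism and distinct
  # mutants are separate keys
  expect_equal(nrow(out), 4)
  wt_ecoli <- out[out$organism == "Escherichia coli" &
                    out$enzyme_type == "wild-type", ]
  expect_equal(wt_ecoli$value, 5.0)
  expect_equal(sort(out$value), c(0.1, 2.0, 5.0, 9.9))

  # brute-force group-by oracle on a random instance
  set.seed(2)
  rnd <- do.call(make_raw, lapply(1:40, function(i) {
    list(substrate = sample(c("s1", "s2", "s3"), 1),
         organism = sample(c("o1", "o2"), 1),
         value = round(runif(1, 0.1, 9), 3))
  }))
  out2 <- deduplicate(rnd)
  oracle <- tapply(rnd$value,
                   paste(rnd$substrate, rnd$organism), max)
  expect_equal(nrow(out2), length(oracle))
  expect_equal(sort(out2$value), sort(as.numeric(oracle)))
  # mutation strings canonicalize: order and case insensitive
  dup_mut <- make_raw(
    list(enzyme_type = "mutant", mutations = "K2R;L4A", value = 1),
    list(enzyme_type = "mutant", mutations = "l4a; k2r", value = 7)
  )
  out3 <- deduplicate(dup_mut)
  expect_equal(nrow(out3), 1)
  expect_equal(out3$value, 7)
})

test_that("log-scale conversion normalizes units first", {
  expect_equal(to_log_scale(1.0, "kcat"), 0.0)
  expect_equal(to_log_scale(100.0, "kcat"), 2.0)
  expect_equal(to_log_scale(60, "kcat", unit = "min^-1"), 0.0)
  expect_equal(to_log_scale(1000, "Km", unit = "uM"), 0.0)
  expect_error(to_log_scale(0.0, "kcat"), "positive")
  expect_error(to_log_scale(1, "Km", unit = "furlongs"), "unknown unit")
})

test_that("pairwise identity reproduces alignment worked examples", {
  expect_equal(pairwise_identity("ACDEFG", "ACDEFG"), 100.0)
  expect_equal(pairwise_identity("AAAA", "TTTT"), 0.0)
  expect_equal(pairwise_identity("ACDEFG", "ACDEYG"), 100 * 5 / 6,
               tolerance = 1e-9)
  expect_equal(pairwise_identity("ACDEFG", "ACDEYG"),
               pairwise_identity("ACDEYG", "ACDEFG"))
  expect_error(pairwise_identity("", "AA"), "non-empty")
})

test_that("select_pdb picks the best chain above the 90% threshold", {
  target <- "MKVLAWGHKL"
  cands <- tibble::tibble(
    pdb_id = c("1ABC", "2DEF", "3GHI"),
    chain = c("A", "A", "B"),
    sequence = c("MKVLAWGHKL",          # 100%
                 "MKVLAWGHKV",          # 90% (not > 90)
                 "MKVAAWGHKL")          # 90%
  )
  hit <- select_pdb(target, cands)
  expect_equal(hit$pdb_id, "1ABC")
  expect_equal(hit$identity, 100)
  # all candidates at or below 90: none selected
  expect_null(select_pdb(target, cands[2:3, ]))
  expect_null(select_pdb(target, cands[0, ]))
  # tie above threshold resolves lexicographically
  tie <- tibble::tibble(pdb_id = c("9ZZZ", "1AAA"), chain = c("A", "A"),
                        sequence = c(target, target))
  expect_equal(select_pdb(target, tie)$pdb_id, "1AAA")
})

test_that("resolution filter drops only poor experimental structures", {
  recs <- tibble::tibble(id = 1:3, resolution = c(2.1, 3.5, NA))
  out <- filter_resolution(recs)
  expect_equal(out$id, c(1, 3))
  # boundary: exactly 3.0 retained
  expect_equal(nrow(filter_resolution(tibble::tibble(resolution = 3.0))), 1)
})

test_that("split_dataset partitions with the floor-then-train rule", {
  recs <- tibble::tibble(id = 1:100)
  sp <- split_dataset(recs, seed = 4)
  expect_equal(unname(table(sp$split)), c(80, 10, 10), ignore_attr = TRUE)
  expect_identical(sp, split_dataset(recs, seed = 4))
  expect_false(identical(sp$split, split_dataset(recs, seed = 5)$split))
  # partition property
  expect_setequal(sp$row, 1:100)

  sp13 <- split_dataset(tibble::tibble(id = 1:13), seed = 1)
  expect_equal(unname(table(sp13$split)), c(11, 1, 1), ignore_attr = TRUE)
  expect_error(split_dataset(tibble::tibble(id = 1:5), seed = 1),
               "at least 10")
})

test_that("similarity bins follow the boundary conventions", {
  train <- c("AAAAAAAAAA", "ACDEFGHIKL")
  # identical sequence -> 99-100%
  bins <- similarity_bins(c("ACDEFGHIKL"), train)
  expect_equal(as.character(bins$bin), "99-100%")
  expect_equal(bins$max_identity, 100)
  # constructed max identity 50% -> 40-80%; exactly 40 -> 40-80%
  half <- similarity_bins("ACDEFWWWWW", train)   # 5/10 vs train[2]
  expect_equal(half$max_identity, 50)
  expect_equal(as.character(half$bin), "40-80%")
  forty <- similarity_bins("ACDEWWWWWW", train)  # 4/10
  expect_equal(forty$max_identity, 40)
  expect_equal(as.character(forty$bin), "40-80%")
  expect_error(similarity_bins("AAAA", character(0)), "empty")
  # binning covers [0, 100]: no NA for any identity
  probe <- similarity_bins(c("WWWWWWWWWW", "AAAAAWWWWW"), train)
  expect_false(any(is.na(probe$bin)))
})

test_that("preferred substrates take max kcat or min Km deterministically", {
  kcat <- make_raw(
    list(substrate = "S1", smiles = "CC", value = 2.0),
    list(substrate = "S2", smiles = "CCC", value = 5.0)
  )
  out <- preferred_substrate(kcat)
  expect_equal(out$substrate_label[out$substrate == "S2"], "preferred")
  expect_equal(out$substrate_label[out$substrate == "S1"], "alternative")

  km <- make_raw(
    list(substrate = "S1", smiles = "CC", value = 0.1, parameter = "Km",
         unit = "mM"),
    list(substrate = "S2", smiles = "CCC", value = 0.5, parameter = "Km",
         unit = "mM")
  )
  out_km <- preferred_substrate(km)
  expect_equal(out_km$substrate_label[out_km$substrate == "S1"], "preferred")

  # tie resolves to the lexicographically smallest substrate name
  tie <- make_raw(
    list(substrate = "B", value = 3), list(substrate = "A", value = 3)
  )
  out_tie <- preferred_substrate(tie)
  expect_equal(out_tie$substrate_label[out_tie$substrate == "A"], "preferred")

  # singleton group skipped with warning
  mixed <- make_raw(
    list(substrate = "S1", value = 1),
    list(substrate = "S2", value = 2),
    list(substrate = "S9", organism = "Homo sapiens", value = 3)
  )
  expect_warning(out_m <- preferred_substrate(mixed), "single substrate")
  expect_equal(nrow(out_m), 2)
  expect_equal(sum(out_m$substrate_label == "preferred"), 1)
})
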