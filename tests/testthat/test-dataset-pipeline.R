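make_csv <- function(df, sep = ",") {
  path <- tempfile(fileext = if (sep == ",") ".csv" else ".tsv")
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  path
}

test_that("load_records parses CSV/TSV, honours column maps, rejects bad rows", {
  df <- data.frame(epitope = c("SIINFEKL", "XYZ123", "GILGFVFTL"),
                   tcr = c("CASSLG", "CASSAR", "CASSQE"),
                   label = c(1, 1, 0))
  expect_message(recs <- load_records(make_csv(df)), "1 invalid")
  expect_identical(nrow(recs), 2L)  # the row with digits is dropped
  expect_identical(recs$tcr_id, recs$tcr)

  # reordered TSV with custom column names parses to the same records
  df2 <- data.frame(bind = c(1, 0), cdr3 = c("CASSLG", "CASSQE"),
                    antigen = c("SIINFEKL", "GILGFVFTL"))
  recs2 <- load_records(make_csv(df2, "\t"), format = "tsv",
                        column_map = c(epitope = "antigen", tcr = "cdr3",
                                       label = "bind"))
  expect_identical(recs2[c("epitope", "tcr", "label")],
                   recs[c("epitope", "tcr", "label")])

  expect_error(load_records(make_csv(df), column_map = c(epitope = "nope",
                                                         tcr = "tcr", label = "label")),
               "absent")
  allbad <- data.frame(epitope = "123", tcr = "456", label = 1)
  expect_error(suppressMessages(load_records(make_csv(allbad))), "no valid rows")
})

test_that("curation enforces the min/max TCRs-per-epitope window", {
  set.seed(3)
  mk <- function(epi, n) data.frame(
    epitope = epi, tcr = vapply(seq_len(n), function(i) random_peptide(12), ""),
    label = 1, stringsAsFactors = FALSE)
  recs <- rbind(mk("AAAAAAAAA", 14),   # below min -> removed entirely
                mk("CCCCCCCCC", 15),   # at min -> kept whole
                mk("DDDDDDDDD", 600))  # above max -> downsampled to 400
  out <- curate_dataset(recs, curation_config(15, 400, rng_seed = 9))
  tab <- table(out$epitope)
  expect_false("AAAAAAAAA" %in% names(tab))
  expect_identical(as.integer(tab[["CCCCCCCCC"]]), 15L)
  expect_identical(as.integer(tab[["DDDDDDDDD"]]), 400L)
  # idempotent: curating the curated set changes nothing
  expect_identical(curate_dataset(out, curation_config(15, 400, rng_seed = 9)), out)
  # deterministic under the seed
  expect_identical(out, curate_dataset(recs, curation_config(15, 400, rng_seed = 9)))
  # duplicated TCRs within an epitope collapse before counting
  dup <- mk("EEEEEEEEE", 10)
  dup <- rbind(dup, dup)  # every TCR twice
  expect_error(curate_dataset(dup, curation_config(15, 400)), "census")
})

test_that("negative generation balances labels without colliding with positives", {
  set.seed(4)
  pos <- data.frame(
    epitope = rep(vapply(1:5, function(i) random_peptide(9), ""), each = 2),
    tcr = vapply(1:10, function(i) random_peptide(13), ""),
    label = 1, stringsAsFactors = FALSE)
  out <- generate_negatives(pos, rng_seed = 5)
  expect_identical(nrow(out), 20L)
  expect_identical(sum(out$label == 0), 10L)
  expect_identical(sum(out$label == 1), 10L)
  pos_keys <- paste(pos$epitope, pos$tcr)
  neg <- out[out$label == 0, ]
  expect_false(any(paste(neg$epitope, neg$tcr) %in% pos_keys))
  # each TCR gains exactly as many negatives as it has positives
  expect_identical(table(neg$tcr_id), table(out$tcr_id[out$label == 1]))
  # determinism
  expect_identical(out, generate_negatives(pos, rng_seed = 5))
  # single epitope in scope: no admissible negative exists
  single <- pos[pos$epitope == pos$epitope[1], ]
  expect_warning(res <- generate_negatives(single, rng_seed = 5), "omitted")
  expect_identical(sum(res$label == 0), 0L)
})

test_that("fold assignment keeps TCRs (and epitopes, strictly) disjoint", {
  set.seed(6)
  bench <- generate_benchmark(synthetic_config(n_epitopes = 12,
                                               tcrs_per_epitope = 20,
                                               rng_seed = 61))
  pos <- bench$records[bench$records$label == 1, ]
  # some TCRs appear under two epitopes to exercise strict conflict handling
  cross <- pos[1:10, ]
  cross$epitope <- pos$epitope[match(setdiff(unique(pos$epitope),
                                             cross$epitope), pos$epitope)][1]
  pos2 <- rbind(pos, cross)

  fa <- make_folds(pos2, 4, "tcr_split", rng_seed = 7)
  d <- apply_folds(pos2, fa)
  expect_identical(nrow(d), nrow(pos2))  # nothing dropped
  per_tcr <- tapply(d$fold, d$tcr_id, function(f) length(unique(f)))
  expect_true(all(per_tcr == 1L))

  fa2 <- suppressMessages(make_folds(pos2, 4, "strict_split", rng_seed = 7))
  d2 <- apply_folds(pos2, fa2)
  for (f in 1:3) for (g in (f + 1):4) {
    expect_length(intersect(d2$epitope[d2$fold == f], d2$epitope[d2$fold == g]), 0)
    expect_length(intersect(d2$tcr_id[d2$fold == f], d2$tcr_id[d2$fold == g]), 0)
  }
  # greedy balancing keeps folds within a reasonable band
  sizes <- table(d2$fold)
  expect_lt(max(sizes) / min(sizes), 1.5)

  # single fold puts every record in fold 1
  fa3 <- make_folds(pos, 1, "tcr_split", rng_seed = 1)
  expect_true(all(fa3$fold_of == 1L))
  expect_error(make_folds(pos, 100, "strict_split", rng_seed = 1), "epitopes")
})

test_that("within-fold negatives preserve strict disjointness", {
  bench <- generate_benchmark(synthetic_config(n_epitopes = 10,
                                               tcrs_per_epitope = 18,
                                               rng_seed = 8))
  pos <- bench$records[bench$records$label == 1, ]
  fa <- suppressMessages(make_folds(pos, 3, "strict_split", rng_seed = 9))
  d <- apply_folds(pos, fa)
  full <- generate_negatives(d[, c("epitope", "tcr", "label", "tcr_id")],
                             scope = d$fold, rng_seed = 10)
  expect_identical(sum(full$label == 0), sum(full$label == 1))
  for (f in unique(full$fold)) {
    others <- full[full$fold != f, ]
    expect_length(intersect(full$epitope[full$fold == f], others$epitope), 0)
    expect_length(intersect(full$tcr_id[full$fold == f], others$tcr_id), 0)
  }
})

test_that("CPI preprocessing filters lengths, balances and splits 90/10", {
  set.seed(12)
  pairs <- data.frame(
    smiles = c(rep("CCO", 50), rep("CC(=O)NC", 49),
               paste(rep("C", 251), collapse = "")),   # 251 tokens: dropped
    protein = c(vapply(1:99, function(i) random_peptide(30), ""),
                random_peptide(40)),
    stringsAsFactors = FALSE)
  pairs$protein[50] <- random_peptide(1029)            # too long: dropped
  out <- preprocess_cpi(pairs, rng_seed = 13)
  all_rows <- rbind(out$train, out$validation)
  expect_identical(nrow(all_rows), 196L)               # 98 kept pairs, doubled
  expect_identical(sum(all_rows$label == 1), 98L)
  expect_identical(nrow(out$train), 176L)              # floor(0.9 * 196)
  expect_identical(nrow(out$validation), 20L)
  expect_true(all(nchar(all_rows$protein) <= 1028))
  expect_error(preprocess_cpi(pairs[0, ]), "empty")
})

test_that("curated datasets round-trip through the CSV writer", {
  bench <- generate_benchmark(synthetic_config(n_epitopes = 5,
                                               tcrs_per_epitope = 8,
                                               rng_seed = 14))
  path <- tempfile(fileext = ".csv")
  write_records(bench$records, path, rng_seed = 14)
  back <- load_records(path, column_map = c(epitope = "epitope", tcr = "tcr",
                                            label = "label", tcr_id = "tcr_id"))
  expect_identical(back[c("epitope", "tcr", "label")],
                   bench$records[c("epitope", "tcr", "label")])
  side <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(side$n_records, nrow(bench$records))
  expect_equal(side$rng_seed, 14)
})
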