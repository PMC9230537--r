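test_that("RBP keyword pattern accepts the documented variants and rejects bare words", {
  pass <- c("tailspike", "tail spike", "tail-fiber", "receptor-binding protein")
  fail <- c("spike", "tail protein", "binding protein")
  expect_true(all(match_rbp_annotation(pass)))
  expect_false(any(match_rbp_annotation(fail)))
  # case-insensitive, embedded in longer products, spelling variants
  expect_true(match_rbp_annotation("Putative Tail Fibre Protein"))
  expect_true(match_rbp_annotation("phage receptor recognizing protein"))
  expect_false(match_rbp_annotation(""))
})

test_that("exclusion keyword rules are substring and case-insensitive", {
  expect_true(is_excluded_rbp("tail fiber assembly protein"))
  expect_true(is_excluded_rbp("tail-fiber hinge connector"))
  expect_false(is_excluded_rbp("tail fiber protein"))
  expect_true(is_excluded_other("hypothetical protein"))
  expect_true(is_excluded_other("Putative holin"))
  expect_false(is_excluded_other("major capsid protein"))
})

test_that("quality filters enforce length windows and the canonical alphabet", {
  mk <- function(n) strrep("A", n)
  expect_equal(quality_filter_reason(mk(199), "RBP"), "length")
  expect_equal(quality_filter_reason(mk(200), "RBP"), "ok")
  expect_equal(quality_filter_reason(mk(1500), "RBP"), "ok")
  expect_equal(quality_filter_reason(mk(1501), "RBP"), "length")
  expect_equal(quality_filter_reason(mk(29), "Other"), "length")
  expect_equal(quality_filter_reason(mk(30), "Other"), "ok")
  expect_equal(quality_filter_reason(paste0(mk(499), "X"), "Other"), "unknown_aa")
  # trailing stop is tolerated, internal stop is not
  expect_true(passes_quality_filters(paste0(mk(300), "*"), "RBP"))
  expect_false(passes_quality_filters(paste0(mk(150), "*", mk(150)), "RBP"))
})

test_that("deduplication collapses within groups and removes cross-group pairs from both", {
  df <- function(seqs) data.frame(sequence = seqs, stringsAsFactors = FALSE)
  r <- deduplicate(df(c("AAA", "AAA", "CCC")), df("DDD"))
  expect_equal(r$rbps$sequence, c("AAA", "CCC"))
  expect_equal(r$others$sequence, "DDD")
  expect_equal(unname(r$removed["dup_within_rbp"]), 1L)

  r <- deduplicate(df("AAA"), df(c("AAA", "CCC")))
  expect_equal(nrow(r$rbps), 0L)
  expect_equal(r$others$sequence, "CCC")
  expect_equal(unname(r$removed["dup_cross"]), 2L)

  r <- deduplicate(df(character()), df(character()))
  expect_equal(nrow(r$rbps), 0L)
  expect_equal(nrow(r$others), 0L)
})

test_that("date split is inclusive of the cutoff month", {
  d <- as.Date(c("2021-08-15", "2021-10-01", "2021-09-30", "2021-09-01"))
  expect_equal(split_by_date(d, "2021-09"), c("train", "test", "train", "train"))
  expect_error(split_by_date(as.Date(c("2021-08-01", NA)), "2021-09"),
               "unparseable")
  expect_error(suppressWarnings(split_by_date(Sys.Date(), "September-2021")))
})

test_that("Other subsampling is sized ratio*n_rbp, seeded, and bounded by the pool", {
  pool <- data.frame(sequence = replicate(100, random_aa_seq(30)),
                     stringsAsFactors = FALSE)
  s1 <- subsample_others(pool, n_rbp = 5, ratio = 10, seed = 7)
  expect_equal(nrow(s1), 50L)
  s2 <- subsample_others(pool, n_rbp = 5, ratio = 10, seed = 7)
  expect_identical(s1, s2)
  s3 <- subsample_others(pool, n_rbp = 5, ratio = 10, seed = 8)
  expect_false(identical(s1$sequence, s3$sequence))
  expect_equal(nrow(subsample_others(pool, 5, ratio = 0)), 0L)
  expect_error(subsample_others(pool, 50, ratio = 10), "exceeds")
})

test_that("curation of a known fixture yields the planned group sizes and ledger", {
  fx <- gen_genbank(n_cds = 200, dir = withr::local_tempdir(), seed = 11)
  ds <- curate_dataset(fx$paths, cutoff = "2021-09", ratio = 10, seed = 42)
  ec <- fx$expected_counts
  expect_equal(nrow(ds$rbps), unname(ec["retained_rbps"]))
  expect_equal(nrow(ds$others), unname(ec["retained_others"]))
  led <- setNames(ds$ledger$removed, ds$ledger$step)
  for (step in setdiff(names(ec), c("retained_rbps", "retained_others", "n_cds"))) {
    expect_equal(unname(led[step]), unname(ec[step]), label = step)
  }
  # conservation: every input CDS is retained or accounted for in the ledger
  expect_equal(unname(ec["n_cds"]),
               nrow(ds$rbps) + nrow(ds$others) + sum(ds$ledger$removed))
  # split agrees with the truth table for retained RBPs
  truth_split <- setNames(fx$truth$split_expected, fx$truth$protein_id)
  expect_equal(ds$rbps$split, unname(truth_split[ds$rbps$protein_id]))
})

test_that("curation is idempotent on its own output", {
  fx <- gen_genbank(n_cds = 150, dir = withr::local_tempdir(), seed = 3)
  ds <- curate_dataset(fx$paths, ratio = 10, seed = 42)
  again <- curate_records(rbind(ds$rbps[names(ds$rbps) != "split"],
                                ds$others[names(ds$others) != "split"]),
                          ratio = 10, seed = 42)
  expect_equal(nrow(again$rbps), nrow(ds$rbps))
  expect_equal(nrow(again$others), nrow(ds$others))
  expect_equal(sum(again$ledger$removed), 0L)
  expect_setequal(again$rbps$sequence, ds$rbps$sequence)
  expect_setequal(again$others$sequence, ds$others$sequence)
})

test_that("train/test partition disjointly covers all retained sequences", {
  fx <- gen_genbank(n_cds = 100, dir = withr::local_tempdir(), seed = 5)
  ds <- curate_dataset(fx$paths)
  all_splits <- c(ds$rbps$split, ds$others$split)
  expect_true(all(all_splits %in% c("train", "test")))
  expect_equal(length(all_splits), nrow(ds$rbps) + nrow(ds$others))
})

test_that("degenerate curation inputs are handled", {
  empty <- curate_records(
    data.frame(genome_accession = character(), protein_id = character(),
               product = character(), sequence = character(),
               record_date = as.Date(character())))
  expect_equal(nrow(empty$rbps), 0L)
  expect_equal(nrow(empty$others), 0L)
  expect_equal(sum(empty$ledger$removed), 0L)

  hyp <- data.frame(genome_accession = "G", protein_id = paste0("p", 1:3),
                    product = "hypothetical protein",
                    sequence = replicate(3, random_aa_seq(100)),
                    record_date = as.Date("2021-05-01"))
  ds <- curate_records(hyp, ratio = NULL)
  expect_equal(nrow(ds$others), 0L)
  expect_equal(sum(ds$ledger$removed), 3L)
})

test_that("dataset export writes FASTA with structured headers plus ledger", {
  fx <- gen_genbank(n_cds = 60, dir = withr::local_tempdir(), seed = 2)
  ds <- curate_dataset(fx$paths)
  out <- withr::local_tempdir()
  write_dataset(ds, out)
  faa <- Biostrings::readAAStringSet(file.path(out, "rbps.faa"))
  expect_equal(length(faa), nrow(ds$rbps))
  parts <- strsplit(names(faa)[1], "|", fixed = TRUE)[[1]]
  expect_length(parts, 4)
  expect_equal(parts[3], "RBP")
  expect_true(file.exists(file.path(out, "ledger.tsv")))
})
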