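mk_hits <- function(target, starts, ends = starts + 30,
                    hmms = sprintf("h%d", seq_along(starts))) {
  data.frame(target_id = rep(target, length(starts)), hmm_name = hmms,
             ali_start = starts, ali_end = ends,
             bit_score = rep(50, length(starts)), stringsAsFactors = FALSE)
}

test_that("architecture calling assigns sides by hit start with the 200-residue cutoff", {
  hits <- mk_hits("t1", c(150, 201, 200, 450), hmms = c("a", "b", "c", "d"))
  arch <- call_architecture("t1", hits)
  expect_setequal(arch$n_terminal$hmm_name, c("a", "c"))
  expect_setequal(arch$c_terminal$hmm_name, c("b", "d"))
  expect_equal(arch$signature, c("a", "c", "b", "d"))
  expect_equal(nrow(arch$n_terminal) + nrow(arch$c_terminal), nrow(hits))
  empty <- call_architecture("t2", hits[0, ])
  expect_equal(empty$signature, character())
  expect_false(is_rbp_by_domains(empty))
  expect_true(is_rbp_by_domains(arch))
  expect_true(is_rbp_by_domains(call_architecture("t1", hits[1, ])))
})

test_that("one-sided architectures are identified on the correct side", {
  archs <- list(
    n_only = call_architecture("n_only", mk_hits("n_only", 100)),
    c_only = call_architecture("c_only", mk_hits("c_only", 300)),
    both = call_architecture("both", mk_hits("both", c(100, 300))),
    none = call_architecture("none", mk_hits("none", numeric())))
  os <- find_one_sided(archs)
  expect_equal(os$missing_C, "n_only")
  expect_equal(os$missing_N, "c_only")
  expect_false(any(c("both", "none") %in% unlist(os)))
})

test_that("terminus parts use the documented coordinate conventions", {
  seqs <- c(long_noN = random_aa_seq(800), short_noN = random_aa_seq(150),
            noC = random_aa_seq(800), flush = random_aa_seq(260))
  archs <- list(
    long_noN = call_architecture("long_noN", mk_hits("long_noN", 300)),
    short_noN = call_architecture("short_noN", mk_hits("short_noN", numeric())),
    noC = call_architecture("noC", mk_hits("noC", 100, ends = 230)),
    flush = call_architecture("flush", mk_hits("flush", 100, ends = 260)))
  os <- list(missing_N = c("long_noN", "short_noN"), missing_C = c("noC", "flush"))
  expect_message(parts <- extract_parts(os, archs, seqs), "dropped")
  pN <- parts[parts$parent_id == "long_noN", ]
  expect_equal(c(pN$start, pN$end), c(1L, 200L))
  expect_equal(pN$sequence, substr(unname(seqs["long_noN"]), 1, 200))
  expect_equal(parts[parts$parent_id == "short_noN", ]$end, 150L)
  pC <- parts[parts$parent_id == "noC", ]
  expect_equal(c(pC$start, pC$end), c(231L, 800L))
  # a C part with no residues left (hit flush with the terminus) is dropped
  expect_false("flush" %in% parts$parent_id)
})

test_that("greedy clustering partitions parts and respects the identity threshold", {
  p <- function(id, s) data.frame(parent_id = id, side = "C", start = 1L,
                                  end = nchar(s), sequence = s,
                                  stringsAsFactors = FALSE)
  same <- do.call(rbind, lapply(1:5, function(i) p(paste0("s", i), strrep("ACDEFGHIKL", 8))))
  cl <- greedy_cluster(same, 0.9)
  expect_length(cl, 1)
  expect_equal(nrow(cl[[1]]$members), 5L)

  two <- rbind(p("a", strrep("AC", 40)), p("b", strrep("WY", 40)))
  expect_length(greedy_cluster(two, 0.9), 2)

  # 3 families x 6 lightly mutated members: within-family identity stays
  # above 0.9 (verified below), between-family identity is far lower
  set.seed(55)
  fams <- replicate(3, random_aa_seq(100))
  parts <- do.call(rbind, unlist(lapply(1:3, function(f) {
    lapply(1:6, function(m) {
      p(sprintf("f%d_m%d", f, m), rbpdetect:::mutate_sequence(fams[f], 0.015))
    })
  }), recursive = FALSE))
  fam_of <- sub("_m\\d+", "", parts$parent_id)
  within <- outer(seq_len(nrow(parts)), seq_len(nrow(parts)), Vectorize(function(i, j) {
    if (i >= j || fam_of[i] != fam_of[j]) return(1)
    pairwise_identity(parts$sequence[i], parts$sequence[j])
  }))
  expect_true(all(within > 0.9))  # the fixture really is >90% within-family
  cl <- greedy_cluster(parts, 0.9)
  expect_length(cl, 3)
  expect_equal(sort(vapply(cl, function(c1) nrow(c1$members), 0L)), c(6L, 6L, 6L))
  # partition: every part in exactly one cluster
  all_ids <- unlist(lapply(cl, function(c1) c1$members$parent_id))
  expect_setequal(all_ids, parts$parent_id)
  expect_equal(length(all_ids), nrow(parts))
  # member-to-representative identity respects the threshold
  for (c1 in cl) {
    idts <- vapply(c1$members$sequence, pairwise_identity, 0, a = c1$rep_seq)
    expect_true(all(idts >= 0.9))
  }
  expect_error(greedy_cluster(rbind(p("x", "AAAA"),
                                    within(p("y", "AAAA"), side <- "N")), 0.9),
               "separately")
})

test_that("cluster alignment requires five members and handles insertions", {
  p <- function(id, s) data.frame(parent_id = id, side = "C", start = 1L,
                                  end = nchar(s), sequence = s,
                                  stringsAsFactors = FALSE)
  five <- do.call(rbind, lapply(1:5, function(i) p(paste0("s", i), "ACDEFGHIKL")))
  cl <- greedy_cluster(five, 0.9)[[1]]
  al <- align_cluster(cl)
  expect_s3_class(al, "msa")
  expect_true(all(al$sequences == "ACDEFGHIKL"))  # gapless, identical rows
  expect_message(expect_null(align_cluster(greedy_cluster(five[1:4, ], 0.9)[[1]])),
                 "skipped")
  # one member carries an internal insertion -> one gapped column
  base <- "ACDEFGHIKLMNPQRSTVWY"
  ins <- "ACDEFGHIKLWMNPQRSTVWY"
  aln <- align_center_star(c(a = base, b = base, c = ins, d = base, e = base))
  aln_mat <- do.call(rbind, strsplit(aln$sequences, ""))
  gap_cols <- colSums(aln_mat == "-")
  expect_equal(sum(gap_cols > 0), 1L)
  expect_equal(nchar(aln$sequences[1]), nchar(ins))
})

test_that("custom-HMM construction discovers withheld families and never loses detections", {
  fix <- gen_modular_proteins(n_families_N = 2, n_withheld_C = 2,
                              carriers_per_family = 6, heldout_per_family = 4,
                              mutation_rate = 0.05, seed = 21)
  res <- construct_custom_hmms(fix$train, fix$base_hmms, threshold = 25,
                               identity_threshold = 0.7)
  expect_equal(unname(res$report$n_built["C"]), 2L)
  expect_equal(unname(res$report$n_built["N"]), 0L)
  expect_true(all(grepl("^custom_C_", names(res$new_hmms))))
  # augmentation monotonicity: domain-positive set never shrinks
  before <- unique(scan_sequences(fix$train, fix$base_hmms, 25)$target_id)
  after <- unique(scan_sequences(fix$train, res$hmm_set, 25)$target_id)
  expect_true(all(before %in% after))
  # the new HMMs hit their own training parts
  expect_gt(res$report$custom_hit_proteins, 0)
})

test_that("no one-sided input means no custom HMMs", {
  fix <- gen_modular_proteins(n_families_N = 1, n_withheld_C = 1,
                              carriers_per_family = 3, heldout_per_family = 2,
                              mutation_rate = 0.05, seed = 4)
  # scanning with an HMM set that contains both sides leaves nothing one-sided
  c_hmm <- build_from_msa(
    msa(replicate(8, rbpdetect:::mutate_sequence(
      fix$families$consensus[fix$families$side == "C"], 0.05))), "CfamKnown")
  full_set <- c(fix$base_hmms, list(CfamKnown = c_hmm))
  res <- construct_custom_hmms(fix$train, full_set, threshold = 25,
                               identity_threshold = 0.7)
  expect_equal(sum(res$report$n_built), 0L)
  expect_length(res$new_hmms, 0)
})
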