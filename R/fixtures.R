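#' Deterministic synthetic GenBank fixture with curation ground truth
#'
#' Writes multi-record GenBank flat files whose CDS products span the RBP
#' keyword space (pass / fail / exclusion annotations), with controlled
#' lengths, non-canonical residues, planted duplicates (within-group and
#' cross-group) and record dates straddling the train/test cutoff. Every
#' CDS is generated with exactly one planned curation outcome, so the truth
#' table determines the expected group sizes and ledger counts of
#' [curate_dataset()] without re-running the curation rules.
#'
#' @param n_cds Total number of CDS features (default 1000).
#' @param dir Output directory for the GenBank files.
#' @param seed RNG seed; the same seed yields byte-identical files.
#' @param cutoff Train/test cutoff month used for the expected split.
#' @param cds_per_genome CDS features per genome record.
#' @return List with `paths` (GenBank files), `truth` (one row per CDS:
#'   ids, `category`, `expected` outcome, `split_expected`) and
#'   `expected_counts` (named ledger/retention expectations for
#'   ratio-10 subsampling).
#' @export
gen_genbank <- function(n_cds = 1000, dir = tempfile("gbfix"), seed = 1,
                        cutoff = "2021-09", cds_per_genome = 20) {
  force(dir)
  withr_seed(seed, gen_genbank_impl(n_cds, dir, cutoff, cds_per_genome))
}

rbp_pass_products <- function() {
  c("tail fiber protein", "tailspike protein", "tail spike", "tail-fiber",
    "receptor-binding protein", "receptor binding protein",
    "tail fibre protein", "receptor-recognizing protein")
}

rbp_excluded_products <- function() {
  c("tail fiber assembly protein", "tail-fiber hinge connector",
    "tail fiber chaperone", "baseplate tail-fiber attachment",
    "structural tail spike", "tail fiber assembly chaperone")
}

other_clean_products <- function() {
  c("major capsid protein", "terminase large subunit", "portal protein",
    "holin", "endolysin", "DNA polymerase", "integrase", "tail protein",
    "spike", "binding protein", "head-tail adaptor")
}

other_excluded_products <- function() {
  c("hypothetical protein", "putative holin", "uncharacterized protein",
    "predicted protein", "probable tail protein", "unknown function")
}

gen_genbank_impl <- function(n_cds, dir, cutoff, cds_per_genome) {
  frac <- c(rbp_keep = 0.08, rbp_excluded = 0.02, rbp_length = 0.02,
            rbp_unknown_aa = 0.01, other_keep = 0.75, other_excluded = 0.05,
            other_length = 0.02, other_unknown_aa = 0.02,
            dup_within_rbp = 0.01, dup_within_other = 0.01, dup_cross = 0.01)
  counts <- round(frac * n_cds)
  counts["other_keep"] <- n_cds - sum(counts[names(counts) != "other_keep"])

  base_cats <- setdiff(names(counts), c("dup_within_rbp", "dup_within_other",
                                        "dup_cross"))
  cats <- c(rep(base_cats, counts[base_cats]))
  cats <- sample(cats)   # shuffle originals; duplicates appended after

  plan <- data.frame(category = cats, sequence = NA_character_,
                     product = NA_character_, stringsAsFactors = FALSE)
  pick <- function(pool) pool[sample.int(length(pool), 1)]
  plant_x <- function(s) {
    pos <- sample.int(nchar(s), 1)
    paste0(substr(s, 1, pos - 1), "X", substr(s, pos + 1, nchar(s)))
  }
  for (i in seq_len(nrow(plan))) {
    cat_i <- plan$category[i]
    if (cat_i == "rbp_keep") {
      plan$sequence[i] <- sample_background(sample(200:700, 1))
      plan$product[i] <- pick(rbp_pass_products())
    } else if (cat_i == "rbp_excluded") {
      plan$sequence[i] <- sample_background(sample(200:700, 1))
      plan$product[i] <- pick(rbp_excluded_products())
    } else if (cat_i == "rbp_length") {
      plan$sequence[i] <- sample_background(sample(50:199, 1))
      plan$product[i] <- pick(rbp_pass_products())
    } else if (cat_i == "rbp_unknown_aa") {
      plan$sequence[i] <- plant_x(sample_background(sample(200:700, 1)))
      plan$product[i] <- pick(rbp_pass_products())
    } else if (cat_i == "other_keep") {
      plan$sequence[i] <- sample_background(sample(30:400, 1))
      plan$product[i] <- pick(other_clean_products())
    } else if (cat_i == "other_excluded") {
      plan$sequence[i] <- sample_background(sample(30:400, 1))
      plan$product[i] <- pick(other_excluded_products())
    } else if (cat_i == "other_length") {
      plan$sequence[i] <- sample_background(sample(10:29, 1))
      plan$product[i] <- pick(other_clean_products())
    } else if (cat_i == "other_unknown_aa") {
      plan$sequence[i] <- plant_x(sample_background(sample(30:400, 1)))
      plan$product[i] <- pick(other_clean_products())
    }
  }

  plan$expected <- c(rbp_keep = "retained_rbp",
                     rbp_excluded = "removed_rbp_excluded_keyword",
                     rbp_length = "removed_rbp_length",
                     rbp_unknown_aa = "removed_rbp_unknown_aa",
                     other_keep = "other_pool",
                     other_excluded = "removed_other_excluded_keyword",
                     other_length = "removed_other_length",
                     other_unknown_aa = "removed_other_unknown_aa")[plan$category]

  # planned duplicates, appended so originals come first in input order
  add_dup <- function(plan, n, target_cat, category, product_pool, expected,
                      flip_target = FALSE) {
    targets <- which(plan$category == target_cat &
                       !plan$expected %in% "removed_dup_cross")
    targets <- sample(targets, n)
    for (t in targets) {
      plan <- rbind(plan, data.frame(
        category = category, sequence = plan$sequence[t],
        product = pick(product_pool), expected = expected,
        stringsAsFactors = FALSE))
      if (flip_target) plan$expected[t] <- "removed_dup_cross"
    }
    plan
  }
  plan <- add_dup(plan, counts["dup_within_rbp"], "rbp_keep",
                  "dup_within_rbp", rbp_pass_products(),
                  "removed_dup_within_rbp")
  plan <- add_dup(plan, counts["dup_within_other"], "other_keep",
                  "dup_within_other", other_clean_products(),
                  "removed_dup_within_other")
  plan <- add_dup(plan, counts["dup_cross"], "rbp_keep",
                  "dup_cross", other_clean_products(),
                  "removed_dup_cross", flip_target = TRUE)

  n_total <- nrow(plan)
  n_genomes <- ceiling(n_total / cds_per_genome)
  plan$genome_accession <- sprintf("SYNPHG%04d",
                                   rep(seq_len(n_genomes),
                                       each = cds_per_genome)[seq_len(n_total)])
  plan$protein_id <- sprintf("SYNP_%05d", seq_len(n_total))
  month <- sample(1:12, n_genomes, replace = TRUE)
  day <- sample(1:28, n_genomes, replace = TRUE)
  gdate <- as.Date(sprintf("2021-%02d-%02d", month, day))
  plan$record_date <- gdate[match(plan$genome_accession,
                                  sprintf("SYNPHG%04d", seq_len(n_genomes)))]
  plan$split_expected <- split_by_date(plan$record_date, cutoff)

  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  genomes_per_file <- 25L
  for (fi in seq_len(ceiling(n_genomes / genomes_per_file))) {
    gset <- seq((fi - 1) * genomes_per_file + 1,
                min(fi * genomes_per_file, n_genomes))
    lines <- unlist(lapply(gset, function(g) {
      acc <- sprintf("SYNPHG%04d", g)
      rows <- plan[plan$genome_accession == acc, , drop = FALSE]
      format_genbank_record(acc, gdate[g], rows)
    }))
    p <- file.path(dir, sprintf("fixture_%02d.gbk", fi))
    writeLines(lines, p)
    paths <- c(paths, p)
  }

  n_rbp_retained <- sum(plan$expected == "retained_rbp")
  pool <- sum(plan$expected == "other_pool")
  kept_others <- round(10 * n_rbp_retained)
  expected_counts <- c(
    rbp_excluded_keyword = sum(plan$expected == "removed_rbp_excluded_keyword"),
    other_excluded_keyword = sum(plan$expected == "removed_other_excluded_keyword"),
    rbp_unknown_aa = sum(plan$expected == "removed_rbp_unknown_aa"),
    rbp_length = sum(plan$expected == "removed_rbp_length"),
    other_unknown_aa = sum(plan$expected == "removed_other_unknown_aa"),
    other_length = sum(plan$expected == "removed_other_length"),
    dup_within_rbp = sum(plan$expected == "removed_dup_within_rbp"),
    dup_within_other = sum(plan$expected == "removed_dup_within_other"),
    dup_cross = sum(plan$expected == "removed_dup_cross"),
    other_subsampled_out = pool - kept_others,
    retained_rbps = n_rbp_retained,
    retained_others = kept_others,
    n_cds = n_total)

  list(paths = paths, truth = plan, expected_counts = expected_counts,
       config = list(seed_note = "reproducible given seed", cutoff = cutoff))
}

format_genbank_record <- function(acc, date, rows) {
  glen <- sum(nchar(rows$sequence)) * 3 + 100 * (nrow(rows) + 1)
  out <- c(
    sprintf("LOCUS       %s%19d bp    DNA     linear   PHG %s", acc, glen,
            toupper(format(date, "%d-%b-%Y"))),
    sprintf("DEFINITION  Synthetic phage genome %s.", acc),
    sprintf("ACCESSION   %s", acc),
    "FEATURES             Location/Qualifiers",
    sprintf("     source          1..%d", glen))
  pos <- 1L
  for (i in seq_len(nrow(rows))) {
    cds_len <- nchar(rows$sequence[i]) * 3 + 3
    out <- c(out,
      sprintf("     CDS             %d..%d", pos, pos + cds_len - 1),
      sprintf("                     /product=\"%s\"", rows$product[i]),
      sprintf("                     /protein_id=\"%s\"", rows$protein_id[i]),
      wrap_qualifier("translation", rows$sequence[i]))
    pos <- pos + cds_len + 97L
  }
  c(out, "//")
}

wrap_qualifier <- function(key, value) {
  txt <- paste0("/", key, "=\"", value, "\"")
  chunks <- substring(txt, seq(1, nchar(txt), 58), pmin(seq(58, nchar(txt) + 57, 58), nchar(txt)))
  paste0(strrep(" ", 21), chunks)
}

#' Synthetic modular RBP-like proteins with reusable domain families
#'
#' Emulates the modular architecture of receptor-binding proteins: each
#' protein is an N-terminal structural domain, a short background-residue
#' linker, and a C-terminal domain, with domain family members mutated from
#' a family consensus by point substitution. N-terminal families are
#' "known" (profile HMMs for them are returned as the base set); the
#' C-terminal families are withheld from the base set so the custom-HMM
#' construction pipeline has something to discover. Held-out carriers and
#' per-sequence shuffled decoys are produced for detection-rate estimates.
#'
#' @param n_families_N Number of known N-terminal families (default 2).
#' @param n_withheld_C Number of withheld C-terminal families (default 3).
#' @param carriers_per_family Training carriers per withheld family.
#' @param heldout_per_family Held-out carriers per withheld family.
#' @param mutation_rate Per-residue substitution rate (default 0.10).
#' @param n_len,c_len Domain consensus lengths.
#' @param seed RNG seed.
#' @return List: `train` / `heldout` / `decoys` (named sequence vectors),
#'   `truth` (per protein: families and domain coordinates), `base_hmms`
#'   (profile HMMs of the known N families), `families` (consensus table).
#' @export
gen_modular_proteins <- function(n_families_N = 2, n_withheld_C = 3,
                                 carriers_per_family = 8,
                                 heldout_per_family = 20,
                                 mutation_rate = 0.10,
                                 n_len = 150, c_len = 120, seed = 1) {
  withr_seed(seed, {
    n_fams <- paste0("NfamKnown", seq_len(n_families_N))
    c_fams <- paste0("CfamWithheld", seq_len(n_withheld_C))
    consensus <- c(
      setNames(replicate(n_families_N, sample_background(n_len)), n_fams),
      setNames(replicate(n_withheld_C, sample_background(c_len)), c_fams))

    make_carrier <- function(id, nf, cf) {
      linker <- sample_background(sample(5:15, 1))
      n_dom <- mutate_sequence(consensus[[nf]], mutation_rate)
      c_dom <- mutate_sequence(consensus[[cf]], mutation_rate)
      seqs <- paste0(n_dom, linker, c_dom)
      data.frame(id = id, sequence = seqs, n_family = nf, c_family = cf,
                 n_start = 1L, n_end = nchar(n_dom),
                 c_start = nchar(n_dom) + nchar(linker) + 1L,
                 c_end = nchar(seqs), stringsAsFactors = FALSE)
    }
    rows <- list()
    for (cf in c_fams) {
      for (r in seq_len(carriers_per_family)) {
        rows[[length(rows) + 1L]] <- cbind(
          make_carrier(sprintf("train_%s_%02d", cf, r),
                       sample(n_fams, 1), cf), role = "train")
      }
      for (r in seq_len(heldout_per_family)) {
        rows[[length(rows) + 1L]] <- cbind(
          make_carrier(sprintf("heldout_%s_%02d", cf, r),
                       sample(n_fams, 1), cf), role = "heldout")
      }
    }
    truth <- do.call(rbind, rows)

    shuffle_seq <- function(s) {
      paste(sample(strsplit(s, "")[[1]]), collapse = "")
    }
    heldout <- setNames(truth$sequence[truth$role == "heldout"],
                        truth$id[truth$role == "heldout"])
    decoys <- setNames(vapply(heldout, shuffle_seq, ""),
                       paste0("decoy_", seq_along(heldout)))

    base_hmms <- lapply(n_fams, function(nf) {
      copies <- replicate(10, mutate_sequence(consensus[[nf]], mutation_rate))
      build_from_msa(msa(copies), name = nf)
    })
    names(base_hmms) <- n_fams

    list(train = setNames(truth$sequence[truth$role == "train"],
                          truth$id[truth$role == "train"]),
         heldout = heldout, decoys = decoys, truth = truth,
         base_hmms = base_hmms,
         families = data.frame(family = names(consensus),
                               side = c(rep("N", n_families_N),
                                        rep("C", n_withheld_C)),
                               withheld = c(rep(FALSE, n_families_N),
                                            rep(TRUE, n_withheld_C)),
                               consensus = unname(unlist(consensus)),
                               stringsAsFactors = FALSE))
  })
}

#' Synthetic two-class protein set with controllable separability
#'
#' Background-residue sequences; the positive class carries a designated
#' 3-mer signature motif planted a number of times proportional to the
#' effect size. Effect 0 makes the classes exchangeable.
#'
#' @param n Number of sequences.
#' @param effect Effect size >= 0; positives get `round(effect * 20)` motif
#'   copies each.
#' @param prevalence Positive-class fraction (default 0.5).
#' @param len_range Sequence length range.
#' @param motif Signature motif (default `"WCW"`).
#' @param seed RNG seed.
#' @return List with `seqs` (named) and `labels` (1 = positive).
#' @export
gen_two_class <- function(n = 500, effect = 1, prevalence = 0.5,
                          len_range = c(150, 250), motif = "WCW", seed = 1) {
  stopifnot(effect >= 0)
  withr_seed(seed, {
    n_pos <- round(n * prevalence)
    labels <- c(rep(1L, n_pos), rep(0L, n - n_pos))
    copies <- round(effect * 20)
    seqs <- vapply(seq_len(n), function(i) {
      s <- sample_background(sample(len_range[1]:len_range[2], 1))
      if (labels[i] == 1L && copies > 0) {
        for (p in sample.int(nchar(s) - nchar(motif) + 1, copies)) {
          substr(s, p, p + nchar(motif) - 1) <- motif
        }
      }
      s
    }, "")
    names(seqs) <- sprintf("prot_%04d", seq_len(n))
    list(seqs = seqs, labels = labels)
  })
}

#' Synthetic two-class set where only HMM scores carry signal
#'
#' Long background sequences in both classes; positives additionally carry
#' one short, heavily mutated domain at a random internal position. The
#' domain is short and mutated enough that k-mer composition barely moves,
#' while a profile HMM built from domain copies still scores carriers well
#' above background -- so HMM bit-score features separate the classes far
#' better than composition embeddings do.
#'
#' @param n Number of sequences (half positive).
#' @param seq_len Sequence length.
#' @param domain_len Planted domain length (default 30).
#' @param mutation_rate Per-residue substitution rate of planted copies.
#' @param seed RNG seed.
#' @return List with `seqs`, `labels`, and `hmm` (a profile HMM of the
#'   planted domain family, built from independent mutated copies).
#' @export
gen_fusion_fixture <- function(n = 150, seq_len = 500, domain_len = 30,
                               mutation_rate = 0.3, seed = 1) {
  withr_seed(seed, {
    consensus <- sample_background(domain_len)
    n_pos <- round(n / 2)
    labels <- c(rep(1L, n_pos), rep(0L, n - n_pos))
    seqs <- vapply(seq_len(n), function(i) {
      s <- sample_background(seq_len)
      if (labels[i] == 1L) {
        dom <- mutate_sequence(consensus, mutation_rate)
        p <- sample.int(seq_len - domain_len + 1, 1)
        substr(s, p, p + domain_len - 1) <- dom
      }
      s
    }, "")
    names(seqs) <- sprintf("fus_%04d", seq_len(n))
    hmm <- build_from_msa(
      msa(replicate(12, mutate_sequence(consensus, mutation_rate))),
      name = "planted_domain")
    list(seqs = seqs, labels = labels, hmm = hmm)
  })
}
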