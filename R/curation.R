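#' RBP annotation keyword pattern
#'
#' Case-insensitive regular expression matching the annotation keywords used
#' to label a coding sequence as a receptor-binding protein: tail fiber /
#' tail fibre, tail spike, receptor-binding protein, receptor-recognizing
#' protein, and their spacing / hyphenation variants. The bare words "spike",
#' "fiber" or "tail protein" never match.
#' @return A single regex string.
#' @export
rbp_keyword_pattern <- function() {
  paste0("tail[ -]?fib(er|re)", "|",
         "tail[ -]?spike", "|",
         "receptor[ -]binding protein", "|",
         "receptor[ -]recogni[sz]ing protein")
}

#' Does a product annotation look like an RBP?
#'
#' @param product Character vector of `/product` annotation strings.
#' @return Logical vector; `TRUE` where the annotation matches the RBP
#'   keyword pattern (case-insensitive). Empty strings never match.
#' @export
match_rbp_annotation <- function(product) {
  grepl(rbp_keyword_pattern(), product, ignore.case = TRUE, perl = TRUE)
}

# exclusion keyword lists; substring matching, case-insensitive, whole product
rbp_exclusion_keywords <- function() {
  c("adaptor", "wedge", "baseplate", "hinge", "connector", "structural",
    "component", "assembly", "chaperone", "attachment", "capsid",
    "proximal", "measure")
}

other_exclusion_keywords <- function() {
  c("probable", "probably", "uncharacterized", "uncharacterised",
    "putative", "hypothetical", "unknown", "predicted")
}

contains_keyword <- function(product, keywords) {
  hit <- rep(FALSE, length(product))
  for (kw in keywords) {
    hit <- hit | grepl(kw, product, ignore.case = TRUE, fixed = FALSE)
  }
  hit
}

#' Exclusion rules applied after keyword labeling
#'
#' RBP-labeled products mentioning a related-but-not-RBP role (assembly,
#' hinge, baseplate, chaperone, ...) are discarded; Other-labeled products
#' with non-committal annotations (hypothetical, putative, ...) are discarded
#' because they might be unannotated RBPs. Substring matching,
#' case-insensitive.
#' @param product Character vector of annotations.
#' @return Logical vector (`TRUE` = excluded).
#' @export
is_excluded_rbp <- function(product) {
  contains_keyword(product, rbp_exclusion_keywords())
}

#' @rdname is_excluded_rbp
#' @export
is_excluded_other <- function(product) {
  contains_keyword(product, other_exclusion_keywords())
}

#' Sequence quality filter
#'
#' A retained RBP must be 200-1500 residues (boundaries inclusive); a
#' retained Other must be at least 30 residues; no retained sequence may
#' contain a residue outside the 20 canonical amino acids (one trailing stop
#' `*` is stripped first).
#'
#' @param sequence Character vector of protein sequences.
#' @param group `"RBP"` or `"Other"` (scalar or vector).
#' @return Character vector: `"ok"`, `"unknown_aa"` or `"length"` per entry;
#'   the unknown-residue check takes precedence.
#' @export
quality_filter_reason <- function(sequence, group) {
  sequence <- strip_stop(sequence)
  group <- rep_len(group, length(sequence))
  len <- nchar(sequence)
  reason <- rep("ok", length(sequence))
  bad_len <- ifelse(group == "RBP", len < 200 | len > 1500, len < 30)
  reason[bad_len] <- "length"
  reason[!is_canonical(sequence)] <- "unknown_aa"
  reason
}

#' @rdname quality_filter_reason
#' @return `passes_quality_filters()` returns a logical vector.
#' @export
passes_quality_filters <- function(sequence, group) {
  quality_filter_reason(sequence, group) == "ok"
}

#' Remove duplicate sequences within and across the two groups
#'
#' Exact-sequence duplicates within each group collapse to the first
#' occurrence (stable input order). Any sequence present in both groups is
#' removed from both: group membership is contradictory evidence about its
#' label.
#'
#' @param rbps,others data.frames with a `sequence` column.
#' @return List with elements `rbps`, `others` (the deduplicated frames) and
#'   `removed` (named counts: `dup_within_rbp`, `dup_within_other`,
#'   `dup_cross`).
#' @export
deduplicate <- function(rbps, others) {
  dup_r <- duplicated(rbps$sequence)
  dup_o <- duplicated(others$sequence)
  r1 <- rbps[!dup_r, , drop = FALSE]
  o1 <- others[!dup_o, , drop = FALSE]
  cross <- intersect(r1$sequence, o1$sequence)
  r2 <- r1[!r1$sequence %in% cross, , drop = FALSE]
  o2 <- o1[!o1$sequence %in% cross, , drop = FALSE]
  list(rbps = r2, others = o2,
       removed = c(dup_within_rbp = sum(dup_r),
                   dup_within_other = sum(dup_o),
                   dup_cross = (nrow(r1) - nrow(r2)) + (nrow(o1) - nrow(o2))))
}

#' Assign records to train or test by record date
#'
#' Records dated in or before the cutoff month go to the training split;
#' later records go to the test split (the cutoff month is inclusive).
#'
#' @param record_date Date vector.
#' @param cutoff Cutoff month as `"YYYY-MM"`.
#' @return Character vector of `"train"` / `"test"`.
#' @export
split_by_date <- function(record_date, cutoff = "2021-09") {
  if (anyNA(record_date)) {
    stop("unparseable record date at position(s): ",
         paste(which(is.na(record_date)), collapse = ", "))
  }
  cut <- as.integer(strsplit(cutoff, "-")[[1]])
  if (length(cut) != 2 || anyNA(cut)) stop("cutoff must be 'YYYY-MM'")
  ym <- as.integer(format(record_date, "%Y")) * 12L +
    as.integer(format(record_date, "%m"))
  ifelse(ym <= cut[1] * 12L + cut[2], "train", "test")
}

#' Randomly subsample the Other group
#'
#' Draws a uniform random subset (without replacement) of size
#' `round(ratio * n_rbp)` from the Other pool, reproducibly for a given seed.
#'
#' @param others data.frame of Other records.
#' @param n_rbp Number of retained RBP sequences.
#' @param ratio Others-to-RBP ratio (default 10).
#' @param seed Integer RNG seed.
#' @return The subsampled data.frame (original row order preserved).
#' @export
subsample_others <- function(others, n_rbp, ratio = 10, seed = 42) {
  size <- round(ratio * n_rbp)
  if (size > nrow(others)) {
    stop("requested subsample (", size, ") exceeds Other pool (",
         nrow(others), ")")
  }
  if (size == 0) return(others[0, , drop = FALSE])
  keep <- withr_seed(seed, sample(nrow(others), size))
  others[sort(keep), , drop = FALSE]
}

# evaluate expr under a temporary RNG state
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Curate labeled RBP / Other datasets from parsed CDS records
#'
#' Runs the full curation cascade on a CDS table: keyword labeling,
#' per-group exclusion keywords, quality filters (unknown residues, length),
#' deduplication within and across groups, random subsampling of the Other
#' group to `ratio` times the RBP count, and a date-based train/test split.
#' The ledger accounts for every removed sequence.
#'
#' @param cds data.frame as returned by [read_genbank_cds()].
#' @param cutoff Train/test cutoff month `"YYYY-MM"` (inclusive on the train
#'   side).
#' @param ratio Others-to-RBP subsampling ratio; `NULL` disables subsampling.
#' @param seed RNG seed for the subsample.
#' @return An object of class `rbp_dataset`: list with data.frames `rbps`
#'   and `others` (each with a `split` column), the `ledger` (step, count)
#'   and the `config` used.
#' @export
curate_records <- function(cds, cutoff = "2021-09", ratio = 10, seed = 42) {
  stopifnot(is.data.frame(cds))
  ledger <- c()
  is_rbp <- match_rbp_annotation(cds$product)
  rbps <- cds[is_rbp, , drop = FALSE]
  others <- cds[!is_rbp, , drop = FALSE]

  drop_r <- is_excluded_rbp(rbps$product)
  ledger["rbp_excluded_keyword"] <- sum(drop_r)
  rbps <- rbps[!drop_r, , drop = FALSE]
  drop_o <- is_excluded_other(others$product)
  ledger["other_excluded_keyword"] <- sum(drop_o)
  others <- others[!drop_o, , drop = FALSE]

  reason_r <- quality_filter_reason(rbps$sequence, "RBP")
  ledger["rbp_unknown_aa"] <- sum(reason_r == "unknown_aa")
  ledger["rbp_length"] <- sum(reason_r == "length")
  rbps <- rbps[reason_r == "ok", , drop = FALSE]
  reason_o <- quality_filter_reason(others$sequence, "Other")
  ledger["other_unknown_aa"] <- sum(reason_o == "unknown_aa")
  ledger["other_length"] <- sum(reason_o == "length")
  others <- others[reason_o == "ok", , drop = FALSE]

  dd <- deduplicate(rbps, others)
  ledger <- c(ledger, dd$removed)
  rbps <- dd$rbps
  others <- dd$others

  if (!is.null(ratio)) {
    kept <- subsample_others(others, nrow(rbps), ratio, seed)
    ledger["other_subsampled_out"] <- nrow(others) - nrow(kept)
    others <- kept
  } else {
    ledger["other_subsampled_out"] <- 0L
  }

  rbps$split <- if (nrow(rbps)) split_by_date(rbps$record_date, cutoff) else character()
  others$split <- if (nrow(others)) split_by_date(others$record_date, cutoff) else character()
  rownames(rbps) <- rownames(others) <- NULL

  structure(list(rbps = rbps, others = others,
                 ledger = data.frame(step = names(ledger),
                                     removed = as.integer(ledger),
                                     stringsAsFactors = FALSE),
                 config = list(cutoff = cutoff, ratio = ratio, seed = seed,
                               date_source = "LOCUS line record date")),
            class = "rbp_dataset")
}

#' @rdname curate_records
#' @param genbank_paths GenBank flat files to read.
#' @param ... Passed on to `curate_records()`.
#' @export
curate_dataset <- function(genbank_paths, ...) {
  curate_records(read_genbank_cds(genbank_paths), ...)
}

#' @export
print.rbp_dataset <- function(x, ...) {
  cat("Curated phage protein dataset\n")
  cat(sprintf("  RBPs:   %d  (train %d / test %d)\n", nrow(x$rbps),
              sum(x$rbps$split == "train"), sum(x$rbps$split == "test")))
  cat(sprintf("  Others: %d  (train %d / test %d)\n", nrow(x$others),
              sum(x$others$split == "train"), sum(x$others$split == "test")))
  cat("  Removed:", sum(x$ledger$removed), "sequences in",
      nrow(x$ledger), "filter steps\n")
  invisible(x)
}

#' Write a curated dataset to FASTA + ledger TSV
#'
#' Emits `rbps.faa` and `others.faa` with headers
#' `<genome_accession>|<protein_id>|<label>|<split>`, the filter ledger as
#' `ledger.tsv` and the configuration as `config.json`.
#' @param dataset An `rbp_dataset`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "rbp_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_group <- function(df, label, file) {
    seqs <- Biostrings::AAStringSet(strip_stop(df$sequence))
    names(seqs) <- paste(df$genome_accession, df$protein_id, label, df$split,
                         sep = "|")
    Biostrings::writeXStringSet(seqs, file.path(dir, file))
  }
  write_group(dataset$rbps, "RBP", "rbps.faa")
  write_group(dataset$others, "Other", "others.faa")
  write.table(dataset$ledger, file.path(dir, "ledger.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  jsonlite::write_json(dataset$config, file.path(dir, "config.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
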