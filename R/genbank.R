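#' Read CDS proteins from GenBank flat files
#'
#' Minimal parser for annotated (multi-record) GenBank flat files, extracting
#' one row per CDS feature: the translated protein, its `/product` annotation,
#' the genome accession and the record date (from the LOCUS line). CDS
#' features without a `/translation` qualifier are translated from the genome
#' sequence using genetic code table 11 when the location is a simple
#' `start..end` or `complement(start..end)` span; CDSs with locations the
#' parser does not support (e.g. `join(...)`) are skipped and counted.
#'
#' @param paths Character vector of GenBank file paths.
#' @return A data.frame with columns `genome_accession`, `protein_id`,
#'   `product`, `sequence`, `record_date` (class `Date`), plus an attribute
#'   `skipped` giving the number of CDSs that could not be translated.
#' @export
read_genbank_cds <- function(paths) {
  recs <- list()
  skipped <- 0L
  for (path in paths) {
    if (!file.exists(path)) stop("GenBank file not found: ", path)
    lines <- readLines(path, warn = FALSE)
    if (!length(lines) || !any(startsWith(lines, "LOCUS"))) {
      stop("not a GenBank flat file (no LOCUS line): ", path)
    }
    if (!any(trimws(lines) == "//")) {
      stop("truncated GenBank file (missing '//' terminator): ", path)
    }
    starts <- which(startsWith(lines, "LOCUS"))
    ends <- which(trimws(lines) == "//")
    for (i in seq_along(starts)) {
      end <- ends[ends > starts[i]][1]
      if (is.na(end)) stop("truncated GenBank record in ", path)
      out <- parse_genbank_record(lines[starts[i]:end], path)
      skipped <- skipped + out$skipped
      recs[[length(recs) + 1L]] <- out$cds
    }
  }
  df <- do.call(rbind, c(recs, list(empty_cds_frame())))
  rownames(df) <- NULL
  attr(df, "skipped") <- skipped
  df
}

empty_cds_frame <- function() {
  data.frame(genome_accession = character(), protein_id = character(),
             product = character(), sequence = character(),
             record_date = as.Date(character()), stringsAsFactors = FALSE)
}

parse_genbank_record <- function(lines, path) {
  locus <- lines[1]
  date <- parse_locus_date(locus)
  acc <- sub("^ACCESSION\\s+(\\S+).*$", "\\1",
             grep("^ACCESSION\\s+\\S", lines, value = TRUE)[1])
  if (is.na(acc)) acc <- strsplit(trimws(sub("^LOCUS", "", locus)), "\\s+")[[1]][1]

  ori_at <- grep("^ORIGIN", lines)
  genome <- NULL
  if (length(ori_at)) {
    seqlines <- lines[(ori_at[1] + 1L):(length(lines) - 1L)]
    genome <- toupper(gsub("[^A-Za-z]", "", paste(seqlines, collapse = "")))
  }

  feat_at <- grep("^FEATURES", lines)
  cds <- empty_cds_frame()
  skipped <- 0L
  if (length(feat_at)) {
    feat_end <- if (length(ori_at)) ori_at[1] - 1L else length(lines) - 1L
    flines <- lines[(feat_at[1] + 1L):feat_end]
    # feature boundaries: a non-blank key in columns 6-20
    key_at <- grep("^ {5}\\S", flines)
    for (j in seq_along(key_at)) {
      key <- sub("^\\s+", "", substr(flines[key_at[j]], 1, 20))
      key <- sub("\\s.*$", "", key)
      if (key != "CDS") next
      stop_at <- if (j < length(key_at)) key_at[j + 1L] - 1L else length(flines)
      block <- flines[key_at[j]:stop_at]
      rec <- parse_cds_feature(block, genome)
      if (is.null(rec)) skipped <- skipped + 1L else {
        cds <- rbind(cds, data.frame(
          genome_accession = acc, protein_id = rec$protein_id,
          product = rec$product, sequence = rec$sequence,
          record_date = date, stringsAsFactors = FALSE))
      }
    }
  }
  list(cds = cds, skipped = skipped)
}

parse_locus_date <- function(locus) {
  m <- regmatches(locus, regexpr("\\d{2}-[A-Z]{3}-\\d{4}", locus))
  if (!length(m)) stop("LOCUS line has no parseable date: ", locus)
  as.Date(m, format = "%d-%b-%Y")
}

parse_cds_feature <- function(block, genome) {
  # location is on the key line (and possible continuations before the first /)
  qual_at <- grep("^\\s{21}/", block)
  loc_end <- if (length(qual_at)) qual_at[1] - 1L else length(block)
  loc <- gsub("\\s", "", paste(sub("^\\s+CDS\\s+", "", block[1]),
                               paste(block[seq_len(loc_end)[-1]], collapse = ""),
                               sep = ""))
  loc <- gsub("\\s", "", sub("^CDS", "", loc))

  quals <- parse_qualifiers(block[seq_along(block) >= min(c(qual_at, Inf))])
  product <- if (!is.null(quals$product)) quals$product else ""
  pid <- if (!is.null(quals$protein_id)) quals$protein_id else NA_character_

  if (!is.null(quals$translation)) {
    seqaa <- toupper(gsub("[^A-Za-z*]", "", quals$translation))
  } else {
    seqaa <- translate_cds_location(loc, genome)
    if (is.null(seqaa)) return(NULL)
  }
  if (!nzchar(seqaa)) return(NULL)
  if (is.na(pid)) pid <- paste0("cds_", substr(digest_seq(seqaa), 1, 8))
  list(protein_id = pid, product = product, sequence = seqaa)
}

parse_qualifiers <- function(lines) {
  if (!length(lines)) return(list())
  txt <- sub("^\\s{21}", "", lines)
  starts <- grep("^/", txt)
  out <- list()
  for (j in seq_along(starts)) {
    stop_at <- if (j < length(starts)) starts[j + 1L] - 1L else length(txt)
    chunk <- paste(txt[starts[j]:stop_at], collapse = "")
    key <- sub("^/([A-Za-z_]+).*$", "\\1", chunk)
    val <- if (grepl("=", chunk)) sub("^/[A-Za-z_]+=", "", chunk) else ""
    val <- gsub("\"", "", val)
    out[[key]] <- val
  }
  out
}

translate_cds_location <- function(loc, genome) {
  if (is.null(genome) || !nzchar(genome)) return(NULL)
  comp <- grepl("^complement\\(", loc)
  span <- sub("^complement\\(", "", sub("\\)$", "", loc))
  if (!grepl("^<?\\d+\\.\\.>?\\d+$", span)) return(NULL)  # join() etc: skip
  bounds <- as.integer(gsub("[<>]", "", strsplit(span, "\\.\\.")[[1]]))
  if (bounds[2] > nchar(genome)) return(NULL)
  dna <- Biostrings::DNAString(substr(genome, bounds[1], bounds[2]))
  if (comp) dna <- Biostrings::reverseComplement(dna)
  if (length(dna) %% 3L != 0L) return(NULL)
  aa <- as.character(Biostrings::translate(
    dna, genetic.code = Biostrings::getGeneticCode("11"),
    if.fuzzy.codon = "X"))
  sub("\\*$", "", aa)
}

digest_seq <- function(s) {
  # tiny stable hash (FNV-style) for fallback protein ids
  v <- utf8ToInt(s)
  h <- 2166136261
  for (x in v) h <- ((h * 16777619) + x) %% 2^31
  sprintf("%08x", as.integer(h))
}
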