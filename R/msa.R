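#' Multiple sequence alignment container
#'
#' @param sequences Character vector of equal-length aligned sequences
#'   (gap character `-`).
#' @param ids Member identifiers (defaults to names of `sequences`).
#' @return Object of class `msa`.
#' @export
msa <- function(sequences, ids = names(sequences)) {
  sequences <- toupper(sequences)
  if (!length(sequences)) stop("an alignment needs at least one row")
  if (length(unique(nchar(sequences))) != 1) {
    stop("aligned sequences must all have the same length")
  }
  if (is.null(ids)) ids <- paste0("seq", seq_along(sequences))
  structure(list(ids = ids, sequences = unname(sequences)), class = "msa")
}

#' @export
print.msa <- function(x, ...) {
  cat(sprintf("MSA: %d sequences x %d columns\n", length(x$sequences),
              nchar(x$sequences[1])))
  invisible(x)
}

as_msa_matrix <- function(x) {
  seqs <- if (inherits(x, "msa")) x$sequences else as.character(x)
  if (length(unique(nchar(seqs))) != 1) stop("rows differ in length")
  do.call(rbind, strsplit(seqs, "", fixed = TRUE))
}

# identity-scoring substitution matrix for pairwise alignment
identity_submat <- function() {
  alph <- aa_alphabet()
  m <- matrix(-1L, 20, 20, dimnames = list(alph, alph))
  diag(m) <- 2L
  m
}

align_pair <- function(a, b) {
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    substitutionMatrix = identity_submat(),
    gapOpening = 10, gapExtension = 0.5, type = "global")
  list(a = as.character(Biostrings::alignedPattern(aln)),
       b = as.character(Biostrings::alignedSubject(aln)))
}

#' Global pairwise identity normalized by the shorter sequence
#'
#' Identity = identical aligned positions / length of the shorter sequence
#' (the CD-HIT convention), from a global alignment with identity scoring.
#' @param a,b Protein sequences.
#' @return Identity in `[0, 1]`.
#' @export
pairwise_identity <- function(a, b) {
  if (a == b) return(1)
  al <- align_pair(a, b)
  x <- strsplit(al$a, "")[[1]]
  y <- strsplit(al$b, "")[[1]]
  sum(x == y & x != "-") / min(nchar(a), nchar(b))
}

#' Center-star progressive multiple alignment
#'
#' Aligns every member to a center sequence pairwise and merges the pairwise
#' alignments column-wise ("once a gap, always a gap"): insertions relative
#' to the center open gap blocks shared by all rows.
#'
#' @param sequences Named character vector; the center is `sequences[center]`.
#' @param center Index of the center (star) sequence, default 1.
#' @return An [msa] with the center as the first row.
#' @export
align_center_star <- function(sequences, center = 1) {
  ids <- names(sequences)
  if (is.null(ids)) ids <- paste0("seq", seq_along(sequences))
  c_seq <- sequences[[center]]
  others <- setdiff(seq_along(sequences), center)
  if (!length(others)) return(msa(setNames(c_seq, ids[center])))

  Lc <- nchar(c_seq)
  # per member: residues aligned to each center position (or "-"), plus
  # insert strings after center positions 0..Lc
  profiles <- lapply(others, function(i) {
    al <- align_pair(c_seq, sequences[[i]])
    cc <- strsplit(al$a, "")[[1]]
    mm <- strsplit(al$b, "")[[1]]
    aligned <- character(Lc)
    inserts <- character(Lc + 1)
    inserts[] <- ""
    j <- 0L
    for (p in seq_along(cc)) {
      if (cc[p] == "-") {
        inserts[j + 1L] <- paste0(inserts[j + 1L], mm[p])
      } else {
        j <- j + 1L
        aligned[j] <- mm[p]
      }
    }
    list(aligned = aligned, inserts = inserts)
  })
  ins_len <- sapply(0:Lc + 1L, function(j) {
    max(c(0L, vapply(profiles, function(p) nchar(p$inserts[j]), 0L)))
  })
  pad <- function(s, n) paste0(s, strrep("-", n - nchar(s)))
  c_chars <- strsplit(c_seq, "")[[1]]
  build_row <- function(aligned, inserts) {
    out <- pad(inserts[1], ins_len[1])
    for (j in seq_len(Lc)) {
      out <- paste0(out, aligned[j], pad(inserts[j + 1L], ins_len[j + 1L]))
    }
    out
  }
  rows <- c(build_row(c_chars, rep("", Lc + 1)),
            vapply(profiles, function(p) build_row(p$aligned, p$inserts), ""))
  msa(rows, ids = c(ids[center], ids[others]))
}
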