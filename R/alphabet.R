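#' The 20 canonical amino acids, alphabetical one-letter codes
#'
#' Ordering is fixed package-wide: emission rows, k-mer indices and HMMER3
#' columns all use this order.
#' @return Character vector of length 20.
#' @export
aa_alphabet <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

#' Background amino-acid frequencies
#'
#' Robinson-Robinson amino-acid frequencies (the null model HMMER uses),
#' renormalized to sum exactly to 1, in [aa_alphabet()] order. These are the
#' reference distribution for all log-odds scores and for sampling linker /
#' decoy residues in the synthetic generators.
#' @return Named numeric vector of length 20 summing to 1.
#' @export
aa_background <- function() {
  p <- c(A = 0.0787945, C = 0.0151600, D = 0.0535222, E = 0.0668298,
         F = 0.0397062, G = 0.0695071, H = 0.0229198, I = 0.0590092,
         K = 0.0594422, L = 0.0963728, M = 0.0237718, N = 0.0414386,
         P = 0.0482904, Q = 0.0395639, R = 0.0540978, S = 0.0683364,
         T = 0.0540687, V = 0.0673417, W = 0.0114135, Y = 0.0304133)
  p / sum(p)
}

# integer encoding 1..20; NA for anything non-canonical
aa_encode <- function(seq) {
  match(strsplit(seq, "", fixed = TRUE)[[1]], aa_alphabet())
}

#' Test whether sequences use only the 20 canonical amino acids
#'
#' B, J, O, U, X, Z and the stop character `*` all count as non-canonical.
#' A single trailing `*` (a translated stop codon retained by some GenBank
#' submitters) is stripped before the check.
#' @param seqs Character vector of protein sequences.
#' @return Logical vector.
#' @export
is_canonical <- function(seqs) {
  seqs <- strip_stop(seqs)
  !grepl(paste0("[^", paste(aa_alphabet(), collapse = ""), "]"), seqs)
}

strip_stop <- function(seqs) sub("\\*$", "", toupper(seqs))

# sample n residues from the background distribution
sample_background <- function(n) {
  paste(sample(aa_alphabet(), n, replace = TRUE, prob = aa_background()),
        collapse = "")
}

# point-substitution mutation at the given per-residue rate; substitutions
# only, so mutated copies keep the parent's length
mutate_sequence <- function(seq, rate) {
  if (rate <= 0) return(seq)
  x <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- runif(length(x)) < rate
  if (any(hit)) {
    alph <- aa_alphabet()
    x[hit] <- vapply(x[hit], function(a) sample(setdiff(alph, a), 1), "")
  }
  paste(x, collapse = "")
}
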