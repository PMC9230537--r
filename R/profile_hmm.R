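#' Construct a profile HMM object
#'
#' A plain profile hidden Markov model over the 20 canonical amino acids,
#' with `L` match states, `L + 1` insert states (I0..IL; only I1..I(L-1)
#' take part in local scoring) and per-node transition probabilities. Rows of
#' the transition matrix correspond to nodes 0..L; columns are
#' `MM, MI, MD, IM, II, DM, DD` (node 0's `MM/MI/MD` are the begin
#' transitions).
#'
#' @param name Model name.
#' @param match_emissions `L x 20` row-stochastic matrix in [aa_alphabet()]
#'   column order.
#' @param insert_emissions `(L+1) x 20` row-stochastic matrix; defaults to
#'   the background at every insert state.
#' @param transitions `(L+1) x 7` matrix; each of the `(MM,MI,MD)`,
#'   `(IM,II)` and `(DM,DD)` blocks must sum to 1 per row.
#' @param background Length-20 background distribution.
#' @return An object of class `profile_hmm`.
#' @export
profile_hmm <- function(name, match_emissions, insert_emissions = NULL,
                        transitions = NULL, background = aa_background()) {
  L <- nrow(match_emissions)
  stopifnot(L >= 1, ncol(match_emissions) == 20)
  if (is.null(insert_emissions)) {
    insert_emissions <- matrix(rep(background, L + 1), nrow = L + 1,
                               byrow = TRUE)
  }
  if (is.null(transitions)) {
    transitions <- default_transitions(L)
  }
  h <- structure(list(name = name, L = L,
                      match_emissions = unname(match_emissions),
                      insert_emissions = unname(insert_emissions),
                      transitions = unname(transitions),
                      background = unname(background)),
                 class = "profile_hmm")
  validate_profile_hmm(h)
  h
}

# plausible defaults: stay on the match track with prob .9
default_transitions <- function(L) {
  t <- matrix(rep(c(0.9, 0.05, 0.05, 0.9, 0.1, 0.9, 0.1), L + 1),
              nrow = L + 1, byrow = TRUE,
              dimnames = list(NULL, c("MM", "MI", "MD", "IM", "II", "DM", "DD")))
  t[1, ] <- c(1, 0, 0, 1, 0, 1, 0)          # begin -> M1
  t[L + 1, ] <- c(1, 0, 0, 1, 0, 1, 0)      # node L: exit only
  t
}

validate_profile_hmm <- function(h) {
  tol <- 1e-9
  check_rows <- function(m, what) {
    if (any(m < -tol)) stop(h$name, ": negative probability in ", what)
    if (any(abs(rowSums(m) - 1) > 1e-9)) {
      stop(h$name, ": ", what, " rows do not sum to 1")
    }
  }
  check_rows(h$match_emissions, "match emission")
  check_rows(h$insert_emissions, "insert emission")
  tr <- h$transitions
  stopifnot(nrow(tr) == h$L + 1, ncol(tr) == 7)
  for (blk in list(1:3, 4:5, 6:7)) {
    s <- rowSums(tr[, blk, drop = FALSE])
    if (any(abs(s - 1) > 1e-9)) stop(h$name, ": transition block does not sum to 1")
  }
  invisible(h)
}

#' @export
print.profile_hmm <- function(x, ...) {
  cat(sprintf("Profile HMM '%s': %d match states\n", x$name, x$L))
  cons <- paste(aa_alphabet()[apply(x$match_emissions, 1, which.max)],
                collapse = "")
  cat("  consensus:", if (nchar(cons) > 60) paste0(substr(cons, 1, 60), "...") else cons, "\n")
  invisible(x)
}

#' Build a profile HMM from a multiple sequence alignment
#'
#' Alignment columns whose gap fraction is at most `gap_fraction_threshold`
#' become match states; the remaining columns feed insert-state transition
#' counts. Match emissions are Laplace-smoothed observed counts (uniform
#' sequence weights, `pseudocount` added to each of the 20 residues); insert
#' emissions are fixed at the background. Transition probabilities are
#' Laplace-smoothed observed state-path counts.
#'
#' @param msa An [msa] object (or matrix/character vector of equal-length
#'   aligned sequences, gap = `-`).
#' @param name Model name.
#' @param gap_fraction_threshold Maximum gap fraction for a match column
#'   (default 0.5, the usual fast heuristic).
#' @param pseudocount Additive pseudocount (default 1).
#' @param background Background distribution for log-odds scoring.
#' @return A `profile_hmm`.
#' @export
build_from_msa <- function(msa, name = "custom",
                           gap_fraction_threshold = 0.5, pseudocount = 1,
                           background = aa_background()) {
  rows <- as_msa_matrix(msa)
  nseq <- nrow(rows)
  gap_frac <- colMeans(rows == "-")
  is_match <- gap_frac <= gap_fraction_threshold
  L <- sum(is_match)
  if (L == 0) stop("alignment has no match columns at gap threshold ",
                   gap_fraction_threshold)

  alph <- aa_alphabet()
  match_cols <- which(is_match)
  me <- matrix(pseudocount, nrow = L, ncol = 20)
  for (k in seq_len(L)) {
    col <- rows[, match_cols[k]]
    cnt <- table(factor(col[col != "-"], levels = alph))
    me[k, ] <- me[k, ] + as.numeric(cnt)
  }
  me <- me / rowSums(me)

  # transition counts from per-sequence state paths
  tc <- matrix(pseudocount, nrow = L + 1, ncol = 7,
               dimnames = list(NULL, c("MM", "MI", "MD", "IM", "II", "DM", "DD")))
  node_of_col <- cumsum(is_match)          # node index for match cols
  for (s in seq_len(nseq)) {
    prev_state <- "M"; prev_node <- 0L     # begin treated as node-0 match
    for (j in seq_len(ncol(rows))) {
      res <- rows[s, j]
      if (is_match[j]) {
        st <- if (res == "-") "D" else "M"
        nd <- node_of_col[j]
      } else {
        if (res == "-") next
        st <- "I"; nd <- prev_node
      }
      key <- paste0(prev_state, st)
      col7 <- match(key, c("MM", "MI", "MD", "IM", "II", "DM", "DD"))
      from_node <- if (prev_state == "I") prev_node else prev_node
      if (!is.na(col7)) tc[from_node + 1L, col7] <- tc[from_node + 1L, col7] + 1
      prev_state <- st; prev_node <- nd
    }
  }
  tr <- tc
  tr[, 1:3] <- tc[, 1:3] / rowSums(tc[, 1:3])
  tr[, 4:5] <- tc[, 4:5] / rowSums(tc[, 4:5])
  tr[, 6:7] <- tc[, 6:7] / rowSums(tc[, 6:7])
  tr[L + 1, ] <- c(1, 0, 0, 1, 0, 1, 0)    # last node exits

  profile_hmm(name, me, transitions = tr, background = background)
}

#' Score a sequence against a profile HMM (local Viterbi)
#'
#' Maximum log-odds (model vs background, base 2) over all local alignments:
#' paths that enter the model at any match state, traverse
#' match/insert/delete states, and leave from any match state. Entry and
#' exit are free; emissions are scored in log2 odds against the model
#' background and transitions contribute their log2 probabilities.
#'
#' @param hmm A `profile_hmm`.
#' @param seq Protein sequence (canonical residues only).
#' @return List with `bit_score`, `ali_start`, `ali_end` (1-based inclusive
#'   residue coordinates of the best-scoring alignment).
#' @export
viterbi_score <- function(hmm, seq) {
  stopifnot(inherits(hmm, "profile_hmm"))
  if (!nzchar(seq)) stop("cannot score an empty sequence")
  x <- aa_encode(strip_stop(seq))
  if (anyNA(x)) stop("sequence contains non-canonical residues")
  sc <- hmm_score_tables(hmm)
  res <- .viterbi_local(sc$lm, sc$li, sc$lt, x - 1L)
  res
}

hmm_score_tables <- function(hmm) {
  bg <- hmm$background
  lm <- log2(sweep(hmm$match_emissions, 2, bg, "/"))
  li <- log2(sweep(hmm$insert_emissions[-1, , drop = FALSE], 2, bg, "/"))
  lt <- log2(hmm$transitions[-1, , drop = FALSE])
  list(lm = lm, li = li, lt = lt)
}

#' Scan a sequence against a set of profile HMMs
#'
#' Reports, for each HMM whose best local Viterbi score reaches the bit
#' threshold, its single best hit on the target.
#'
#' @param seq Protein sequence.
#' @param hmm_set List of `profile_hmm` objects (an `hmm_set`).
#' @param threshold Bit-score threshold for calling a hit (default 25).
#' @param target_id Identifier recorded in the hits.
#' @return data.frame of hits (`target_id`, `hmm_name`, `ali_start`,
#'   `ali_end`, `bit_score`), sorted by `ali_start`; zero rows if nothing
#'   reaches the threshold.
#' @export
scan_sequence <- function(seq, hmm_set, threshold = 25, target_id = "query") {
  if (!length(hmm_set)) stop("empty HMM set")
  hits <- lapply(hmm_set, function(h) {
    r <- viterbi_score(h, seq)
    if (r$bit_score >= threshold) {
      data.frame(target_id = target_id, hmm_name = h$name,
                 ali_start = r$ali_start, ali_end = r$ali_end,
                 bit_score = r$bit_score, stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, hits)
  if (is.null(out)) {
    out <- data.frame(target_id = character(), hmm_name = character(),
                      ali_start = integer(), ali_end = integer(),
                      bit_score = numeric(), stringsAsFactors = FALSE)
  }
  out <- out[order(out$ali_start, out$hmm_name), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Scan many sequences against a set of profile HMMs
#'
#' @param seqs Named character vector of protein sequences.
#' @inheritParams scan_sequence
#' @return One hits data.frame (row-bound over targets).
#' @export
scan_sequences <- function(seqs, hmm_set, threshold = 25) {
  ids <- names(seqs)
  if (is.null(ids)) ids <- paste0("seq", seq_along(seqs))
  out <- mapply(function(s, id) scan_sequence(s, hmm_set, threshold, id),
                seqs, ids, SIMPLIFY = FALSE)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
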