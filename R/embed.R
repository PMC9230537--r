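#' Fixed-length protein embeddings
#'
#' Computes one fixed-length numeric vector per protein. The built-in
#' embedder is a deterministic hashed k-mer frequency representation
#' (default k = 3, d = 400): each k-mer index is mapped to a bucket by a
#' fixed multiplicative hash and the bucket counts are normalized to sum
#' to 1. Embeddings from a pretrained protein language model (d = 1024)
#' can be supplied instead as a precomputed matrix wherever an
#' `EmbeddingMatrix` is accepted; this package does not ship model weights.
#'
#' @param seqs Named character vector of protein sequences.
#' @param k K-mer length (default 3).
#' @param d Embedding dimension (default 400).
#' @return Numeric matrix `n x d`, rownames = protein ids, with attributes
#'   `embedder` (tag) and `schema`.
#' @export
embed_sequences <- function(seqs, k = 3, d = 400) {
  ids <- names(seqs)
  if (is.null(ids)) ids <- paste0("seq", seq_along(seqs))
  X <- matrix(0, nrow = length(seqs), ncol = d,
              dimnames = list(ids, paste0("e", seq_len(d))))
  for (i in seq_along(seqs)) {
    x <- aa_encode(strip_stop(seqs[[i]]))
    if (anyNA(x)) stop("non-canonical residue in sequence ", ids[i])
    n <- length(x) - k + 1L
    if (n < 1L) next
    idx <- rep(0, n)
    for (j in seq_len(k)) idx <- idx * 20 + (x[j:(j + n - 1L)] - 1)
    bucket <- ((idx * 2654435761) %% 2147483647) %% d + 1
    tab <- tabulate(bucket, nbins = d)
    X[i, ] <- tab / sum(tab)
  }
  attr(X, "embedder") <- sprintf("kmer-hash-k%d-d%d", k, d)
  attr(X, "schema") <- list(embed_dim = d, hmm_names = character())
  X
}

#' Per-protein HMM bit-score features
#'
#' Best local Viterbi bit score of every HMM on every protein, with 0 for
#' proteins the HMM does not hit at the threshold. Column order follows the
#' HMM set and is recorded so fused feature blocks are reproducible.
#'
#' @param seqs Named character vector of proteins.
#' @param hmm_set List of `profile_hmm`.
#' @param threshold Bit threshold below which a score is zeroed (default 25).
#' @return Numeric matrix `n x |hmm_set|` (columns named by HMM).
#' @export
hmm_score_features <- function(seqs, hmm_set, threshold = 25) {
  ids <- names(seqs)
  hmm_names <- vapply(hmm_set, function(h) h$name, "")
  S <- matrix(0, nrow = length(seqs), ncol = length(hmm_set),
              dimnames = list(ids, hmm_names))
  for (i in seq_along(seqs)) {
    for (j in seq_along(hmm_set)) {
      sc <- viterbi_score(hmm_set[[j]], seqs[[i]])$bit_score
      if (sc >= threshold) S[i, j] <- sc
    }
  }
  S
}

#' Fuse embeddings with HMM score features
#'
#' Column-wise concatenation of an embedding matrix and a per-protein HMM
#' bit-score block (same proteins, same order). The schema attribute
#' records the HMM block so a fitted model can verify its input layout.
#'
#' @param embeddings `n x d` matrix from [embed_sequences()] (or a
#'   precomputed language-model embedding matrix with rownames).
#' @param hmm_scores `n x m` matrix from [hmm_score_features()].
#' @return `n x (d + m)` matrix.
#' @export
fuse_features <- function(embeddings, hmm_scores) {
  if (is.null(rownames(embeddings)) || is.null(rownames(hmm_scores))) {
    stop("both blocks need protein ids as rownames")
  }
  if (!identical(rownames(embeddings), rownames(hmm_scores))) {
    stop("protein ids of the two feature blocks do not match")
  }
  X <- cbind(embeddings, hmm_scores)
  attr(X, "embedder") <- attr(embeddings, "embedder")
  attr(X, "schema") <- list(embed_dim = ncol(embeddings),
                            hmm_names = colnames(hmm_scores))
  X
}
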