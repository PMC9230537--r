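#' Call the N/C domain architecture of a target
#'
#' Phage receptor-binding proteins are modular: structural domains sit in
#' the N-terminal region and cleaving/binding/chaperone domains in the
#' C-terminal region. Hits starting within the first 200 residues are
#' assigned to the N-terminal side (the cutoff residue included); hits
#' starting later are C-terminal.
#'
#' @param target_id Target identifier.
#' @param hits Hits data.frame from [scan_sequence()] for this target.
#' @param n_cutoff N/C boundary residue (default 200).
#' @return Object of class `architecture`: `target_id`, `n_terminal` and
#'   `c_terminal` hit data.frames (ordered by `ali_start`) and `signature`,
#'   the ordered tuple of HMM names N to C.
#' @export
call_architecture <- function(target_id, hits, n_cutoff = 200) {
  hits <- hits[hits$target_id == target_id, , drop = FALSE]
  hits <- hits[order(hits$ali_start, hits$hmm_name), , drop = FALSE]
  n_side <- hits[hits$ali_start <= n_cutoff, , drop = FALSE]
  c_side <- hits[hits$ali_start > n_cutoff, , drop = FALSE]
  structure(list(target_id = target_id,
                 n_terminal = n_side, c_terminal = c_side,
                 signature = c(n_side$hmm_name, c_side$hmm_name)),
            class = "architecture")
}

#' @export
print.architecture <- function(x, ...) {
  sig <- if (length(x$signature)) paste(x$signature, collapse = " > ") else "(none)"
  cat(sprintf("%s: %s  [N: %d, C: %d]\n", x$target_id, sig,
              nrow(x$n_terminal), nrow(x$c_terminal)))
  invisible(x)
}

#' Call architectures for a set of targets
#'
#' @param hits Combined hits data.frame (from [scan_sequences()]).
#' @param target_ids All target ids to report (targets without hits get an
#'   empty architecture).
#' @inheritParams call_architecture
#' @return Named list of `architecture` objects.
#' @export
call_architectures <- function(hits, target_ids, n_cutoff = 200) {
  out <- lapply(target_ids, call_architecture, hits = hits,
                n_cutoff = n_cutoff)
  names(out) <- target_ids
  out
}

#' Domain-based RBP designation
#'
#' A protein is designated an RBP when at least one domain of the assembled
#' RBP-related HMM set is recognized on it, at either terminus.
#' @param architecture An `architecture`.
#' @return Logical scalar.
#' @export
is_rbp_by_domains <- function(architecture) {
  nrow(architecture$n_terminal) + nrow(architecture$c_terminal) >= 1
}

#' Find proteins with a domain at only one terminus
#'
#' @param architectures List of `architecture` objects.
#' @return List with `missing_N` (ids with C-side hits but no N-side hit)
#'   and `missing_C` (ids with N-side hits but no C-side hit).
#' @export
find_one_sided <- function(architectures) {
  nN <- vapply(architectures, function(a) nrow(a$n_terminal), 0L)
  nC <- vapply(architectures, function(a) nrow(a$c_terminal), 0L)
  ids <- vapply(architectures, function(a) a$target_id, "")
  list(missing_N = unname(ids[nN == 0 & nC > 0]),
       missing_C = unname(ids[nN > 0 & nC == 0]))
}

#' Extract unknown terminus parts from one-sided proteins
#'
#' For proteins missing an N-terminal domain, the N part is residues 1 to
#' min(200, length); for proteins missing a C-terminal domain, the C part
#' starts one residue after the end of the last N-side hit and runs to the
#' end of the protein. Empty C parts (the last N hit reaches the terminus)
#' are dropped.
#'
#' @param one_sided Result of [find_one_sided()].
#' @param architectures List of `architecture` objects (named by target).
#' @param seqs Named character vector of full-length protein sequences.
#' @param n_cutoff N/C boundary residue (default 200).
#' @return data.frame of parts: `parent_id`, `side`, `start`, `end`,
#'   `sequence`.
#' @export
extract_parts <- function(one_sided, architectures, seqs, n_cutoff = 200) {
  rows <- list()
  for (id in one_sided$missing_N) {
    len <- nchar(seqs[[id]])
    end <- min(n_cutoff, len)
    rows[[length(rows) + 1L]] <- data.frame(
      parent_id = id, side = "N", start = 1L, end = end,
      sequence = substr(seqs[[id]], 1, end), stringsAsFactors = FALSE)
  }
  dropped <- 0L
  for (id in one_sided$missing_C) {
    len <- nchar(seqs[[id]])
    last_n <- max(architectures[[id]]$n_terminal$ali_end)
    if (last_n >= len) { dropped <- dropped + 1L; next }
    rows[[length(rows) + 1L]] <- data.frame(
      parent_id = id, side = "C", start = last_n + 1L, end = len,
      sequence = substr(seqs[[id]], last_n + 1L, len), stringsAsFactors = FALSE)
  }
  if (dropped) message(dropped, " empty C-terminal part(s) dropped")
  out <- do.call(rbind, c(rows, list(data.frame(
    parent_id = character(), side = character(), start = integer(),
    end = integer(), sequence = character(), stringsAsFactors = FALSE))))
  rownames(out) <- NULL
  out
}

#' Greedy incremental clustering of terminus parts
#'
#' CD-HIT-style clustering: parts are sorted by length (descending, stable)
#' and each joins the first existing cluster whose representative it matches
#' at or above the identity threshold (global identity normalized by the
#' shorter sequence); otherwise it founds a new cluster.
#'
#' @param parts data.frame of parts of one side (from [extract_parts()]).
#' @param identity_threshold Identity threshold in `[0, 1]` (default 0.9).
#' @return List of clusters; each has `representative` (parent id),
#'   `members` (data.frame subset of `parts`) and `identity_threshold`.
#' @export
greedy_cluster <- function(parts, identity_threshold = 0.9) {
  if (!nrow(parts)) return(list())
  if (length(unique(parts$side)) > 1) {
    stop("cluster N-terminal and C-terminal parts separately")
  }
  ord <- order(-nchar(parts$sequence))
  parts <- parts[ord, , drop = FALSE]
  clusters <- list()
  for (i in seq_len(nrow(parts))) {
    placed <- FALSE
    for (ci in seq_along(clusters)) {
      idty <- pairwise_identity(clusters[[ci]]$rep_seq, parts$sequence[i])
      if (idty >= identity_threshold) {
        clusters[[ci]]$members <- rbind(clusters[[ci]]$members,
                                        parts[i, , drop = FALSE])
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      clusters[[length(clusters) + 1L]] <- list(
        representative = parts$parent_id[i],
        rep_seq = parts$sequence[i],
        members = parts[i, , drop = FALSE],
        identity_threshold = identity_threshold)
    }
  }
  clusters
}

#' Align the members of one cluster
#'
#' Clusters with at least `min_members` sequences (default 5) are aligned by
#' center-star progressive alignment around the representative; smaller
#' clusters are skipped.
#'
#' @param cluster One cluster from [greedy_cluster()].
#' @param min_members Minimum cluster size to align.
#' @return An [msa], or `NULL` if the cluster is too small.
#' @export
align_cluster <- function(cluster, min_members = 5) {
  n <- nrow(cluster$members)
  if (n < min_members) {
    message("cluster of ", n, " < ", min_members, " members: skipped")
    return(NULL)
  }
  seqs <- setNames(cluster$members$sequence, cluster$members$parent_id)
  align_center_star(seqs, center = 1)
}

#' Build custom HMMs for unknown termini and augment the HMM set
#'
#' The full custom-HMM construction pipeline: scan the training proteins
#' with the base HMM set, find one-sided architectures, extract the unknown
#' N/C parts, cluster each side greedily, align clusters of five or more
#' members, build a profile HMM per aligned cluster
#' (named `custom_N_<k>` / `custom_C_<k>`), and re-scan with the augmented
#' set to count the detections gained.
#'
#' @param seqs Named character vector of training proteins (annotated RBPs).
#' @param base_hmms List of `profile_hmm` (the curated base set).
#' @param threshold Hit-calling bit threshold (default 25).
#' @param identity_threshold Clustering identity threshold (default 0.9).
#' @param min_members Minimum cluster size for HMM construction (default 5).
#' @param n_cutoff N/C boundary residue (default 200).
#' @return List with `hmm_set` (augmented), `new_hmms`, `architectures`
#'   (under the base set) and `report` (counts per stage, plus
#'   `newly_detected`: proteins with no base-set hit that gain one, and
#'   `custom_hit_proteins`: proteins hit by at least one custom HMM).
#' @export
construct_custom_hmms <- function(seqs, base_hmms, threshold = 25,
                                  identity_threshold = 0.9, min_members = 5,
                                  n_cutoff = 200) {
  ids <- names(seqs)
  hits <- scan_sequences(seqs, base_hmms, threshold)
  archs <- call_architectures(hits, ids, n_cutoff)
  one_sided <- find_one_sided(archs)
  parts <- extract_parts(one_sided, archs, seqs, n_cutoff)

  new_hmms <- list()
  n_clusters <- c(N = 0L, C = 0L)
  n_built <- c(N = 0L, C = 0L)
  for (side in c("N", "C")) {
    cl <- greedy_cluster(parts[parts$side == side, , drop = FALSE],
                         identity_threshold)
    n_clusters[side] <- length(cl)
    for (c1 in cl) {
      al <- suppressMessages(align_cluster(c1, min_members))
      if (is.null(al)) next
      n_built[side] <- n_built[side] + 1L
      nm <- sprintf("custom_%s_%d", side, n_built[side])
      new_hmms[[nm]] <- build_from_msa(al, name = nm)
    }
  }

  augmented <- c(base_hmms, new_hmms)
  names(augmented) <- vapply(augmented, function(h) h$name, "")
  rescan <- scan_sequences(seqs, augmented, threshold)
  pos_before <- unique(hits$target_id)
  pos_after <- unique(rescan$target_id)
  custom_hits <- rescan[rescan$hmm_name %in% names(new_hmms), , drop = FALSE]

  report <- list(
    n_input = length(seqs),
    n_detected_base = length(pos_before),
    n_one_sided_missing_N = length(one_sided$missing_N),
    n_one_sided_missing_C = length(one_sided$missing_C),
    n_parts = c(N = sum(parts$side == "N"), C = sum(parts$side == "C")),
    n_clusters = n_clusters,
    n_built = n_built,
    newly_detected = length(setdiff(pos_after, pos_before)),
    custom_hit_proteins = length(unique(custom_hits$target_id)))

  list(hmm_set = augmented, new_hmms = new_hmms, architectures = archs,
       report = report)
}
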