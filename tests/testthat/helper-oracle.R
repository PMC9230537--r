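# Independent oracles used to check the implementation.

# Brute-force local Viterbi by exhaustive path enumeration. A local path
# starts at any match state on any residue, walks M/I/D transitions, and is
# scored at every match state it visits (free entry and exit). Feasible for
# L <= 4 and sequences <= 6 residues.
oracle_viterbi <- function(hmm, seq) {
  x <- match(strsplit(seq, "", fixed = TRUE)[[1]], aa_alphabet())
  L <- hmm$L
  bg <- hmm$background
  em <- log2(sweep(hmm$match_emissions, 2, bg, "/"))
  ei <- log2(sweep(hmm$insert_emissions[-1, , drop = FALSE], 2, bg, "/"))
  lt <- log2(hmm$transitions[-1, , drop = FALSE])  # nodes 1..L; MM MI MD IM II DM DD
  n <- length(x)
  best <- -Inf
  walk <- function(type, k, i, sc) {
    if (type == "M") {
      best <<- max(best, sc)
      if (k < L) {
        if (i < n) walk("M", k + 1, i + 1, sc + lt[k, 1] + em[k + 1, x[i + 1]])
        if (i < n) walk("I", k, i + 1, sc + lt[k, 2] + ei[k, x[i + 1]])
        walk("D", k + 1, i, sc + lt[k, 3])
      }
    } else if (type == "I") {
      if (i < n) walk("I", k, i + 1, sc + lt[k, 5] + ei[k, x[i + 1]])
      if (i < n) walk("M", k + 1, i + 1, sc + lt[k, 4] + em[k + 1, x[i + 1]])
    } else {
      if (k < L) {
        walk("D", k + 1, i, sc + lt[k, 7])
        if (i < n) walk("M", k + 1, i + 1, sc + lt[k, 6] + em[k + 1, x[i + 1]])
      }
    }
  }
  for (i0 in seq_len(n)) {
    for (k0 in seq_len(L)) walk("M", k0, i0, em[k0, x[i0]])
  }
  best
}

# random fully-specified profile HMM for oracle comparison
random_toy_hmm <- function(L) {
  rdir <- function(n) {
    g <- stats::rgamma(n, 1)
    g / sum(g)
  }
  me <- t(replicate(L, rdir(20)))
  ie <- t(replicate(L + 1, rdir(20)))
  tr <- t(replicate(L + 1, c(rdir(3), rdir(2), rdir(2))))
  tr[L + 1, ] <- c(1, 0, 0, 1, 0, 1, 0)
  profile_hmm("toy", me, ie, tr)
}

random_aa_seq <- function(n) {
  paste(sample(aa_alphabet(), n, replace = TRUE), collapse = "")
}

# direct set-algebra recomputation of Venn region counts
oracle_regions <- function(sets, positives) {
  m <- length(sets)
  combos <- expand.grid(rep(list(c(FALSE, TRUE)), m))[-1, , drop = FALSE]
  counts <- apply(combos, 1, function(z) {
    inside <- positives
    for (j in seq_len(m)) {
      inside <- if (z[j]) intersect(inside, sets[[j]]) else setdiff(inside, sets[[j]])
    }
    length(inside)
  })
  names(counts) <- apply(combos, 1, function(z) {
    paste(names(sets)[as.logical(z)], collapse = "&")
  })
  counts
}

# minimal handwritten GenBank record text, for parser tests
toy_genbank_text <- function() {
  c("LOCUS       TOYPHG01               1200 bp    DNA     linear   PHG 15-AUG-2021",
    "DEFINITION  Toy phage genome.",
    "ACCESSION   TOYPHG01",
    "FEATURES             Location/Qualifiers",
    "     source          1..1200",
    "     CDS             1..903",
    "                     /product=\"tail fiber protein\"",
    "                     /protein_id=\"TOY_0001\"",
    paste0("                     /translation=\"",
           paste(rep("MKT", 100), collapse = ""), "\""),
    "     CDS             10..18",
    "                     /product=\"holin\"",
    "                     /protein_id=\"TOY_0002\"",
    "                     /translation=\"MKH\"",
    "//")
}
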