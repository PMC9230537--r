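#' Read and write HMMER3 ASCII profile files
#'
#' `write_hmmer3()` serializes profile HMMs to the `HMMER3/f` ASCII dialect
#' (probabilities stored as negative natural logs to five decimals, `*` for
#' probability zero); `read_hmmer3()` parses files in that dialect,
#' including files produced by HMMER's own `hmmbuild` (unknown header lines
#' and per-node annotation columns are ignored). A write-read-write cycle is
#' byte-identical from the second write on; probabilities survive a round
#' trip to within the file format's five-decimal precision (about 1e-4).
#'
#' @param path File path.
#' @return `read_hmmer3()` returns a list of [profile_hmm] objects (named by
#'   model name); `write_hmmer3()` returns `path` invisibly.
#' @export
read_hmmer3 <- function(path) {
  lines <- readLines(path, warn = FALSE)
  starts <- grep("^HMMER3/", lines)
  if (!length(starts)) stop("not a HMMER3 ASCII file: ", path)
  ends <- which(trimws(lines) == "//")
  hmms <- list()
  for (s in starts) {
    e <- ends[ends > s][1]
    if (is.na(e)) stop("profile starting at line ", s, " has no '//' terminator")
    h <- parse_hmmer3_profile(lines[s:e], s)
    hmms[[h$name]] <- h
  }
  hmms
}

parse_hmmer3_profile <- function(lines, offset) {
  name <- NULL
  leng <- NULL
  hmm_at <- NULL
  for (i in seq_along(lines)) {
    tok <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (!length(tok)) next
    if (tok[1] == "NAME") name <- tok[2]
    if (tok[1] == "LENG") leng <- as.integer(tok[2])
    if (tok[1] == "ALPH" && tolower(tok[2]) != "amino") {
      stop("unsupported alphabet '", tok[2], "' at line ", offset + i - 1)
    }
    if (tok[1] == "HMM") { hmm_at <- i; break }
  }
  if (is.null(name) || is.null(leng) || is.null(hmm_at)) {
    stop("malformed HMMER3 header near line ", offset)
  }
  body <- lines[(hmm_at + 2L):length(lines)]   # skip transition-label line
  body <- body[trimws(body) != "//"]
  vals <- function(line, lineno) {
    tok <- strsplit(trimws(line), "\\s+")[[1]]
    suppressWarnings(v <- ifelse(tok == "*", Inf, as.numeric(tok)))
    if (anyNA(v)) v[is.na(v)] <- NaN
    list(tok = tok, p = exp(-v))
  }
  i <- 1L
  background <- aa_background()
  if (grepl("^\\s*COMPO\\s", body[i])) {
    v <- vals(body[i])
    background <- v$p[-1]
    if (length(background) != 20 || anyNA(background)) {
      stop("malformed COMPO line near line ", offset + hmm_at + 1)
    }
    i <- i + 1L
  }
  ins0 <- vals(body[i])$p
  tr0 <- vals(body[i + 1L])$p
  if (length(ins0) != 20 || length(tr0) != 7) {
    stop("malformed node-0 lines near line ", offset + hmm_at + i)
  }
  i <- i + 2L
  me <- matrix(NA_real_, leng, 20)
  ie <- matrix(NA_real_, leng + 1, 20)
  tr <- matrix(NA_real_, leng + 1, 7)
  ie[1, ] <- ins0
  tr[1, ] <- tr0
  for (k in seq_len(leng)) {
    if (i + 2L > length(body) + 1L) stop("truncated profile '", name, "'")
    m <- vals(body[i])
    if (is.na(suppressWarnings(as.integer(m$tok[1]))) ||
        as.integer(m$tok[1]) != k) {
      stop("expected node ", k, " of '", name, "' near line ",
           offset + hmm_at + i, " but found: ", trimws(body[i]))
    }
    me[k, ] <- m$p[2:21]
    ie[k + 1, ] <- vals(body[i + 1L])$p[1:20]
    tr[k + 1, ] <- vals(body[i + 2L])$p[1:7]
    i <- i + 3L
  }
  if (anyNA(me) || anyNA(ie) || anyNA(tr)) {
    stop("truncated emission/transition matrix in profile '", name, "'")
  }
  # renormalize away the fixed-precision storage error
  me <- me / rowSums(me)
  ie <- ie / rowSums(ie)
  for (blk in list(1:3, 4:5, 6:7)) {
    s <- rowSums(tr[, blk, drop = FALSE])
    s[s == 0] <- 1
    tr[, blk] <- tr[, blk, drop = FALSE] / s
  }
  tr[leng + 1, ] <- c(tr[leng + 1, 1:3] / sum(tr[leng + 1, 1:3]), 1, 0, 1, 0)
  profile_hmm(name, me, ie, tr, background / sum(background))
}

#' @rdname read_hmmer3
#' @param hmms A `profile_hmm` or list of them.
#' @export
write_hmmer3 <- function(hmms, path) {
  if (inherits(hmms, "profile_hmm")) hmms <- list(hmms)
  out <- unlist(lapply(hmms, format_hmmer3_profile))
  writeLines(out, path)
  invisible(path)
}

fmt_p <- function(p) {
  ifelse(p <= 0, sprintf("%8s", "*"), sprintf("%8.5f", -log(p)))
}

format_hmmer3_profile <- function(h) {
  stopifnot(inherits(h, "profile_hmm"))
  alph <- aa_alphabet()
  cons <- alph[apply(h$match_emissions, 1, which.max)]
  lines <- c(
    "HMMER3/f [rbpdetect profile format]",
    sprintf("NAME  %s", h$name),
    sprintf("LENG  %d", h$L),
    "ALPH  amino",
    "RF    no",
    "MM    no",
    "CONS  yes",
    "CS    no",
    "MAP   yes",
    paste0("HMM      ", paste(sprintf("%8s", alph), collapse = " ")),
    paste0("         ",
           paste(sprintf("%8s", c("m->m", "m->i", "m->d", "i->m", "i->i",
                                  "d->m", "d->d")), collapse = " ")),
    paste0("  COMPO  ", paste(fmt_p(h$background), collapse = " ")),
    paste0("         ", paste(fmt_p(h$insert_emissions[1, ]), collapse = " ")),
    paste0("         ", paste(fmt_p(h$transitions[1, ]), collapse = " "))
  )
  for (k in seq_len(h$L)) {
    lines <- c(lines,
      paste0(sprintf("%7d  ", k),
             paste(fmt_p(h$match_emissions[k, ]), collapse = " "),
             sprintf(" %6d %s - - -", k, cons[k])),
      paste0("         ", paste(fmt_p(h$insert_emissions[k + 1, ]), collapse = " ")),
      paste0("         ", paste(fmt_p(h$transitions[k + 1, ]), collapse = " ")))
  }
  c(lines, "//")
}
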