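#' Low-complexity-region detection parameters
#'
#' The two window criteria: (i) a single residue occupies at least
#' `single_min_frac` of each `window_len`-residue window, sustained over a
#' biased stretch of at least `single_min_run` residues ("more than 14");
#' (ii) the most abundant residue occupies at least `pair_first_min_frac`
#' and a second residue at least `pair_second_min_frac` of the window,
#' sustained over at least `pair_min_run` residues ("more than 19").
#' Fraction thresholds are applied as integer counts via ceiling
#' (5, 4 and 2 of a 10-residue window at the defaults), avoiding
#' floating-point comparisons.
#'
#' @param window_len sliding-window length in residues.
#' @param single_min_frac minimum fraction for the single-residue criterion.
#' @param single_min_run minimum biased-stretch length for single regions.
#' @param pair_first_min_frac minimum fraction of the most abundant residue.
#' @param pair_second_min_frac minimum fraction of the second residue.
#' @param pair_min_run minimum biased-stretch length for pair regions.
#' @return A named list of validated parameters, class `lcr_params`.
#' @export
lcr_params <- function(window_len = 10L, single_min_frac = 0.50,
                       single_min_run = 15L, pair_first_min_frac = 0.40,
                       pair_second_min_frac = 0.20, pair_min_run = 20L) {
  p <- list(window_len = as.integer(window_len),
            single_min_frac = single_min_frac,
            single_min_run = as.integer(single_min_run),
            pair_first_min_frac = pair_first_min_frac,
            pair_second_min_frac = pair_second_min_frac,
            pair_min_run = as.integer(pair_min_run))
  stopifnot(p$window_len >= 2L,
            p$single_min_frac > 0, p$single_min_frac <= 1,
            p$pair_first_min_frac > 0, p$pair_first_min_frac <= 1,
            p$pair_second_min_frac > 0, p$pair_second_min_frac <= 1,
            p$single_min_run >= p$window_len,
            p$pair_min_run >= p$window_len)
  class(p) <- "lcr_params"
  p
}

empty_lcr_frame <- function() {
  data.frame(protein_id = character(), kind = character(),
             residues = character(), label = character(),
             start = integer(), end = integer(), length = integer(),
             stringsAsFactors = FALSE)
}

# Per-window residue counts: matrix of n_windows x residues present.
# Row i holds counts within positions [i, i + window_len - 1].
window_counts <- function(chars, window_len) {
  n <- length(chars)
  nw <- n - window_len + 1L
  letters_present <- sort(unique(chars))
  counts <- vapply(letters_present, function(a) {
    cs <- c(0L, cumsum(chars == a))
    cs[(window_len + 1L):(n + 1L)] - cs[1L:nw]
  }, integer(nw))
  if (nw == 1L) counts <- matrix(counts, nrow = 1L,
                                 dimnames = list(NULL, letters_present))
  counts
}

#' Flag windows under the single-residue criterion
#'
#' A window starting at 1-based position `i` is flagged for residue `a` iff
#' `a` occurs at least `ceiling(single_min_frac * window_len)` times within
#' positions `[i, i + window_len - 1]`. `X` (unknown) counts in the window
#' denominator but is never flagged itself.
#'
#' @param sequence amino-acid string.
#' @param params an [lcr_params()] object.
#' @return Named list: residue letter -> integer vector of flagged window
#'   start positions (empty list if the sequence is shorter than the window).
#' @export
flag_windows_single <- function(sequence, params = lcr_params()) {
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1L]]
  if (length(chars) < params$window_len) return(list())
  thr <- as.integer(ceiling(params$single_min_frac * params$window_len))
  counts <- window_counts(chars, params$window_len)
  out <- list()
  for (a in colnames(counts)) {
    if (a == "X") next
    hits <- which(counts[, a] >= thr)
    if (length(hits) > 0L) out[[a]] <- as.integer(hits)
  }
  out
}

#' Flag windows under the two-residue criterion
#'
#' A window is flagged for the unordered pair \{X,Y\} iff the better-counted
#' member attains the maximum residue count of the window and occurs at
#' least `ceiling(pair_first_min_frac * window_len)` times, and the other
#' member occurs at least `ceiling(pair_second_min_frac * window_len)`
#' times. All qualifying pairs are emitted, so count ties produce multiple
#' pairs. `X` (unknown) is never part of a pair.
#'
#' @inheritParams flag_windows_single
#' @return Named list: two-letter alphabetized pair (e.g. `"GS"`) -> integer
#'   vector of flagged window start positions.
#' @export
flag_windows_pair <- function(sequence, params = lcr_params()) {
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1L]]
  if (length(chars) < params$window_len) return(list())
  thr1 <- as.integer(ceiling(params$pair_first_min_frac * params$window_len))
  thr2 <- as.integer(ceiling(params$pair_second_min_frac * params$window_len))
  counts <- window_counts(chars, params$window_len)
  letters_here <- setdiff(colnames(counts), "X")
  if (length(letters_here) < 2L) return(list())
  # the window maximum may be attained by 'X'-excluded letters only
  winmax <- apply(counts[, letters_here, drop = FALSE], 1L, max)
  out <- list()
  for (i in seq_len(length(letters_here) - 1L)) {
    for (j in (i + 1L):length(letters_here)) {
      a <- letters_here[i]; b <- letters_here[j]
      ca <- counts[, a]; cb <- counts[, b]
      hi <- pmax(ca, cb); lo <- pmin(ca, cb)
      hits <- which(hi == winmax & hi >= thr1 & lo >= thr2)
      if (length(hits) > 0L) out[[paste0(a, b)]] <- as.integer(hits)
    }
  }
  out
}

# Turn flagged window starts into biased regions. Covered positions are the
# union of flagged-window spans; each maximal covered run is trimmed to the
# first/last occurrence of the focal residue(s) before the length test, so
# window overhang into unbiased flanks never inflates a region.
coverage_regions <- function(chars, starts, window_len, focal, min_run) {
  n <- length(chars)
  covered <- logical(n)
  for (s in starts) covered[s:(s + window_len - 1L)] <- TRUE
  is_focal <- chars %in% focal
  r <- rle(covered)
  ends <- cumsum(r$lengths)
  begins <- ends - r$lengths + 1L
  spans <- list()
  for (k in which(r$values)) {
    a <- begins[k]; b <- ends[k]
    foc <- which(is_focal[a:b]) + a - 1L
    if (length(foc) == 0L) next
    a2 <- foc[1L]; b2 <- foc[length(foc)]
    if (b2 - a2 + 1L >= min_run) spans[[length(spans) + 1L]] <- c(a2, b2)
  }
  spans
}

#' Detect low-complexity regions in one protein
#'
#' Runs both window criteria and reports single-residue and residue-pair
#' regions independently (a span may be reported under both kinds; only
#' exactly identical `(kind, residues, span)` tuples are deduplicated).
#' Labels are formed deterministically from the residues, pairs
#' alphabetized (`"GS-rich"`, never `"SG-rich"`).
#'
#' @param protein a single-row protein record set, or a list/row with
#'   `id` and `sequence`.
#' @param params an [lcr_params()] object.
#' @return `data.frame` with columns `protein_id`, `kind`
#'   (`"single"`/`"pair"`), `residues`, `label`, `start`, `end`, `length`,
#'   sorted by `(start, kind, residues)`.
#' @export
detect_lcrs <- function(protein, params = lcr_params()) {
  id <- protein$id[1L]
  sequence <- toupper(protein$sequence[1L])
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  out <- empty_lcr_frame()
  if (length(chars) < params$window_len) return(out)

  singles <- flag_windows_single(sequence, params)
  for (a in names(singles)) {
    spans <- coverage_regions(chars, singles[[a]], params$window_len,
                              a, params$single_min_run)
    for (sp in spans) {
      out <- rbind(out, data.frame(
        protein_id = id, kind = "single", residues = a,
        label = paste0(a, "-rich"), start = sp[1L], end = sp[2L],
        length = sp[2L] - sp[1L] + 1L, stringsAsFactors = FALSE))
    }
  }
  pairs <- flag_windows_pair(sequence, params)
  for (ab in names(pairs)) {
    focal <- strsplit(ab, "", fixed = TRUE)[[1L]]
    spans <- coverage_regions(chars, pairs[[ab]], params$window_len,
                              focal, params$pair_min_run)
    for (sp in spans) {
      out <- rbind(out, data.frame(
        protein_id = id, kind = "pair", residues = ab,
        label = paste0(ab, "-rich"), start = sp[1L], end = sp[2L],
        length = sp[2L] - sp[1L] + 1L, stringsAsFactors = FALSE))
    }
  }
  out <- unique(out)
  out[order(out$start, out$kind, out$residues), , drop = FALSE]
}

#' Detect low-complexity regions across a record set
#'
#' @param records protein record set.
#' @param params an [lcr_params()] object.
#' @return Row-bound [detect_lcrs()] results for every record.
#' @export
detect_lcrs_all <- function(records, params = lcr_params()) {
  res <- lapply(seq_len(nrow(records)), function(i) {
    detect_lcrs(records[i, , drop = FALSE], params)
  })
  out <- do.call(rbind, c(list(empty_lcr_frame()), res))
  rownames(out) <- NULL
  out
}

#' Find maximal homopolymer runs of one residue
#'
#' Reports every maximal (non-extendable) run of `residue` with length at
#' least `min_len`, in sequence order. Used for C-terminal poly-Asp tails.
#'
#' @param protein a single-row protein record set.
#' @param residue single amino-acid letter.
#' @param min_len minimum run length (at least 2).
#' @return `data.frame` with columns `protein_id`, `residue`, `start`,
#'   `end`, `length`.
#' @export
find_homopolymer_runs <- function(protein, residue, min_len = 2L) {
  stopifnot(min_len >= 2L, nchar(residue) == 1L)
  residue <- toupper(residue)
  chars <- strsplit(toupper(protein$sequence[1L]), "", fixed = TRUE)[[1L]]
  r <- rle(chars == residue)
  ends <- cumsum(r$lengths)
  begins <- ends - r$lengths + 1L
  keep <- which(r$values & r$lengths >= min_len)
  data.frame(protein_id = protein$id[1L], residue = residue,
             start = begins[keep], end = ends[keep],
             length = r$lengths[keep], stringsAsFactors = FALSE)
}
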