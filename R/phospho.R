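#' Likely phosphorylation sites above a probability threshold
#'
#' @param track phospho `data.frame` for one protein (`position`,
#'   `residue`, `probability`), as from [read_phospho_table()].
#' @param threshold probability cutoff; comparison is strict (`>`), so a
#'   site at exactly the threshold is not called.
#' @return Integer vector of likely 1-based positions, increasing.
#' @export
likely_sites <- function(track, threshold = 0.5) {
  sort(as.integer(track$position[track$probability > threshold]))
}

#' Overlay likely phosphorylation sites on low-complexity regions
#'
#' Counts how many likely sites fall inside at least one LCR. Overlapping
#' regions are merged to a position set first, so no site is ever counted
#' twice; per-region densities are still reported against each original
#' region.
#'
#' @param positions integer vector of likely site positions.
#' @param lcrs LCR `data.frame` for the same protein ([detect_lcrs()]).
#' @param protein_length sequence length; positions outside
#'   `[1, protein_length]` are an error.
#' @return List with `n_likely`, `n_in_lcr`, `frac_in_lcr` (0 when there
#'   are no likely sites, with `frac_defined = FALSE` flagging the
#'   undefined base), `frac_defined`, and `per_region` (`data.frame`:
#'   `start`, `end`, `label`, `n_sites`, `density` in sites per residue).
#' @export
overlay_lcr <- function(positions, lcrs, protein_length) {
  positions <- as.integer(positions)
  if (any(positions < 1L | positions > protein_length)) {
    stop("likely-site position(s) outside [1, ", protein_length, "]")
  }
  in_lcr <- logical(protein_length)
  for (i in seq_len(nrow(lcrs))) in_lcr[lcrs$start[i]:lcrs$end[i]] <- TRUE
  n_likely <- length(positions)
  n_in <- sum(in_lcr[positions])
  per_region <- if (nrow(lcrs) == 0L) {
    data.frame(start = integer(), end = integer(), label = character(),
               n_sites = integer(), density = numeric(),
               stringsAsFactors = FALSE)
  } else {
    ns <- vapply(seq_len(nrow(lcrs)), function(i) {
      sum(positions >= lcrs$start[i] & positions <= lcrs$end[i])
    }, integer(1L))
    data.frame(start = lcrs$start, end = lcrs$end, label = lcrs$label,
               n_sites = ns, density = ns / (lcrs$end - lcrs$start + 1L),
               stringsAsFactors = FALSE)
  }
  list(n_likely = n_likely, n_in_lcr = as.integer(n_in),
       frac_in_lcr = if (n_likely == 0L) 0 else n_in / n_likely,
       frac_defined = n_likely > 0L,
       per_region = per_region)
}
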