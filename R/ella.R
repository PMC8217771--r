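#' Construct and validate a lectin plate
#'
#' @param absorbance numeric matrix of raw A405 readings, one row per
#'   lectin (rownames are the lectin names), one column per replicate.
#' @param background numeric vector of replicate readings from the
#'   no-lectin control well.
#' @return A `lectin_plate` object (list with `lectins`, `absorbance`,
#'   `background`).
#' @export
lectin_plate <- function(absorbance, background) {
  absorbance <- as.matrix(absorbance)
  if (is.null(rownames(absorbance)) || any(!nzchar(rownames(absorbance)))) {
    stop("absorbance rows must be named by lectin")
  }
  if (anyDuplicated(rownames(absorbance))) stop("duplicate lectin names")
  if (length(background) == 0L) stop("background required")
  if (ncol(absorbance) < 1L) stop("need >=1 replicate per lectin")
  if (any(absorbance < 0) || any(background < 0)) {
    stop("absorbance readings must be >= 0")
  }
  structure(list(lectins = rownames(absorbance), absorbance = absorbance,
                 background = as.numeric(background)),
            class = "lectin_plate")
}

#' Normalize a lectin plate to percent of maximum reactivity
#'
#' The mean background (no-lectin control) is subtracted from every
#' replicate reading; per-lectin means are computed, and the highest mean
#' defines 100% reactivity. Replicate spread is reported as the sample
#' (n-1) standard deviation on the same percent scale. Negative
#' background-subtracted values are kept as-is unless `clamp0 = TRUE`.
#'
#' @param plate a [lectin_plate()] object.
#' @param clamp0 clamp negative background-subtracted readings to zero.
#' @return `data.frame` with columns `lectin`, `mean_percent`,
#'   `sd_percent` (NA with a single replicate). The maximum `mean_percent`
#'   is exactly 100.
#' @export
normalize_plate <- function(plate, clamp0 = FALSE) {
  stopifnot(inherits(plate, "lectin_plate"))
  bg <- mean(plate$background)
  adj <- plate$absorbance - bg
  if (clamp0) adj[adj < 0] <- 0
  m <- rowMeans(adj)
  M <- max(m)
  if (M <= 0) stop("no signal above background")
  sdv <- apply(adj, 1L, function(x) {
    if (length(x) > 1L) stats::sd(x) else NA_real_
  })
  data.frame(lectin = plate$lectins,
             mean_percent = 100 * m / M,
             sd_percent = 100 * sdv / M,
             stringsAsFactors = FALSE, row.names = NULL)
}
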