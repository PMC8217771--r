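## Default 21-lectin panel (three commercial kits of 7 biotinylated lectins)
## with programmed relative reactivities emulating an O-glycan- and
## chitin-rich shell matrix: jacalin maximal, DSL strong, LEL/STL/PSA
## intermediate, the rest weak.
DEFAULT_LECTINS <- c("ConA", "DBA", "PNA", "RCA", "SBA", "UEA I", "WGA",
                     "GSL I", "LCA", "PHA-E", "PHA-L", "PSA", "SJA", "sWGA",
                     "DSL", "ECL", "GSL II", "Jacalin", "LEL", "STL", "VVA")
DEFAULT_PLATE_TRUE <- c(0.20, 0.28, 0.05, 0.10, 0.27, 0.04, 0.08,
                        0.26, 0.06, 0.05, 0.25, 0.35, 0.03, 0.07,
                        0.80, 0.24, 0.12, 1.00, 0.45, 0.40, 0.06)

#' Specification for the synthetic-data generator
#'
#' Defines a seeded synthetic corpus emulating the inputs of a shell
#' proteome survey: protein sequences with planted low-complexity
#' stretches and poly-Asp tails, domain annotations, four-extract
#' peptide-evidence tables, per-residue phosphorylation-probability
#' tracks concentrated on S/T, and a 21-lectin plate with replicate noise
#' and a background well.
#'
#' In `clean` mode the background of a protein is drawn uniformly from
#' the standard residues excluding that protein's planted focal residues,
#' and any sequence whose detected LCRs are not all attributable to a
#' planted span is regenerated, so planted-feature recovery is exact by
#' construction. `clean = FALSE` disables both (realistic mode).
#'
#' @param n_proteins number of proteins.
#' @param length_range integer `(min, max)` sequence length before any
#'   appended tail.
#' @param background_freqs named probabilities over the 20 standard
#'   residues (default uniform); must sum to 1.
#' @param planted_lcrs list of `list(kind, residues, length, purity)`
#'   entries; entry `j` is planted in protein `j`. Single plants are pure
#'   runs; pair plants are a periodic motif holding every window at
#'   exactly the pair thresholds without triggering the single criterion
#'   (see [gen_protein_set()]).
#' @param planted_polyD_tail optional integer; a poly-Asp run of this
#'   length appended to the C-terminus of the last protein.
#' @param planted_domains optional `data.frame` with columns `protein`
#'   (index), `accession`, `start`, `end` (optional `name`, `source`).
#' @param evidence_pattern character vector over
#'   `common_to_four`, `in_three`, `ASM_specific`, `AIM_specific`,
#'   `other`, `rejected`, recycled over proteins.
#' @param phospho_rate_in_lcr probability that an S/T inside a planted LCR
#'   gets a likely (>0.5) phosphorylation probability.
#' @param phospho_rate_outside same, outside planted LCRs.
#' @param plate_spec list with `lectins`, `true_values`, `background`,
#'   `noise_sd`, `n_rep`; defaults to the 21-lectin panel above.
#' @param clean logical, see above.
#' @param seed integer seed; identical seed gives an identical corpus.
#' @return Validated list of class `synth_spec`.
#' @export
synth_spec <- function(n_proteins = 20L, length_range = c(60L, 120L),
                       background_freqs = NULL, planted_lcrs = list(),
                       planted_polyD_tail = NULL, planted_domains = NULL,
                       evidence_pattern = c("common_to_four", "in_three",
                                            "ASM_specific", "AIM_specific"),
                       phospho_rate_in_lcr = 0.8,
                       phospho_rate_outside = 0.05,
                       plate_spec = NULL, clean = TRUE, seed = 1L) {
  if (is.null(background_freqs)) {
    background_freqs <- stats::setNames(rep(1 / 20, 20L), AA_STANDARD)
  }
  stopifnot(abs(sum(background_freqs) - 1) < 1e-9,
            all(names(background_freqs) %in% AA_STANDARD),
            n_proteins >= 1L, length(length_range) == 2L,
            length_range[1L] >= 10L, length_range[1L] <= length_range[2L],
            phospho_rate_in_lcr >= 0, phospho_rate_in_lcr <= 1,
            phospho_rate_outside >= 0, phospho_rate_outside <= 1)
  if (length(planted_lcrs) > n_proteins) {
    stop("more planted LCRs than proteins")
  }
  for (pl in planted_lcrs) {
    stopifnot(pl$kind %in% c("single", "pair"), pl$length >= 1L)
    pl$purity <- pl$purity %||% 1
    stopifnot(pl$purity > 0, pl$purity <= 1)
    if (pl$kind == "single") stopifnot(nchar(pl$residues) == 1L)
    if (pl$kind == "pair") stopifnot(nchar(pl$residues) == 2L)
  }
  if (is.null(plate_spec)) {
    plate_spec <- list(lectins = DEFAULT_LECTINS,
                       true_values = DEFAULT_PLATE_TRUE,
                       background = 0.1, noise_sd = 0.05, n_rep = 3L)
  }
  stopifnot(length(plate_spec$lectins) == length(plate_spec$true_values),
            plate_spec$noise_sd >= 0, plate_spec$n_rep >= 1L)
  structure(list(n_proteins = as.integer(n_proteins),
                 length_range = as.integer(length_range),
                 background_freqs = background_freqs,
                 planted_lcrs = planted_lcrs,
                 planted_polyD_tail = planted_polyD_tail,
                 planted_domains = planted_domains,
                 evidence_pattern = evidence_pattern,
                 phospho_rate_in_lcr = phospho_rate_in_lcr,
                 phospho_rate_outside = phospho_rate_outside,
                 plate_spec = plate_spec, clean = clean,
                 seed = as.integer(seed)),
            class = "synth_spec")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Single plants are pure runs. Pair plants are a 10-periodic motif holding
# every window at exactly the pair thresholds (4 first-residue, 2 second,
# 4 background of 10) with a focal residue pinned at each end; an all-focal
# two-residue stretch would additionally satisfy the single criterion (one
# residue always fills >=50% of a two-letter window), which would confound
# pair-recovery experiments.
plant_stretch <- function(pl, background_letters, background_probs) {
  res <- sort(strsplit(toupper(pl$residues), "", fixed = TRUE)[[1L]])
  purity <- pl$purity %||% 1
  if (pl$kind == "single") {
    base <- rep(res, pl$length)
  } else {
    nonfocal <- setdiff(background_letters, res)
    unit_idx <- rep_len(c(1L, 2L, 1L, 0L, 0L), pl$length)
    base <- sample(nonfocal, pl$length, replace = TRUE)
    base[unit_idx == 1L] <- res[1L]
    base[unit_idx == 2L] <- res[2L]
    if (unit_idx[pl$length] == 0L) base[pl$length] <- res[2L]
  }
  if (purity < 1) {
    nonfocal <- setdiff(background_letters, res)
    swap <- stats::runif(pl$length) > purity
    base[swap] <- sample(nonfocal, sum(swap), replace = TRUE)
  }
  base
}

#' Generate a synthetic protein set with recorded ground truth
#'
#' @param spec a [synth_spec()] object.
#' @return List with `records` (protein record set), `truth` (list with
#'   `lcrs`: planted spans incl. purity and an `exact` flag, `domains`:
#'   planted domain-hit rows, `polyD`: tail span if any).
#' @export
gen_protein_set <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  set.seed(spec$seed)
  np <- length(spec$planted_lcrs)
  ids <- sprintf("SYN_%04d", seq_len(spec$n_proteins))
  seqs <- character(spec$n_proteins)
  truth_lcrs <- list()
  truth_polyD <- NULL
  params <- lcr_params()

  for (i in seq_len(spec$n_proteins)) {
    pl <- if (i <= np) spec$planted_lcrs[[i]] else NULL
    tail_len <- if (i == spec$n_proteins && !is.null(spec$planted_polyD_tail))
      as.integer(spec$planted_polyD_tail) else 0L
    L <- sample(spec$length_range[1L]:spec$length_range[2L], 1L)
    focal <- character(0)
    if (!is.null(pl)) focal <- strsplit(toupper(pl$residues), "", TRUE)[[1L]]
    if (tail_len > 0L) focal <- union(focal, "D")
    freqs <- spec$background_freqs
    if (spec$clean && length(focal) > 0L) {
      freqs <- freqs[setdiff(names(freqs), focal)]
      freqs <- freqs / sum(freqs)
    }
    if (!is.null(pl) && pl$length > L) stop("planted feature longer than protein")
    plant_start <- NA_integer_
    for (attempt in seq_len(100L)) {
      bg <- sample(names(freqs), L, replace = TRUE, prob = freqs)
      if (!is.null(pl)) {
        plant_start <- sample.int(L - pl$length + 1L, 1L)
        bg[plant_start:(plant_start + pl$length - 1L)] <-
          plant_stretch(pl, names(freqs), freqs)
      }
      if (tail_len > 0L) bg <- c(bg, rep("D", tail_len))
      seq_i <- paste(bg, collapse = "")
      if (!spec$clean) break
      # a detected region is attributable to a plant iff its residues are
      # all focal residues of that plant and its span stays within the
      # planted span (window-length margin); anything else is a background
      # artifact and the background is redrawn
      det <- detect_lcrs(list(id = ids[i], sequence = seq_i), params)
      spans <- list()
      if (!is.null(pl)) {
        spans[[length(spans) + 1L]] <- list(
          at = c(plant_start, plant_start + pl$length - 1L),
          focal = strsplit(toupper(pl$residues), "", TRUE)[[1L]])
      }
      if (tail_len > 0L) {
        spans[[length(spans) + 1L]] <- list(at = c(L + 1L, L + tail_len),
                                            focal = "D")
      }
      ok <- all(vapply(seq_len(nrow(det)), function(k) {
        reg_res <- strsplit(det$residues[k], "", fixed = TRUE)[[1L]]
        any(vapply(spans, function(sp) {
          all(reg_res %in% sp$focal) &&
            det$start[k] >= sp$at[1L] - params$window_len &&
            det$end[k] <= sp$at[2L] + params$window_len
        }, logical(1L)))
      }, logical(1L)))
      if (ok) break
      if (attempt == 100L) stop("could not generate an LCR-free background")
    }
    seqs[i] <- seq_i
    if (!is.null(pl)) {
      res_sorted <- paste(sort(strsplit(toupper(pl$residues), "",
                                        TRUE)[[1L]]), collapse = "")
      truth_lcrs[[length(truth_lcrs) + 1L]] <- data.frame(
        protein_id = ids[i], kind = pl$kind, residues = res_sorted,
        start = plant_start, end = plant_start + pl$length - 1L,
        length = pl$length, purity = pl$purity %||% 1,
        exact = (pl$purity %||% 1) == 1,
        stringsAsFactors = FALSE)
    }
    if (tail_len > 0L) {
      truth_polyD <- data.frame(protein_id = ids[i], residue = "D",
                                start = L + 1L, end = L + tail_len,
                                length = tail_len, stringsAsFactors = FALSE)
    }
  }

  truth_domains <- NULL
  if (!is.null(spec$planted_domains)) {
    pd <- spec$planted_domains
    stopifnot(all(c("protein", "accession", "start", "end") %in% names(pd)))
    if (any(pd$end > nchar(seqs[pd$protein]))) {
      stop("planted feature longer than protein")
    }
    truth_domains <- data.frame(
      protein_id = ids[pd$protein], source = pd$source %||% "synthetic",
      accession = pd$accession, name = pd$name %||% pd$accession,
      start = as.integer(pd$start), end = as.integer(pd$end),
      stringsAsFactors = FALSE)
  }

  records <- protein_records(ids, seqs,
                             description = "synthetic shell matrix protein")
  lcr_truth <- if (length(truth_lcrs) > 0L) do.call(rbind, truth_lcrs) else
    data.frame(protein_id = character(), kind = character(),
               residues = character(), start = integer(), end = integer(),
               length = integer(), purity = numeric(), exact = logical(),
               stringsAsFactors = FALSE)
  list(records = records,
       truth = list(lcrs = lcr_truth, domains = truth_domains,
                    polyD = truth_polyD))
}

#' Generate a four-extract peptide-evidence table
#'
#' Each protein receives the deterministic count template of its recycled
#' `evidence_pattern` entry over the canonical extracts
#' (`ASM_2bl`, `ASM_3bl`, `AIM_2bl`, `AIM_3bl`): `common_to_four`
#' (1,1,1,1), `in_three` (2,1,1,0), `ASM_specific` (2,1,0,0),
#' `AIM_specific` (0,0,1,2), `other` (1,0,1,0), `rejected` (1,0,0,0 —
#' fails the two-peptide rule). Only non-zero entries are emitted.
#'
#' @param spec a [synth_spec()] object.
#' @param protein_ids protein ids (as generated by [gen_protein_set()]).
#' @return Evidence `data.frame` (`protein_id`, `extract_id`,
#'   `peptide_count`) plus attribute `pattern` (named character: the
#'   template assigned to each protein).
#' @export
gen_evidence <- function(spec, protein_ids) {
  tpl <- list(common_to_four = c(1L, 1L, 1L, 1L),
              in_three = c(2L, 1L, 1L, 0L),
              ASM_specific = c(2L, 1L, 0L, 0L),
              AIM_specific = c(0L, 0L, 1L, 2L),
              other = c(1L, 0L, 1L, 0L),
              rejected = c(1L, 0L, 0L, 0L))
  pattern <- rep_len(spec$evidence_pattern, length(protein_ids))
  stopifnot(all(pattern %in% names(tpl)))
  rows <- lapply(seq_along(protein_ids), function(i) {
    counts <- tpl[[pattern[i]]]
    keep <- counts > 0L
    data.frame(protein_id = protein_ids[i],
               extract_id = CANONICAL_EXTRACTS[keep],
               peptide_count = counts[keep], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "pattern") <- stats::setNames(pattern, protein_ids)
  out
}

#' Generate per-residue phosphorylation-probability tracks
#'
#' Every S, T and Y in every sequence receives a probability. S/T sites
#' inside planted LCR spans are "likely" (probability drawn as
#' `0.5 + 0.5 * Beta(2,2)`, strictly above 0.5) with probability
#' `phospho_rate_in_lcr`, and otherwise "unlikely"
#' (`0.5 * Beta(2,2)`, strictly below 0.5); outside planted spans the
#' likely rate is `phospho_rate_outside`. Y sites are always unlikely.
#' The split at 0.5 is exact, so threshold guarantees hold by
#' construction.
#'
#' @param spec a [synth_spec()] object.
#' @param records protein record set from [gen_protein_set()].
#' @param truth the matching `truth` list.
#' @return Phospho `data.frame` (`protein_id`, `position`, `residue`,
#'   `probability`).
#' @export
gen_phospho <- function(spec, records, truth) {
  set.seed(spec$seed + 2L)
  rows <- lapply(seq_len(nrow(records)), function(i) {
    id <- records$id[i]
    chars <- strsplit(records$sequence[i], "", fixed = TRUE)[[1L]]
    pos <- which(chars %in% c("S", "T", "Y"))
    if (length(pos) == 0L) return(NULL)
    spans <- truth$lcrs[truth$lcrs$protein_id == id, , drop = FALSE]
    in_lcr <- vapply(pos, function(p) {
      any(p >= spans$start & p <= spans$end)
    }, logical(1L))
    st <- chars[pos] %in% c("S", "T")
    rate <- ifelse(in_lcr, spec$phospho_rate_in_lcr,
                   spec$phospho_rate_outside)
    likely <- st & (stats::runif(length(pos)) < rate)
    prob <- ifelse(likely,
                   0.5 + 0.5 * stats::rbeta(length(pos), 2, 2),
                   0.5 * stats::rbeta(length(pos), 2, 2))
    data.frame(protein_id = id, position = pos, residue = chars[pos],
               probability = prob, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Generate a lectin plate with replicate noise and programmed truth
#'
#' Readings are `background + true_value + N(0, noise_sd)`, truncated at
#' zero; the background well is `background + N(0, noise_sd)`.
#'
#' @param spec a [synth_spec()] object.
#' @return List with `plate` (a [lectin_plate()]) and `truth_percent`
#'   (named vector: programmed percent-of-maximum reactivities).
#' @export
gen_plate <- function(spec) {
  set.seed(spec$seed + 3L)
  ps <- spec$plate_spec
  n <- length(ps$lectins)
  vals <- matrix(pmax(0, ps$background + ps$true_values +
                        stats::rnorm(n * ps$n_rep, sd = ps$noise_sd)),
                 nrow = n, ncol = ps$n_rep)
  rownames(vals) <- ps$lectins
  bgv <- pmax(0, ps$background + stats::rnorm(ps$n_rep, sd = ps$noise_sd))
  list(plate = lectin_plate(vals, bgv),
       truth_percent = stats::setNames(
         100 * ps$true_values / max(ps$true_values), ps$lectins))
}
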