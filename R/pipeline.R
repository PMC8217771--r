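#' Run the full shell-matrix-protein characterization pipeline
#'
#' Orchestrates reading, LCR detection, physicochemical profiling,
#' evidence filtering, classification, phosphorylation overlay and plate
#' normalization, and emits a Table-1-style report plus a summary. Inputs
#' may be given as file paths (read with the `core_io` readers) or as
#' already-constructed objects. When `evidence` is `NULL` the two-peptide
#' filter is skipped with a warning and all proteins are retained
#' (annotation-only mode). Defaults reproduce the published constants:
#' window 10 with 50%/40%/20% count thresholds sustained over >14/>19
#' residues, acidic rule pI < 3.5 and Asp+Glu > 20%, phosphorylation
#' threshold > 0.5, and at least 2 supporting peptides.
#'
#' @param fasta protein record set or path to a FASTA file.
#' @param domains domain-hit `data.frame` or TSV path (optional).
#' @param features feature-flags `data.frame` or TSV path (optional).
#' @param evidence evidence `data.frame` or CSV path (optional).
#' @param phospho phospho `data.frame` or TSV path (optional).
#' @param plate [lectin_plate()] or plate CSV path (optional).
#' @param params [lcr_params()].
#' @param pka [pka_set()] list.
#' @param catalog [domain_catalog()] `data.frame`.
#' @param phospho_threshold likely-site probability cutoff (strict `>`).
#' @param min_peptides two-peptide rule minimum total.
#' @param pi_cut,de_cut acidic-protein rule cutoffs.
#' @param out_dir optional directory; when given, writes `table1.tsv`,
#'   `summary.json`, `lcr.tsv`, `profile.tsv`, `overlay.tsv`,
#'   `reactivity.tsv` and `run.log` there.
#' @return List with `report` (one row per retained protein), `summary`,
#'   `lcr`, `profile`, `overlay`, `reactivity`, `log`.
#' @export
run_pipeline <- function(fasta, domains = NULL, features = NULL,
                         evidence = NULL, phospho = NULL, plate = NULL,
                         params = lcr_params(),
                         pka = pka_set("IPC_protein"),
                         catalog = domain_catalog(),
                         phospho_threshold = 0.5, min_peptides = 2L,
                         pi_cut = 3.5, de_cut = 0.20, out_dir = NULL) {
  logline <- character(0)
  note <- function(...) logline <<- c(logline, sprintf(...))

  records <- if (is.character(fasta)) read_fasta(fasta) else
    validate_protein_records(fasta)
  note("input: %d protein(s)", nrow(records))
  if (is.character(domains)) domains <- read_domain_table(domains, records)
  if (is.null(domains)) {
    domains <- data.frame(protein_id = character(), source = character(),
                          accession = character(), name = character(),
                          start = integer(), end = integer(),
                          stringsAsFactors = FALSE)
  }
  if (is.character(features)) features <- read_features_table(features)
  if (is.character(evidence)) evidence <- read_evidence_table(evidence)
  if (is.character(phospho)) phospho <- read_phospho_table(phospho, records)
  if (is.character(plate)) plate <- read_plate_csv(plate)

  note(paste("lcr: window %d, single >=%.0f%% over >=%d,",
             "pair >=%.0f%%+%.0f%% over >=%d"),
       params$window_len, 100 * params$single_min_frac,
       params$single_min_run, 100 * params$pair_first_min_frac,
       100 * params$pair_second_min_frac, params$pair_min_run)
  lcr <- detect_lcrs_all(records, params)

  note("physchem: pKa set %s; acidic iff pI < %.2f and Asp+Glu > %.0f%%",
       pka$name, pi_cut, 100 * de_cut)
  profile <- physchem_profile(records, pka)
  profile$is_acidic <- classify_acidic(profile$pi, profile$asp_glu_fraction,
                                       pi_cut, de_cut)

  if (is.null(evidence)) {
    warning("no evidence table: two-peptide filter skipped, all proteins retained")
    note("evidence: none (filter skipped)")
    retained <- records
    pres_class <- stats::setNames(rep(NA_character_, nrow(records)),
                                  records$id)
    presence_counts <- NULL
  } else {
    note("evidence: two-peptide rule, >=%d distinct peptides in total",
         min_peptides)
    rule <- apply_peptide_rule(evidence, min_peptides)
    accepted <- rule$protein_id[rule$accepted]
    retained <- records[records$id %in% accepted, , drop = FALSE]
    pres <- presence_sets(evidence)
    part <- presence_partition(pres[names(pres) %in% accepted])
    pres_class <- part$classes
    presence_counts <- part$counts
    note("evidence: %d/%d protein(s) accepted", nrow(retained),
         nrow(records))
  }

  classification <- classify_proteins(retained, domains,
                                      lcr[lcr$protein_id %in% retained$id, ,
                                          drop = FALSE], catalog)

  overlay <- NULL
  if (!is.null(phospho)) {
    note("phospho: likely iff probability > %.2f", phospho_threshold)
    rows <- lapply(seq_len(nrow(retained)), function(i) {
      id <- retained$id[i]
      track <- phospho[phospho$protein_id == id, , drop = FALSE]
      sites <- likely_sites(track, phospho_threshold)
      ov <- overlay_lcr(sites, lcr[lcr$protein_id == id, , drop = FALSE],
                        nchar(retained$sequence[i]))
      data.frame(protein_id = id, n_likely = ov$n_likely,
                 n_in_lcr = ov$n_in_lcr, frac_in_lcr = ov$frac_in_lcr,
                 frac_defined = ov$frac_defined, stringsAsFactors = FALSE)
    })
    overlay <- do.call(rbind, c(list(NULL), rows))
  }

  reactivity <- NULL
  if (!is.null(plate)) {
    reactivity <- normalize_plate(plate)
    note("ella: background-subtracted, max mean = 100%%")
  }

  report <- merge(classification,
                  profile[, c("protein_id", "length", "mw", "pi",
                              "asp_glu_fraction", "is_acidic")],
                  by = "protein_id")
  report$pi <- round(report$pi, 2)  # reporting precision; profile keeps full
  report$presence_class <- unname(pres_class[report$protein_id])
  if (!is.null(features)) {
    report <- merge(report, features, by = "protein_id", all.x = TRUE)
  }
  report <- report[order(report$protein_id), , drop = FALSE]
  rownames(report) <- NULL

  category_counts <- table(factor(report$category,
                                  levels = c("conserved_domain",
                                             "lcr_containing",
                                             "uncharacterized")))
  summary <- list(
    schema_version = "1.0",
    n_input = nrow(records),
    n_retained = nrow(retained),
    category_counts = stats::setNames(as.integer(category_counts),
                                      names(category_counts)),
    presence_counts = presence_counts,
    acidic_proteins = report$protein_id[report$is_acidic],
    thresholds = list(window_len = params$window_len,
                      single_min_frac = params$single_min_frac,
                      single_min_run = params$single_min_run,
                      pair_first_min_frac = params$pair_first_min_frac,
                      pair_second_min_frac = params$pair_second_min_frac,
                      pair_min_run = params$pair_min_run,
                      pka_set = pka$name, pi_cut = pi_cut, de_cut = de_cut,
                      phospho_threshold = phospho_threshold,
                      min_peptides = min_peptides))

  out <- list(report = report, summary = summary, lcr = lcr,
              profile = profile, overlay = overlay,
              reactivity = reactivity, log = logline)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    wtsv <- function(x, f) utils::write.table(
      x, file.path(out_dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
    wtsv(report, "table1.tsv")
    wtsv(lcr, "lcr.tsv")
    wtsv(profile, "profile.tsv")
    if (!is.null(overlay)) wtsv(overlay, "overlay.tsv")
    if (!is.null(reactivity)) wtsv(reactivity, "reactivity.tsv")
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
    writeLines(logline, file.path(out_dir, "run.log"))
  }
  out
}
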