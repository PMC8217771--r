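## Domain-type groups used for BMSP architecture detection.
VWA_ACCESSIONS <- c("PF00092", "SSF53300")
CHBD_ACCESSIONS <- c("PF01607", "IPR002557", "PF03067")

#' Domain-to-subcategory catalog
#'
#' Maps domain accessions to the functional sub-categories used for
#' conserved-domain shell matrix proteins: affinity to polysaccharides
#' (chitin-binding, concanavalin A-like, thrombospondin type-1, VWA,
#' C-type lectin fold), enzymatic activity (glycoside hydrolase,
#' tyrosinase copper-binding), and protease inhibitors (Kunitz, Kazal).
#' Accessions not in the catalog never trigger the conserved-domain
#' category. User-extensible: rbind additional rows.
#'
#' @param extra optional `data.frame` with columns `accession`,
#'   `subcategory` appended to the defaults.
#' @return `data.frame` with columns `accession`, `subcategory`.
#' @export
domain_catalog <- function(extra = NULL) {
  cat <- data.frame(
    accession = c("PF01607", "IPR002557", "PF03067", "SSF49899", "PF00090",
                  "PF00092", "SSF53300", "SSF56436",
                  "PF00150", "PF00264",
                  "PF00014", "IPR002350"),
    subcategory = c(rep("polysaccharide_affinity", 8L),
                    rep("enzyme", 2L),
                    rep("protease_inhibitor", 2L)),
    stringsAsFactors = FALSE)
  if (!is.null(extra)) {
    stopifnot(all(c("accession", "subcategory") %in% names(extra)))
    cat <- rbind(cat, extra[, c("accession", "subcategory")])
  }
  if (anyDuplicated(cat$accession)) {
    stop("catalog accessions must map to exactly one subcategory")
  }
  cat
}

#' Two-peptide acceptance rule
#'
#' A protein is accepted as a shell matrix protein iff its distinct-peptide
#' total summed over all extracts is at least `min_peptides` ("more than
#' one peptide" = at least 2). Presence in an extract means at least one
#' peptide there.
#'
#' @param evidence evidence `data.frame` (`protein_id`, `extract_id`,
#'   `peptide_count`), as from [read_evidence_table()].
#' @param min_peptides minimum distinct-peptide total.
#' @return `data.frame` with columns `protein_id`, `total_peptides`,
#'   `accepted`.
#' @export
apply_peptide_rule <- function(evidence, min_peptides = 2L) {
  totals <- stats::aggregate(peptide_count ~ protein_id, data = evidence,
                             FUN = sum)
  data.frame(protein_id = totals$protein_id,
             total_peptides = as.integer(totals$peptide_count),
             accepted = totals$peptide_count >= min_peptides,
             stringsAsFactors = FALSE)
}

#' Per-protein extract-presence sets
#'
#' @param evidence evidence `data.frame`.
#' @return Named list: protein id -> character vector of extract ids with
#'   at least one supporting peptide.
#' @export
presence_sets <- function(evidence) {
  pos <- evidence[evidence$peptide_count >= 1L, , drop = FALSE]
  lapply(split(pos$extract_id, pos$protein_id), unique)
}

#' Partition accepted proteins by extract-presence pattern
#'
#' With two acid-soluble (ASM) and two acid-insoluble (AIM) extracts, each
#' protein is classed in this precedence order: `common_to_four` (present
#' in all four), `in_three` (exactly three), `ASM_specific` (only in ASM
#' extracts), `AIM_specific` (only in AIM extracts), `other` (remainder,
#' e.g. one ASM plus one AIM). Classes are mutually exclusive and
#' exhaustive.
#'
#' @param presence named list of extract-id sets, as from
#'   [presence_sets()], restricted to accepted proteins.
#' @param extract_ids the four canonical extract ids (names starting
#'   `ASM`/`AIM` determine the fraction groups).
#' @return List with `classes` (named character, one per protein) and
#'   `counts` (named integer over the five classes, summing to
#'   `length(presence)`).
#' @export
presence_partition <- function(presence, extract_ids = CANONICAL_EXTRACTS) {
  stopifnot(length(extract_ids) == 4L)
  asm <- extract_ids[startsWith(extract_ids, "ASM")]
  aim <- extract_ids[startsWith(extract_ids, "AIM")]
  stopifnot(length(asm) == 2L, length(aim) == 2L)
  classes <- vapply(presence, function(p) {
    unknown <- setdiff(p, extract_ids)
    if (length(unknown) > 0L) {
      stop("unknown extract id(s): ", paste(unknown, collapse = ", "))
    }
    if (length(p) == 4L) return("common_to_four")
    if (length(p) == 3L) return("in_three")
    if (length(p) >= 1L && all(p %in% asm)) return("ASM_specific")
    if (length(p) >= 1L && all(p %in% aim)) return("AIM_specific")
    "other"
  }, character(1L))
  lv <- c("common_to_four", "in_three", "ASM_specific", "AIM_specific",
          "other")
  counts <- table(factor(classes, levels = lv))
  list(classes = classes,
       counts = stats::setNames(as.integer(counts), lv))
}

#' Detect BMSP-like domain architecture
#'
#' Blue Mussel Shell Proteins carry more than one VWA domain at the
#' N-terminus, immediately followed by one or more chitin-binding domains
#' (ChBD). Considering only catalog-categorized domains in start order,
#' the protein is BMSP-like iff the leading block consists of at least two
#' VWA domains and the next categorized domain is a ChBD (no other
#' categorized domain type between the VWA block and the first ChBD).
#'
#' @param domains domain-hit `data.frame` for one protein.
#' @param catalog a [domain_catalog()] `data.frame`.
#' @return List with `n_vwa` (length of the leading VWA block),
#'   `n_chbd_following` (length of the ChBD block that follows it) and
#'   `bmsp_like` (logical).
#' @export
detect_bmsp_architecture <- function(domains, catalog = domain_catalog()) {
  domains <- domains[order(domains$start), , drop = FALSE]
  categorized <- domains[domains$accession %in% catalog$accession, ,
                         drop = FALSE]
  type <- ifelse(categorized$accession %in% VWA_ACCESSIONS, "VWA",
                 ifelse(categorized$accession %in% CHBD_ACCESSIONS, "ChBD",
                        "other"))
  n_vwa <- if (length(type) == 0L || type[1L] != "VWA") 0L else {
    rle(type)$lengths[1L]
  }
  after <- type[-seq_len(n_vwa)]
  n_chbd <- if (length(after) == 0L || after[1L] != "ChBD") 0L else {
    rle(after)$lengths[1L]
  }
  list(n_vwa = as.integer(n_vwa), n_chbd_following = as.integer(n_chbd),
       bmsp_like = n_vwa >= 2L && n_chbd >= 1L)
}

#' Classify one shell matrix protein
#'
#' Category assignment: any catalog domain -> `conserved_domain` (with
#' subcategory by precedence polysaccharide_affinity > enzyme >
#' protease_inhibitor when several apply); else at least one LCR ->
#' `lcr_containing`; else `uncharacterized`. LCR labels are recorded in
#' all categories (conserved-domain proteins may also carry LCRs).
#' Classification is invariant to input row order.
#'
#' @param protein a single-row protein record set.
#' @param domains domain-hit `data.frame` for this protein (possibly
#'   0-row).
#' @param lcrs LCR `data.frame` for this protein, as from [detect_lcrs()].
#' @param catalog a [domain_catalog()] `data.frame`.
#' @return One-row `data.frame`: `protein_id`, `category`, `subcategory`,
#'   `bmsp_like`, `lcr_labels_single`, `lcr_labels_pair` (each a
#'   `;`-joined string, empty when none), `domain_accessions`.
#' @export
classify_protein <- function(protein, domains, lcrs,
                             catalog = domain_catalog()) {
  hits <- merge(domains, catalog, by = "accession")
  subprec <- c("polysaccharide_affinity", "enzyme", "protease_inhibitor")
  if (nrow(hits) > 0L) {
    category <- "conserved_domain"
    subcategory <- subprec[min(match(hits$subcategory, subprec))]
  } else if (nrow(lcrs) > 0L) {
    category <- "lcr_containing"
    subcategory <- "none"
  } else {
    category <- "uncharacterized"
    subcategory <- "none"
  }
  lab1 <- sort(unique(lcrs$label[lcrs$kind == "single"]))
  lab2 <- sort(unique(lcrs$label[lcrs$kind == "pair"]))
  bmsp <- detect_bmsp_architecture(domains, catalog)
  data.frame(protein_id = protein$id[1L], category = category,
             subcategory = subcategory, bmsp_like = bmsp$bmsp_like,
             lcr_labels_single = paste(lab1, collapse = ";"),
             lcr_labels_pair = paste(lab2, collapse = ";"),
             domain_accessions = paste(sort(unique(domains$accession)),
                                       collapse = ";"),
             stringsAsFactors = FALSE)
}

#' Classify a whole record set
#'
#' @param records protein record set.
#' @param domains domain-hit `data.frame` over all proteins (may be 0-row).
#' @param lcrs LCR `data.frame` over all proteins, as from
#'   [detect_lcrs_all()].
#' @param catalog a [domain_catalog()] `data.frame`.
#' @return Row-bound [classify_protein()] results, one row per record.
#' @export
classify_proteins <- function(records, domains, lcrs,
                              catalog = domain_catalog()) {
  rows <- lapply(seq_len(nrow(records)), function(i) {
    p <- records[i, , drop = FALSE]
    classify_protein(p,
                     domains[domains$protein_id == p$id, , drop = FALSE],
                     lcrs[lcrs$protein_id == p$id, , drop = FALSE],
                     catalog)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
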