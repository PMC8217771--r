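#' @title Protein record sets
#' @description A protein record set is a plain `data.frame` with columns
#' `id` (unique, non-empty), `sequence` (uppercase string over the 20
#' standard one-letter amino-acid codes plus `X`), and `description`
#' (free text, possibly empty). All readers and analysis functions in the
#' package consume and produce this shape.
#' @name protein_records
NULL

# 20 standard residues; 'X' (unknown) is tolerated in sequences but never
# counts toward any compositional criterion.
AA_STANDARD <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
AA_ALPHABET <- c(AA_STANDARD, "X")

CANONICAL_EXTRACTS <- c("ASM_2bl", "ASM_3bl", "AIM_2bl", "AIM_3bl")

#' Construct and validate a protein record set
#'
#' @param id character vector of unique, non-empty protein identifiers.
#' @param sequence character vector of amino-acid sequences; uppercased on
#'   construction. Allowed letters are the 20 standard residues plus `X`.
#' @param description optional character vector of free-text descriptions.
#' @return A validated `data.frame` with columns `id`, `sequence`,
#'   `description`.
#' @export
protein_records <- function(id, sequence, description = "") {
  rec <- data.frame(
    id = as.character(id),
    sequence = toupper(as.character(sequence)),
    description = rep_len(as.character(description), length(id)),
    stringsAsFactors = FALSE
  )
  validate_protein_records(rec)
}

validate_protein_records <- function(rec) {
  stopifnot(is.data.frame(rec), all(c("id", "sequence") %in% names(rec)))
  if (any(!nzchar(rec$id))) stop("protein ids must be non-empty")
  dup <- rec$id[duplicated(rec$id)]
  if (length(dup) > 0L) {
    stop("duplicate protein id(s): ", paste(unique(dup), collapse = ", "))
  }
  if (any(nchar(rec$sequence) < 1L)) {
    stop("zero-length sequence for: ",
         paste(rec$id[nchar(rec$sequence) < 1L], collapse = ", "))
  }
  for (i in seq_len(nrow(rec))) {
    chars <- strsplit(rec$sequence[i], "", fixed = TRUE)[[1L]]
    bad <- which(!chars %in% AA_ALPHABET)
    if (length(bad) > 0L) {
      stop(sprintf("illegal character '%s' at position %d in record '%s'",
                   chars[bad[1L]], bad[1L], rec$id[i]))
    }
  }
  if (!"description" %in% names(rec)) rec$description <- ""
  rec[, c("id", "sequence", "description"), drop = FALSE]
}

#' Read a protein FASTA file
#'
#' Sequences are uppercased; a single trailing `*` (stop symbol) is stripped
#' from the end of each sequence. Duplicate ids and characters outside the
#' 20-standard-residue + `X` alphabet are rejected.
#'
#' @param path path to a protein FASTA file.
#' @return A protein record set (`data.frame`: `id`, `sequence`,
#'   `description`).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  aas <- Biostrings::readBStringSet(path)
  if (length(aas) == 0L) stop("no records in FASTA file: ", path)
  headers <- names(aas)
  id <- sub("\\s.*$", "", headers)
  description <- ifelse(grepl("\\s", headers),
                        sub("^\\S+\\s+", "", headers), "")
  sequence <- toupper(as.character(aas))
  sequence <- sub("\\*+$", "", sequence)  # stop symbols at the end only
  names(sequence) <- NULL
  protein_records(id, sequence, description)
}

#' Write a protein record set as FASTA
#'
#' Lines are wrapped at 60 characters. `write_fasta(read_fasta(f))`
#' re-parses to an identical record set.
#'
#' @param records protein record set.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  records <- validate_protein_records(records)
  x <- Biostrings::BStringSet(records$sequence)
  names(x) <- ifelse(nzchar(records$description),
                     paste(records$id, records$description),
                     records$id)
  Biostrings::writeXStringSet(x, path, width = 60L)
  invisible(path)
}

#' Read a domain-annotation table
#'
#' Tab-separated with header columns `protein_id`, `source`, `accession`,
#' `name`, `start`, `end`. Coordinates are 1-based, inclusive on both ends.
#'
#' @param path path to the TSV file.
#' @param records optional protein record set; when given, hit coordinates
#'   are checked against sequence lengths.
#' @return `data.frame` with the six columns above (`start`/`end` integer).
#' @export
read_domain_table <- function(path, records = NULL) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  required <- c("protein_id", "source", "accession", "name", "start", "end")
  missing <- setdiff(required, names(tab))
  if (length(missing) > 0L) {
    stop("domain table missing column(s): ", paste(missing, collapse = ", "))
  }
  if (nrow(tab) == 0L) {
    return(data.frame(protein_id = character(), source = character(),
                      accession = character(), name = character(),
                      start = integer(), end = integer(),
                      stringsAsFactors = FALSE))
  }
  start <- suppressWarnings(as.integer(tab$start))
  end <- suppressWarnings(as.integer(tab$end))
  for (i in seq_len(nrow(tab))) {  # +1 for the header row in line numbers
    if (is.na(start[i]) || is.na(end[i])) {
      stop(sprintf("line %d: non-integer coordinates ('%s', '%s')",
                   i + 1L, tab$start[i], tab$end[i]))
    }
    if (start[i] < 1L || start[i] > end[i]) {
      stop(sprintf("line %d: invalid span %d..%d (need 1 <= start <= end)",
                   i + 1L, start[i], end[i]))
    }
    if (!nzchar(tab$accession[i])) stop(sprintf("line %d: empty accession", i + 1L))
  }
  out <- data.frame(protein_id = tab$protein_id, source = tab$source,
                    accession = tab$accession, name = tab$name,
                    start = start, end = end, stringsAsFactors = FALSE)
  if (!is.null(records)) {
    len <- stats::setNames(nchar(records$sequence), records$id)
    known <- out$protein_id %in% names(len)
    over <- known & out$end > len[out$protein_id]
    if (any(over)) {
      stop("domain hit(s) extend past sequence end for: ",
           paste(unique(out$protein_id[over]), collapse = ", "))
    }
  }
  out
}

#' Read a signal-peptide / transmembrane feature table
#'
#' Tab-separated with header columns `protein_id`, `signal_peptide` (Y/N),
#' `tm_count` (non-negative integer).
#'
#' @param path path to the TSV file.
#' @return `data.frame` with columns `protein_id`, `signal_peptide`
#'   (logical), `tm_count` (integer).
#' @export
read_features_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  required <- c("protein_id", "signal_peptide", "tm_count")
  missing <- setdiff(required, names(tab))
  if (length(missing) > 0L) {
    stop("features table missing column(s): ", paste(missing, collapse = ", "))
  }
  sp <- toupper(trimws(tab$signal_peptide))
  if (any(!sp %in% c("Y", "N"))) {
    stop("signal_peptide must be Y or N (line ",
         which(!sp %in% c("Y", "N"))[1L] + 1L, ")")
  }
  tm <- suppressWarnings(as.integer(tab$tm_count))
  if (any(is.na(tm) | tm < 0L)) {
    stop("tm_count must be a non-negative integer (line ",
         which(is.na(tm) | tm < 0L)[1L] + 1L, ")")
  }
  data.frame(protein_id = tab$protein_id, signal_peptide = sp == "Y",
             tm_count = tm, stringsAsFactors = FALSE)
}

#' Read a peptide-evidence table
#'
#' Comma-separated with header columns `protein_id`, `extract_id`,
#' `peptide_count` (distinct peptides supporting the protein in that
#' extract). Extract ids outside the canonical four
#' (`ASM_2bl`, `ASM_3bl`, `AIM_2bl`, `AIM_3bl`) are preserved with a warning.
#'
#' @param path path to the CSV file.
#' @param extract_ids character vector of expected extract ids.
#' @return `data.frame` with columns `protein_id`, `extract_id`,
#'   `peptide_count` (integer).
#' @export
read_evidence_table <- function(path, extract_ids = CANONICAL_EXTRACTS) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  required <- c("protein_id", "extract_id", "peptide_count")
  missing <- setdiff(required, names(tab))
  if (length(missing) > 0L) {
    stop("evidence table missing column(s): ", paste(missing, collapse = ", "))
  }
  count <- suppressWarnings(as.integer(tab$peptide_count))
  bad <- which(is.na(count) | count < 0L)
  if (length(bad) > 0L) {
    stop("peptide_count must be a non-negative integer (line ",
         bad[1L] + 1L, ")")
  }
  unknown <- setdiff(unique(tab$extract_id), extract_ids)
  if (length(unknown) > 0L) {
    warning("unknown extract id(s) preserved: ",
            paste(unknown, collapse = ", "))
  }
  data.frame(protein_id = tab$protein_id, extract_id = tab$extract_id,
             peptide_count = count, stringsAsFactors = FALSE)
}

#' Read a per-residue phosphorylation-probability table
#'
#' Tab-separated with header columns `protein_id`, `position` (1-based),
#' `residue` (S/T/Y), `probability` (in \[0,1\]). Positions must be strictly
#' increasing within a protein; when `records` is given, the stated residue
#' is cross-checked against the sequence.
#'
#' @param path path to the TSV file.
#' @param records optional protein record set for cross-checking.
#' @return `data.frame` with columns `protein_id`, `position`, `residue`,
#'   `probability`.
#' @export
read_phospho_table <- function(path, records = NULL) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  required <- c("protein_id", "position", "residue", "probability")
  missing <- setdiff(required, names(tab))
  if (length(missing) > 0L) {
    stop("phospho table missing column(s): ", paste(missing, collapse = ", "))
  }
  pos <- suppressWarnings(as.integer(tab$position))
  prob <- suppressWarnings(as.numeric(tab$probability))
  res <- toupper(trimws(tab$residue))
  for (i in seq_len(nrow(tab))) {
    if (is.na(pos[i]) || pos[i] < 1L) {
      stop(sprintf("line %d: invalid position '%s'", i + 1L, tab$position[i]))
    }
    if (is.na(prob[i]) || prob[i] < 0 || prob[i] > 1) {
      stop(sprintf("line %d: probability '%s' outside [0,1]",
                   i + 1L, tab$probability[i]))
    }
    if (!res[i] %in% c("S", "T", "Y")) {
      stop(sprintf("line %d: residue must be S, T or Y, got '%s'",
                   i + 1L, tab$residue[i]))
    }
  }
  out <- data.frame(protein_id = tab$protein_id, position = pos,
                    residue = res, probability = prob,
                    stringsAsFactors = FALSE)
  by_prot <- split(out$position, out$protein_id)
  nonmono <- names(by_prot)[vapply(by_prot, function(p) any(diff(p) <= 0L),
                                   logical(1L))]
  if (length(nonmono) > 0L) {
    stop("positions not strictly increasing for: ",
         paste(nonmono, collapse = ", "))
  }
  if (!is.null(records)) {
    seqs <- stats::setNames(records$sequence, records$id)
    for (i in seq_len(nrow(out))) {
      s <- seqs[[out$protein_id[i]]]
      if (is.null(s)) next
      if (out$position[i] > nchar(s)) {
        stop(sprintf("position %d past end of '%s'", out$position[i],
                     out$protein_id[i]))
      }
      actual <- substr(s, out$position[i], out$position[i])
      if (actual != out$residue[i]) {
        stop(sprintf("residue mismatch at %s:%d (table says %s, sequence has %s)",
                     out$protein_id[i], out$position[i], out$residue[i], actual))
      }
    }
  }
  out
}

#' Read a lectin-plate absorbance CSV
#'
#' Rows are lectin names plus one reserved row `BACKGROUND` (the no-lectin
#' control); columns after the first are replicate A405 readings.
#'
#' @param path path to the CSV file.
#' @return A `lectin_plate` object (see [lectin_plate()]).
#' @export
read_plate_csv <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(tab) < 2L) stop("plate CSV needs a name column plus >=1 replicate")
  nm <- as.character(tab[[1L]])
  vals <- as.matrix(tab[, -1L, drop = FALSE])
  storage.mode(vals) <- "double"
  is_bg <- toupper(nm) == "BACKGROUND"
  if (!any(is_bg)) stop("background required: no BACKGROUND row in plate")
  background <- as.numeric(vals[is_bg, , drop = TRUE])
  absorbance <- vals[!is_bg, , drop = FALSE]
  rownames(absorbance) <- nm[!is_bg]
  lectin_plate(absorbance, background)
}
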