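## Average (isotope-averaged) residue masses in Da, Expasy ProtParam values;
## a residue mass is the free amino acid minus one water.
AA_MASS <- c(
  A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519, H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326)
WATER_MASS <- 18.01524

#' Named pKa sets for isoelectric-point calculation
#'
#' Returns one of the shipped, named pKa parameterizations:
#' `"IPC_protein"` and `"IPC_peptide"` (Kozlowski 2016, the IPC 1.0
#' optimized sets; `IPC_protein` is the default used for whole-protein pI)
#' or `"EMBOSS"` (the EMBOSS `iep` values). Each set carries terminal pKas
#' and side-chain pKas for D, E, C, Y, H, K, R.
#'
#' @param name one of `"IPC_protein"`, `"IPC_peptide"`, `"EMBOSS"`.
#' @return A list with elements `name`, `n_term`, `c_term`, `side_chains`
#'   (named numeric over D, E, C, Y, H, K, R).
#' @export
pka_set <- function(name = c("IPC_protein", "IPC_peptide", "EMBOSS")) {
  name <- match.arg(name)
  sets <- list(
    IPC_protein = list(
      n_term = 9.094, c_term = 2.869,
      side_chains = c(D = 3.872, E = 4.412, C = 7.555, Y = 10.85,
                      H = 5.637, K = 9.052, R = 11.84)),
    IPC_peptide = list(
      n_term = 9.564, c_term = 2.383,
      side_chains = c(D = 3.887, E = 4.317, C = 8.297, Y = 10.071,
                      H = 6.018, K = 10.517, R = 12.503)),
    EMBOSS = list(
      n_term = 8.6, c_term = 3.6,
      side_chains = c(D = 3.9, E = 4.1, C = 8.5, Y = 10.1,
                      H = 6.5, K = 10.8, R = 12.5))
  )
  s <- sets[[name]]
  s$name <- name
  stopifnot(all(unlist(s[c("n_term", "c_term", "side_chains")]) > 0),
            all(unlist(s[c("n_term", "c_term", "side_chains")]) < 14))
  s
}

aa_counts <- function(sequence) {
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1L]]
  table(factor(chars, levels = AA_ALPHABET))
}

#' Amino-acid composition and acidic-residue fraction
#'
#' Fractions are computed over the full sequence length (including `X`).
#' `asp_glu_fraction` is `(count(D) + count(E)) / length`.
#'
#' @param protein a single-row protein record set.
#' @return List with `protein_id`, `length`, `aa_fractions` (named numeric
#'   summing to 1), `asp_glu_fraction`.
#' @export
composition <- function(protein) {
  cnt <- aa_counts(protein$sequence[1L])
  n <- sum(cnt)
  list(protein_id = protein$id[1L], length = as.integer(n),
       aa_fractions = stats::setNames(as.numeric(cnt) / n, names(cnt)),
       asp_glu_fraction = as.numeric(cnt[["D"]] + cnt[["E"]]) / n)
}

#' Molecular weight from average residue masses
#'
#' Sum of Expasy average residue masses plus one water. `X` (unknown)
#' contributes a configurable average residue mass, defaulting to the mean
#' of the 20 standard residue masses.
#'
#' @param protein a single-row protein record set.
#' @param x_mass mass in Da assigned to `X` residues.
#' @return Molecular weight in Da.
#' @export
molecular_weight <- function(protein, x_mass = mean(AA_MASS)) {
  cnt <- aa_counts(protein$sequence[1L])
  sum(AA_MASS[AA_STANDARD] * as.numeric(cnt[AA_STANDARD])) +
    x_mass * as.numeric(cnt[["X"]]) + WATER_MASS
}

#' Net protein charge at a given pH
#'
#' Henderson-Hasselbalch sum over ionizable groups:
#' `Q(pH) = sum_b n_b / (1 + 10^(pH - pKa_b)) - sum_a n_a / (1 + 10^(pKa_a - pH))`
#' with basic groups \{N-terminus, H, K, R\} and acidic groups
#' \{C-terminus, D, E, C, Y\}. `X` residues contribute no charge.
#'
#' @param protein a single-row protein record set.
#' @param pH pH value(s) in \[0, 14\] (vectorized).
#' @param pka a [pka_set()] list.
#' @return Net charge in elementary units, same length as `pH`.
#' @export
net_charge <- function(protein, pH, pka = pka_set("IPC_protein")) {
  cnt <- aa_counts(protein$sequence[1L])
  sc <- pka$side_chains
  basic <- c(`N-term` = pka$n_term,
             stats::setNames(sc[c("H", "K", "R")], c("H", "K", "R")))
  acidic <- c(`C-term` = pka$c_term,
              stats::setNames(sc[c("D", "E", "C", "Y")], c("D", "E", "C", "Y")))
  n_basic <- c(1, as.numeric(cnt[c("H", "K", "R")]))
  n_acidic <- c(1, as.numeric(cnt[c("D", "E", "C", "Y")]))
  vapply(pH, function(p) {
    pos <- sum(n_basic / (1 + 10^(p - basic)))
    neg <- sum(n_acidic / (1 + 10^(acidic - p)))
    pos - neg
  }, numeric(1L))
}

#' Theoretical isoelectric point by bisection
#'
#' Finds the pH in \[0, 14\] where [net_charge()] crosses zero, by bisection
#' to an interval narrower than `tol` pH units. The net charge is strictly
#' decreasing in pH, positive at pH 0 (free N-terminus) and negative at
#' pH 14 (free C-terminus), so the root exists and is unique. Full
#' precision is returned; round to 2 decimals for reporting.
#'
#' @param protein a single-row protein record set.
#' @param pka a [pka_set()] list.
#' @param tol bisection stopping width in pH units.
#' @return The isoelectric point in pH units.
#' @export
isoelectric_point <- function(protein, pka = pka_set("IPC_protein"),
                              tol = 0.001) {
  lo <- 0; hi <- 14
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (net_charge(protein, mid, pka) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Acidic-protein rule
#'
#' A protein is called acidic iff its theoretical pI is strictly below
#' `pi_cut` AND its Asp+Glu fraction is strictly above `de_cut`
#' (defaults 3.5 and 20%).
#'
#' @param pI theoretical isoelectric point (pH units).
#' @param asp_glu_fraction fraction of D plus E residues.
#' @param pi_cut pI cutoff (strict `<`).
#' @param de_cut Asp+Glu fraction cutoff (strict `>`).
#' @return Logical.
#' @export
classify_acidic <- function(pI, asp_glu_fraction, pi_cut = 3.5,
                            de_cut = 0.20) {
  pI < pi_cut & asp_glu_fraction > de_cut
}

#' Physicochemical profile of a record set
#'
#' @param records protein record set.
#' @param pka a [pka_set()] list.
#' @return `data.frame` with columns `protein_id`, `length`, `mw`, `pi`
#'   (full precision), `asp_glu_fraction`, `is_acidic`.
#' @export
physchem_profile <- function(records, pka = pka_set("IPC_protein")) {
  rows <- lapply(seq_len(nrow(records)), function(i) {
    p <- records[i, , drop = FALSE]
    comp <- composition(p)
    pi_val <- isoelectric_point(p, pka)
    data.frame(protein_id = p$id, length = comp$length,
               mw = molecular_weight(p), pi = pi_val,
               asp_glu_fraction = comp$asp_glu_fraction,
               is_acidic = classify_acidic(pi_val, comp$asp_glu_fraction),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
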