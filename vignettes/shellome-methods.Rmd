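---
title: "Methods: how shellome characterizes shell matrix proteins"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: how shellome characterizes shell matrix proteins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shellome)
```

Shell matrix proteins (SMPs) are the proteins occluded in the calcified
shell of molluscs, recovered by decalcifying cleaned shell powder into an
acid-soluble matrix (ASM) and an acid-insoluble matrix (AIM). Most SMPs
have no informative homologs, so their characterization rests on primary
structure: compositional bias, charge, and domain architecture. This
vignette is the package's account of each method, its assumptions, the
parameters that matter, and the choices made where the design was open.

## Low-complexity region detection

### The two window criteria

A low-complexity region (LCR) here is a stretch dominated by one or two
amino-acid types, detected by sliding a window of `window_len = 10`
residues along the sequence:

* **single** — one residue occupies at least `single_min_frac = 50%` of
  the window, sustained over more than 14 consecutive residues
  (`single_min_run = 15`);
* **pair** — the most abundant residue occupies at least
  `pair_first_min_frac = 40%` and a second residue at least
  `pair_second_min_frac = 20%`, sustained over more than 19 consecutive
  residues (`pair_min_run = 20`).

Fractions are applied as integer counts via the ceiling (5, 4 and 2 of 10
at the defaults), so there is no floating-point comparison anywhere in the
criterion. Windows lie fully inside the sequence; a sequence shorter than
the window can hold no LCR. `X` (unknown) counts in the window denominator
but can never be an enriched residue.

### From flagged windows to regions

Flagged windows are turned into regions in three steps: (1) take the union
of positions covered by any flagged window for that residue (or pair);
(2) split into maximal runs of consecutive covered positions; (3) trim
each run to the first and last occurrence of the focal residue(s), and
keep it if the trimmed length meets the run minimum.

The trimming step is the one genuinely open design point. A window
overlapping a biased stretch by only half still satisfies the count
threshold, so untrimmed coverage extends up to `window_len − ⌈f·w⌉`
positions into the unbiased flanks. Without trimming, a pure 14-residue
run embedded in background — below the "more than 14" rule — would
be reported as a ~24-position region, and the criterion's length boundary
would be unfalsifiable on real sequences. Trimming measures every region
on the span of its own biased residues: a 14-run stays 14 and is rejected,
a 15-run is reported at exactly 15. The cost is that a region's endpoints
are always focal residues; for the alternating repeat `"GS" × 10` the pair
region is 1–20 but the single G-rich call is 1–19 and the single S-rich
call 2–20, each trimmed to its own residue's occurrences. Coverage still
merges across short interruptions: in `T×8 A×4 T×8` every window holds at
least five T, so one T-rich region spans 1–20, gap included.

### Ties, coexistence and determinism

All residues and pairs meeting the thresholds are flagged — no single
winner is picked, and ties emit multiple pairs. A pair qualifies when its
better-counted member attains the window maximum and meets the 40% count
and its other member meets the 20% count; with counts G=4, A=2, T=3 in a
window, both {A,G} and {G,T} qualify. Single and pair regions are reported
independently even on identical spans (only exactly identical tuples are
deduplicated): a region can legitimately be T-rich and part of an
ST-rich pair region at once, which is exactly how biased SMP sequences are
annotated in practice. Output is sorted by `(start, kind, residues)` and
labels are alphabetized (`"GS-rich"`), so identical input yields
byte-identical output.

Homopolymer runs (e.g. the 2–15 consecutive aspartates that form acidic
C-terminal tails) are reported by `find_homopolymer_runs()` as maximal
runs above a caller-chosen minimum; they are deliberately separate from
the window criteria, which a short poly-Asp tail does not meet.

## Physicochemical profile

Net charge is the standard Henderson–Hasselbalch sum over ionizable
groups, with basic groups {N-terminus, H, K, R} and acidic groups
{C-terminus, D, E, C, Y} — Cys and Tyr are treated as weak acids, with no
disulfide correction. The theoretical pI is the unique root of the
strictly decreasing charge curve on pH 0–14, found by bisection to a
0.001-pH interval; full precision is kept internally and reporting rounds
to two decimals.

pKa values are named, versioned configuration, never anonymous constants:
`IPC_protein` (default) and `IPC_peptide` are the isoelectric-point
calculator's optimized sets, `EMBOSS` the classic `iep` values. The
default follows the common practice of computing whole-protein pI with the
protein-optimized set; switching sets changes pI by up to ~0.5 pH for
extreme compositions, which is why the set name travels with every
profile. Molecular weight sums Expasy average residue masses plus one
water; `X` contributes a configurable average mass (default: the mean of
the 20 standard residue masses) and never contributes charge.

A protein is *acidic* iff pI < 3.5 and Asp+Glu > 20% of residues. Both
inequalities are strict, matching how such cutoffs are printed; the
boundary cases (pI exactly 3.5, Asp+Glu exactly 20%) are negative.

## Evidence filtering and classification

The two-peptide rule accepts a protein when its distinct peptide total,
summed over all four extracts, is at least `min_peptides = 2`. The sum —
rather than a per-extract threshold — is the committed reading because
extract-specific proteins (present in a single fraction) are an expected
and reported outcome class, and a per-extract rule would silently exclude
any protein identified by one peptide in each of two fractions.

Accepted proteins are partitioned by extract presence in a fixed
precedence: present in all four → `common_to_four`; exactly three →
`in_three`; only ASM extracts → `ASM_specific`; only AIM → `AIM_specific`;
anything else (necessarily one ASM plus one AIM) → `other`. The precedence
makes the classes mutually exclusive and exhaustive, so their counts
always sum to the number of accepted proteins.

Category assignment is hierarchical: any domain in the accession catalog →
`conserved_domain`; otherwise ≥ 1 LCR → `lcr_containing`; otherwise
`uncharacterized`. The catalog is configuration seeded with the accessions
that recur in shell proteomes (chitin-binding PF01607/IPR002557/PF03067,
concanavalin A-like SSF49899, thrombospondin type-1 PF00090, VWA
PF00092/SSF53300, C-type lectin fold SSF56436; glycoside hydrolase PF00150
and tyrosinase PF00264; Kunitz PF00014 and Kazal IPR002350); unknown
accessions never trigger the category, and users extend the catalog rather
than the code. When several catalog domains co-occur the subcategory is
resolved by the fixed precedence polysaccharide affinity > enzyme >
protease inhibitor. LCR labels are recorded for every category, since
modular SMPs routinely combine conserved domains with biased linkers.

BMSP-likeness captures the diagnostic architecture of the Blue Mussel
Shell Protein family: more than one VWA domain in tandem at the
N-terminus, immediately followed by chitin-binding domain(s). Considering
only catalog-categorized domains in start order, the flag requires a
leading block of ≥ 2 VWA and a ChBD as the next categorized domain;
uncategorized hits between them are ignored (domain predictors emit many
overlapping accessions), but any categorized non-ChBD domain breaks the
architecture.

## Phosphorylation overlay

Predicted per-residue phosphorylation probabilities are thresholded
strictly at 0.5 — a site at exactly 0.5 is not "likely". For the overlay,
all LCR spans of a protein are merged into a position set before counting,
so a site under two overlapping regions counts once in `n_in_lcr`;
per-region densities (sites per residue) are still reported against each
original region, because overlapping single and pair calls are distinct
annotations. When a protein has no likely site the fraction is reported as
0 with an explicit `frac_defined = FALSE` flag rather than NA, keeping
downstream aggregation simple while preserving the distinction.

## Lectin-plate normalization

Enzyme-linked lectin assay (ELLA) plates probe matrix glycans with a panel
of biotinylated lectins read as A405 absorbance. Normalization subtracts
the mean of the no-lectin background replicates from every reading,
averages per lectin, and scales so the strongest lectin is exactly 100%;
replicate spread is the sample (n−1) SD on the same scale. Background is
subtracted as a mean because replicate pairing between sample and control
wells is not part of the plate layout. Negative net signals (lectins below
background) are reported as-is by default — clamping is available via
`clamp0 = TRUE` but changes means and SDs and is therefore opt-in. The
normalization is invariant to a shared gain or offset applied to all
readings including background, and exactly one lectin (or a tied set)
attains 100%; an all-background plate is an error, not a silent zero.

## The synthetic-data generator

The generator exists so that every stage can be validated against known
ground truth without the original survey's raw data. It emulates, under a
single integer seed:

* protein sequences of 60–120 residues (uniform background over the 20
  standard residues) with planted biased stretches and optional poly-Asp
  C-terminal tails, with every planted span recorded in a truth table;
* four-extract evidence tables built from deterministic templates, one
  per presence class, plus a `rejected` template that fails the
  two-peptide rule;
* phosphorylation tracks covering every S/T/Y, with likely sites placed
  inside planted LCRs at one rate and outside at another;
* a 21-lectin plate with Gaussian replicate noise (SD 0.05) and a
  background well at 0.1.

Two generator choices deserve explanation. First, **clean mode**: the
background of each protein excludes that protein's planted focal residues,
and a candidate sequence is redrawn unless every detected region is
attributable to a plant (its residues a subset of the plant's focal set,
its span inside the planted span ± one window). This makes recovery
experiments exact — recall has to be 100%, and sub-threshold plants have
to yield zero detections — at the price of realism; `clean = FALSE`
disables both behaviours when false-positive behaviour on arbitrary
backgrounds is the thing under study.

Second, **pair plants are not two-residue-only stretches**. In any window
over a two-letter alphabet one residue necessarily holds ≥ 50%, so a pure
alternating pair stretch of length ≥ 16 always contains single-residue
LCRs as well, and a pair plant could never test the pair criterion in
isolation. Pair plants are therefore a 10-periodic motif holding every
window at exactly the pair thresholds — four of the first residue, two of
the second, four background positions — with a focal residue pinned at
each end so the trimmed detected span equals the planted span. Single
plants are pure runs. Likely/unlikely phosphorylation probabilities are
drawn as `0.5 + 0.5·Beta(2,2)` and `0.5·Beta(2,2)` respectively: both are
proper distributions with interior modes, and the split at 0.5 is exact,
so threshold guarantees in tests are structural rather than statistical.

What passing on synthetic data does **not** show: real SMP backgrounds are
not uniform (shell proteomes are themselves biased toward G/A/S/T/D),
real LCRs have ragged edges and impurities, real evidence counts are not
deterministic templates, and real phosphorylation predictors correlate
neighbouring sites. The generator demonstrates correctness of the
machinery, not field performance.

## Numerical choices and degenerate inputs

* Window thresholds as ceiled integer counts; no floating-point
  comparisons in LCR detection.
* Bisection on [0, 14] with a 0.001-pH stopping width; the charge curve
  is strictly decreasing with guaranteed sign change (free termini), so
  no bracketing failures exist.
* Sequences shorter than the window, proteins with no S/T/Y, empty domain
  tables and header-only annotation files all yield well-typed empty
  results; zero-length sequences, duplicate ids, illegal characters,
  inverted domain coordinates, probabilities outside [0, 1] and plates
  without a background row are errors with the offending record or line
  named.
* All readers treat coordinates as 1-based and inclusive on both ends,
  the domain-annotation convention.
* FASTA is written wrapped at 60 characters; a single trailing `*` stop
  symbol is stripped on read, internal stops are rejected.

## Problem sizes used in validation

The shipped tests and the acceptance script validate on: 500 random
sequences of length 30–80 against the brute-force window-recount oracle
(plus 300 in the unit suite); 200 clean-mode proteins with planted single
(15–30) and pair (20–40) LCRs for recovery, and 40 sub-threshold plants;
100 random sequences for bisection-vs-grid pI agreement on a 0.0005-pH
grid; a 30-protein mixed cohort for end-to-end category and presence
accounting; and 21-lectin plates for normalization round-trips. These
sizes give exact (not sampled) guarantees wherever the clean-mode
construction applies, and they run in well under a minute each.

## Known limitations

* The LCR criteria are compositional, not entropy-based; they will not
  flag regions of mixed low complexity that never concentrate one or two
  residues (a SEG-style detector is a non-goal).
* pI assumes free termini, no post-translational modifications and no
  disulfides; phosphorylation, in particular, lowers effective pI in ways
  the theoretical value cannot reflect.
* The domain catalog triggers on exactly its accession strings; predictor
  output using other member-database accessions for the same families
  must be mapped into the catalog by the user.
* The plate module takes one prepared reading set per plate; kinetic
  series from repeated reads are out of scope.
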