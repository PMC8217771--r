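test_that("purity-1 plants appear verbatim at the recorded span", {
  spec <- synth_spec(n_proteins = 3, planted_lcrs = list(
    list(kind = "single", residues = "T", length = 20, purity = 1)),
    seed = 101)
  gp <- gen_protein_set(spec)
  tr <- gp$truth$lcrs
  expect_equal(nrow(tr), 1L)
  planted <- substr(gp$records$sequence[1], tr$start, tr$end)
  expect_equal(planted, strrep("T", 20))
})

test_that("the corpus is byte-identical under the same seed", {
  spec <- synth_spec(n_proteins = 8, planted_lcrs = list(
    list(kind = "pair", residues = "GS", length = 25, purity = 1)),
    planted_polyD_tail = 8, seed = 55)
  a <- gen_protein_set(spec)
  b <- gen_protein_set(spec)
  expect_identical(a, b)
  expect_identical(gen_phospho(spec, a$records, a$truth),
                   gen_phospho(spec, b$records, b$truth))
  expect_identical(gen_plate(spec)$plate$absorbance,
                   gen_plate(spec)$plate$absorbance)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_fasta(a$records, f1); write_fasta(b$records, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("clean-mode plants are recovered exactly; short plants never fire", {
  set.seed(NULL)
  n <- 40
  plants <- lapply(seq_len(n), function(i) {
    if (i %% 2 == 1) list(kind = "single", residues = "T",
                          length = sample(15:30, 1), purity = 1)
    else list(kind = "pair", residues = "GS",
              length = sample(20:40, 1), purity = 1)
  })
  spec <- synth_spec(n_proteins = n, planted_lcrs = plants, seed = 77)
  gp <- gen_protein_set(spec)
  lcrs <- detect_lcrs_all(gp$records)
  for (i in seq_len(nrow(gp$truth$lcrs))) {
    tr <- gp$truth$lcrs[i, ]
    hit <- lcrs[lcrs$protein_id == tr$protein_id & lcrs$kind == tr$kind &
                  lcrs$residues == tr$residues, ]
    expect_equal(nrow(hit), 1L)
    expect_lte(hit$start, tr$start)
    expect_gte(hit$end, tr$end)
  }
  # sub-threshold plants yield no detections at all in clean mode
  short <- synth_spec(n_proteins = 20, planted_lcrs = c(
    lapply(1:10, function(i) list(kind = "single", residues = "T",
                                  length = 14, purity = 1)),
    lapply(1:10, function(i) list(kind = "pair", residues = "GS",
                                  length = 19, purity = 1))),
    seed = 78)
  gps <- gen_protein_set(short)
  expect_equal(nrow(detect_lcrs_all(gps$records)), 0L)
})

test_that("poly-Asp tails are planted at the C-terminus and found", {
  spec <- synth_spec(n_proteins = 4, planted_polyD_tail = 7, seed = 91)
  gp <- gen_protein_set(spec)
  tail_id <- gp$records$id[4]
  runs <- find_homopolymer_runs(gp$records[4, ], "D", 5)
  expect_equal(nrow(runs), 1L)
  expect_equal(runs$end, nchar(gp$records$sequence[4]))
  expect_equal(runs$length, 7L)
  expect_equal(gp$truth$polyD$protein_id, tail_id)
})

test_that("evidence templates reproduce every presence class", {
  spec <- synth_spec(n_proteins = 6,
                     evidence_pattern = c("common_to_four", "in_three",
                                          "ASM_specific", "AIM_specific",
                                          "other", "rejected"),
                     seed = 5)
  ids <- sprintf("SYN_%04d", 1:6)
  ev <- gen_evidence(spec, ids)
  rule <- apply_peptide_rule(ev)
  expect_setequal(rule$protein_id[rule$accepted], ids[1:5])
  expect_false(rule$accepted[rule$protein_id == ids[6]])
  part <- presence_partition(presence_sets(ev)[ids[1:5]])
  expect_equal(unname(part$classes[ids[1:5]]),
               c("common_to_four", "in_three", "ASM_specific",
                 "AIM_specific", "other"))
})

test_that("phospho tracks respect the threshold split and LCR placement", {
  plants <- lapply(1:10, function(i) list(kind = "single", residues = "S",
                                          length = 20, purity = 1))
  spec <- synth_spec(n_proteins = 10, planted_lcrs = plants,
                     phospho_rate_in_lcr = 1, phospho_rate_outside = 0,
                     seed = 7)
  gp <- gen_protein_set(spec)
  ph <- gen_phospho(spec, gp$records, gp$truth)
  expect_true(all(ph$probability >= 0 & ph$probability <= 1))
  lcrs <- detect_lcrs_all(gp$records)
  for (i in seq_len(nrow(gp$records))) {
    id <- gp$records$id[i]
    sites <- likely_sites(ph[ph$protein_id == id, ])
    ov <- overlay_lcr(sites, lcrs[lcrs$protein_id == id, ],
                      nchar(gp$records$sequence[i]))
    if (ov$n_likely > 0) expect_equal(ov$frac_in_lcr, 1.0)
  }
})

test_that("a noiseless plate round-trips to the programmed percentages", {
  spec <- synth_spec(plate_spec = list(
    lectins = c("Jacalin", "DSL", "LEL"), true_values = c(1.0, 0.8, 0.45),
    background = 0.1, noise_sd = 0, n_rep = 3), seed = 3)
  gpl <- gen_plate(spec)
  out <- normalize_plate(gpl$plate)
  expect_equal(stats::setNames(out$mean_percent, out$lectin),
               gpl$truth_percent, tolerance = 1e-12)
  expect_equal(out$mean_percent, c(100, 80, 45))
})
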