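test_that("single-residue window flagging applies the count threshold", {
  f <- flag_windows_single("AAAAAGGGGG")
  expect_setequal(names(f), c("A", "G"))  # both exactly at 50%
  expect_equal(f$A, 1L)

  f <- flag_windows_single("AAAAGGGGGG")
  expect_equal(names(f), "G")  # A at 4/10 misses the ceiling count of 5

  expect_equal(flag_windows_single("ACDEF"), list())  # shorter than window
  # 'X' never flagged even when dominant
  expect_false("X" %in% names(flag_windows_single(strrep("X", 20))))
})

test_that("pair flagging emits every qualifying pair, ties included", {
  f <- flag_windows_pair("GSGSGSGSGS")
  expect_equal(names(f), "GS")

  # G=4 (max, >=4), A=2 and T=3 (each >=2): both pairs qualify
  f <- flag_windows_pair("GGGGAATTTC")
  expect_setequal(names(f), c("AG", "GT"))

  expect_equal(flag_windows_pair("ACDEFGHIKL"), list())  # max count 1
})

test_that("biased-stretch length boundaries are exact", {
  expect_equal(nrow(detect_lcrs(rec1(strrep("A", 15)))), 1L)
  r <- detect_lcrs(rec1(strrep("A", 15)))
  expect_equal(r[, c("kind", "residues", "start", "end", "label")],
               data.frame(kind = "single", residues = "A", start = 1L,
                          end = 15L, label = "A-rich",
                          stringsAsFactors = FALSE),
               ignore_attr = TRUE)
  expect_equal(nrow(detect_lcrs(rec1(strrep("A", 14)))), 0L)
})

test_that("coverage merges across a short interruption", {
  r <- detect_lcrs(rec1(paste0(strrep("T", 8), strrep("A", 4),
                               strrep("T", 8))))
  single <- r[r$kind == "single", ]
  expect_equal(single$residues, "T")
  expect_equal(c(single$start, single$end), c(1L, 20L))
  # the A/T pair criterion is also met in every window; no suppression
  pair <- r[r$kind == "pair", ]
  expect_equal(pair$residues, "AT")
  expect_equal(c(pair$start, pair$end), c(1L, 20L))
})

test_that("single and pair regions coexist on an alternating repeat", {
  r <- detect_lcrs(rec1(strrep("GS", 10)))
  pair <- r[r$kind == "pair", ]
  expect_equal(pair$residues, "GS")
  expect_equal(pair$label, "GS-rich")  # alphabetized, never SG-rich
  expect_equal(c(pair$start, pair$end, pair$length), c(1L, 20L, 20L))
  singles <- r[r$kind == "single", ]
  expect_setequal(singles$residues, c("G", "S"))
  # spans trimmed to each residue's own occurrences
  expect_equal(singles$start[singles$residues == "G"], 1L)
  expect_equal(singles$end[singles$residues == "G"], 19L)
  expect_equal(singles$start[singles$residues == "S"], 2L)
  expect_equal(singles$end[singles$residues == "S"], 20L)
})

test_that("a biased run flanked by background is measured on its own length", {
  # 14 consecutive T in a non-T background: flagged windows overhang the
  # run, but the region is trimmed to the T span, below the 15 minimum
  seq14 <- paste0(strrep("KVLENMRI", 4), strrep("T", 14), strrep("VKLE", 6))
  expect_equal(nrow(detect_lcrs(rec1(seq14))), 0L)
  seq15 <- paste0(strrep("KVLENMRI", 4), strrep("T", 15), strrep("VKLE", 6))
  r <- detect_lcrs(rec1(seq15))
  expect_equal(nrow(r), 1L)
  expect_equal(c(r$start, r$end), c(33L, 47L))
})

test_that("detect_lcrs matches the brute-force oracle on random sequences", {
  set.seed(42)
  params <- lcr_params()
  for (i in 1:300) {
    s <- random_biased_seq(sample(30:80, 1))
    got <- detect_lcrs(rec1(s), params)
    want <- oracle_lcr(s, params)
    expect_identical(lcr_spans_key(got), lcr_spans_key(want),
                     label = paste("sequence", s))
  }
})

test_that("identical input gives byte-identical output", {
  s <- random_biased_seq(200)
  expect_identical(detect_lcrs(rec1(s)), detect_lcrs(rec1(s)))
})

test_that("lengthening a planted stretch never removes a region", {
  set.seed(7)
  bg <- paste(sample(c("K", "V", "L", "E", "N", "M"), 60, TRUE),
              collapse = "")
  for (len in 15:40) {
    s <- paste0(substr(bg, 1, 30), strrep("Q", len), substr(bg, 31, 60))
    r <- detect_lcrs(rec1(s))
    q <- r[r$kind == "single" & r$residues == "Q", ]
    expect_equal(nrow(q), 1L)
    expect_true(q$start <= 31 && q$end >= 30 + len)
    # every reported region satisfies its length invariant
    expect_true(all(r$length[r$kind == "single"] >= 15))
    expect_true(all(r$length[r$kind == "pair"] >= 20))
  }
})

test_that("homopolymer runs are maximal and ordered", {
  r <- find_homopolymer_runs(rec1("KKDDDDDK"), "D", 5)
  expect_equal(c(r$start, r$end, r$length), c(3L, 7L, 5L))

  r <- find_homopolymer_runs(rec1("DDKDD"), "D", 2)
  expect_equal(r$start, c(1L, 4L))
  expect_equal(r$end, c(2L, 5L))

  set.seed(11)
  for (i in 1:50) {
    s <- paste(sample(c("D", "K", "E"), 200, TRUE, c(0.4, 0.3, 0.3)),
               collapse = "")
    got <- find_homopolymer_runs(rec1(s), "D", 3)
    want <- oracle_runs(s, "D", 3)
    expect_equal(got$start, want$start)
    expect_equal(got$end, want$end)
  }
})
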