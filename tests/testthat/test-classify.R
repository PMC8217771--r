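ev_row <- function(id, extract, n) {
  data.frame(protein_id = id, extract_id = extract, peptide_count = n,
             stringsAsFactors = FALSE)
}

dom_row <- function(acc, start, id = "p") {
  data.frame(protein_id = id, source = "synthetic", accession = acc,
             name = acc, start = start, end = start + 49L,
             stringsAsFactors = FALSE)
}

no_doms <- dom_row("PF01607", 1)[0, ]

test_that("two-peptide rule sums distinct peptides over extracts", {
  ev <- rbind(ev_row("p1", "ASM_2bl", 3),
              ev_row("p2", "ASM_2bl", 1),
              ev_row("p3", "ASM_2bl", 1), ev_row("p3", "AIM_3bl", 1))
  rule <- apply_peptide_rule(ev)
  acc <- rule$protein_id[rule$accepted]
  expect_setequal(acc, c("p1", "p3"))  # p2's single peptide is not enough
  expect_setequal(presence_sets(ev)$p3, c("ASM_2bl", "AIM_3bl"))
})

test_that("presence classes are assigned by precedence and are exhaustive", {
  pres <- list(
    a = c("ASM_2bl", "ASM_3bl", "AIM_2bl", "AIM_3bl"),
    b = c("ASM_2bl", "ASM_3bl", "AIM_2bl"),
    c = c("ASM_2bl"),
    d = c("ASM_2bl", "ASM_3bl"),
    e = c("AIM_2bl", "AIM_3bl"),
    f = c("AIM_3bl"),
    g = c("ASM_2bl", "AIM_3bl"),
    h = c("ASM_3bl", "AIM_2bl"),
    i = c("ASM_2bl", "ASM_3bl", "AIM_3bl"),
    j = c("AIM_2bl")
  )
  part <- presence_partition(pres)
  expect_equal(unname(part$classes[c("a", "b", "c", "d", "e")]),
               c("common_to_four", "in_three", "ASM_specific",
                 "ASM_specific", "AIM_specific"))
  expect_equal(unname(part$classes[c("g", "h")]), c("other", "other"))
  expect_equal(sum(part$counts), length(pres))
  expect_equal(unname(part$counts),
               c(1L, 2L, 2L, 3L, 2L))  # hand enumeration of the ten
  expect_error(presence_partition(list(z = "XYZ")), "unknown extract")
})

test_that("BMSP architecture needs >=2 N-terminal VWA then ChBD", {
  vwa4_chbd <- rbind(dom_row("PF00092", 1), dom_row("PF00092", 60),
                     dom_row("PF00092", 120), dom_row("SSF53300", 180),
                     dom_row("PF01607", 240))
  b <- detect_bmsp_architecture(vwa4_chbd)
  expect_equal(b$n_vwa, 4L)
  expect_gte(b$n_chbd_following, 1L)
  expect_true(b$bmsp_like)

  # order matters: given unsorted rows, sorting is internal
  expect_true(detect_bmsp_architecture(
    vwa4_chbd[sample(nrow(vwa4_chbd)), ])$bmsp_like)

  wrong_order <- rbind(dom_row("PF01607", 1), dom_row("PF00092", 60),
                       dom_row("PF00092", 120))
  expect_false(detect_bmsp_architecture(wrong_order)$bmsp_like)

  one_vwa <- rbind(dom_row("PF00092", 1), dom_row("PF01607", 60))
  expect_false(detect_bmsp_architecture(one_vwa)$bmsp_like)  # "more than one"

  # an intervening categorized non-ChBD domain breaks the architecture
  interposed <- rbind(dom_row("PF00092", 1), dom_row("PF00092", 60),
                      dom_row("PF00150", 120), dom_row("PF01607", 180))
  expect_false(detect_bmsp_architecture(interposed)$bmsp_like)

  # uncategorized domains are ignored entirely
  with_unknown <- rbind(dom_row("PF00092", 1), dom_row("PF99999", 30),
                        dom_row("PF00092", 60), dom_row("PF01607", 120))
  expect_true(detect_bmsp_architecture(with_unknown)$bmsp_like)
})

test_that("architecture sweep: flag true exactly for VWA-block-then-ChBD", {
  arch <- function(types) {
    acc <- c(VWA = "PF00092", ChBD = "PF01607", other = "PF00150")
    do.call(rbind, lapply(seq_along(types), function(i) {
      dom_row(acc[[types[i]]], i * 60L)
    }))
  }
  cases <- list(c("VWA", "VWA", "ChBD"), c("VWA", "VWA", "VWA", "ChBD"),
                c("VWA", "ChBD"), c("ChBD", "VWA", "VWA", "ChBD"),
                c("VWA", "VWA"), c("VWA", "VWA", "other", "ChBD"),
                c("other", "VWA", "VWA", "ChBD"), c("ChBD", "ChBD"))
  want <- c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE)
  got <- vapply(cases, function(ts) {
    detect_bmsp_architecture(arch(ts))$bmsp_like
  }, logical(1))
  expect_equal(got, want)
})

test_that("categories are assigned with domain > LCR > neither precedence", {
  p <- rec1(strrep("T", 60), id = "p")
  lcr_t <- detect_lcrs(p)

  cls <- classify_protein(p, dom_row("PF01607", 1), lcr_t)
  expect_equal(cls$category, "conserved_domain")
  expect_equal(cls$subcategory, "polysaccharide_affinity")
  expect_true(grepl("T-rich", cls$lcr_labels_single))  # labels retained

  cls <- classify_protein(p, no_doms, lcr_t)
  expect_equal(cls$category, "lcr_containing")
  expect_equal(cls$subcategory, "none")

  cls <- classify_protein(rec1("MKVLE", id = "p"), no_doms,
                          detect_lcrs(rec1("MKVLE", id = "p")))
  expect_equal(cls$category, "uncharacterized")

  # subcategory precedence when several catalog domains co-occur
  multi <- rbind(dom_row("PF00014", 1), dom_row("PF00150", 60),
                 dom_row("PF01607", 120))
  expect_equal(classify_protein(p, multi, lcr_t)$subcategory,
               "polysaccharide_affinity")
  expect_equal(classify_protein(p, multi[1:2, ], lcr_t)$subcategory,
               "enzyme")
  # unknown accessions never trigger the conserved-domain category
  expect_equal(classify_protein(p, dom_row("PF99999", 1), lcr_t)$category,
               "lcr_containing")
})

test_that("category counts are exhaustive and order-invariant", {
  set.seed(21)
  rec <- protein_records(
    paste0("p", 1:6),
    c(strrep("T", 60), strrep("GS", 30), paste(
      sample(c("K", "V", "L", "E"), 60, TRUE), collapse = ""),
      strrep("A", 60), paste(sample(c("M", "N", "R", "I"), 60, TRUE),
                             collapse = ""), strrep("D", 60)))
  doms <- rbind(dom_row("PF01607", 1, "p3"), dom_row("PF00014", 1, "p5"))
  lcrs <- detect_lcrs_all(rec)
  cls <- classify_proteins(rec, doms, lcrs)
  expect_equal(nrow(cls), 6L)
  expect_equal(sum(table(cls$category)), 6L)
  expect_setequal(cls$category[cls$protein_id %in% c("p3", "p5")],
                  "conserved_domain")
  # shuffling domain and LCR rows changes nothing
  cls2 <- classify_proteins(rec, doms[sample(nrow(doms)), ],
                            lcrs[sample(nrow(lcrs)), ])
  expect_equal(cls, cls2)
})
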