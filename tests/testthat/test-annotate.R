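test_that("signal heuristic calls a canonical signal and rejects a polar N-terminus", {
  sig <- predict_signal("MKTFLVLLLVLAVFSEAFMRFGKRFMRFGKRY")
  expect_true(sig$present)
  expect_equal(sig$cleavage_after, 17L)
  expect_equal(sig$source, "heuristic")
  expect_true(sig$score > 0.5 && sig$score <= 1)

  none <- predict_signal(paste0(strrep("D", 12), strrep("E", 12), "FMRFGKR"))
  expect_false(none$present)
  expect_equal(none$cleavage_after, 0L)

  expect_error(predict_signal("MKTFLV"), "15")

  ext <- signal_call(TRUE, 22L, 0.9)
  out <- predict_signal("IRRELEVANTSEQX", "external", external_call = ext)
  expect_equal(out$cleavage_after, 22L)
  expect_equal(out$source, "external")
  expect_error(predict_signal("MKTFLVLLLVLAVFSEA", "external"), "external_call")
  expect_error(signal_call(TRUE, 61L), "60")
})

test_that("cleavage sites are maximal basic runs, with optional monobasic calls", {
  s <- find_cleavage_sites("FMRFGKRFLRFGRK")
  expect_equal(s$start, c(6L, 13L))
  expect_equal(s$end, c(7L, 14L))
  expect_equal(s$kind, c("dibasic", "dibasic"))

  m <- find_cleavage_sites("AAKRRAA")
  expect_equal(m[, 1:3], tibble::tibble(start = 3L, end = 5L,
                                        kind = "multibasic"))

  expect_equal(nrow(find_cleavage_sites("AAARAAA", "dibasic_only")), 0)
  expect_equal(nrow(find_cleavage_sites("AAARAAA", "dibasic_and_monobasic")), 0)

  # isolated basic with a basic 2 positions upstream is a monobasic site;
  # one without that context is not
  mono <- find_cleavage_sites("AARAKAA", "dibasic_and_monobasic")
  expect_equal(mono$kind, "monobasic")
  expect_equal(mono$start, 5L)
})

test_that("peptide enumeration cleaves, amidates and classifies", {
  aa <- "FMRFGKRFLRFGRK"
  pep <- enumerate_peptides(aa, find_cleavage_sites(aa))
  expect_equal(pep$seq, c("FMRF", "FLRF"))
  expect_true(all(pep$amidated))
  expect_equal(pep$classification, c("RFamide", "RFamide"))
  expect_equal(pep$copy_group, c(1L, 2L))

  aa2 <- paste0("QLHNFVRFG", "KR", "AAAA")
  pep2 <- enumerate_peptides(aa2, find_cleavage_sites(aa2))
  expect_equal(pep2$seq[1], "QLHNFVRF")
  expect_true(pep2$amidated[1])
  expect_equal(pep2$classification[1], "RFamide")

  aa3 <- paste0("GFDRISGASDFGGFG", "KR", "AAAA")
  pep3 <- enumerate_peptides(aa3, find_cleavage_sites(aa3))
  expect_equal(pep3$seq[1], "GFDRISGASDFGGF")
  expect_equal(pep3$classification[1], "other_amide")

  # a terminal Gly has no convertase context and stays un-amidated
  aa4 <- paste0("FMRFG", "KR", "AAAG")
  pep4 <- enumerate_peptides(aa4, find_cleavage_sites(aa4))
  expect_equal(pep4$seq[2], "AAAG")
  expect_false(pep4$amidated[2])

  # sub-threshold segments become linker fragments, not counted peptides
  aa5 <- paste0("FMRFG", "KR", "AQ", "KR", "FLRFG", "KR")
  pep5 <- enumerate_peptides(aa5, find_cleavage_sites(aa5))
  expect_equal(pep5$is_linker, c(FALSE, TRUE, FALSE))
  expect_equal(pep5$seq[2], "AQ")

  expect_error(
    enumerate_peptides("AAAA", tibble::tibble(start = 3L, end = 9L,
                                              kind = "dibasic")),
    "out of bounds"
  )
})

test_that("classification follows the amidation-dependent family rules", {
  expect_equal(classify_peptide("GSLFRF", TRUE), "RFamide")
  expect_equal(classify_peptide("GSLFRF", FALSE), "non_amide")
  expect_equal(classify_peptide("QLHNFVRF", TRUE), "RFamide")
  expect_equal(classify_peptide("AFMRI", TRUE), "excluded_FxRIamide")
  expect_equal(classify_peptide("AFMRI", FALSE), "non_amide")
  expect_equal(classify_peptide("GFDRISGASDFGGF", TRUE), "other_amide")
  expect_equal(classify_peptide("RF", TRUE), "RFamide")
})

test_that("copy counting groups identical peptides, order-invariantly", {
  pep <- tibble::tibble(
    seq = c("FMRF", "FMRF", "FLRF", "FMRF", "FMRF"),
    start = 1:5, end = 1:5, amidated = TRUE,
    classification = "RFamide", is_linker = FALSE, copy_group = 1L
  )
  tab <- count_copies(pep)
  expect_equal(tab$seq, c("FMRF", "FLRF"))
  expect_equal(tab$copies, c(4L, 1L))
  expect_equal(sum(tab$copies), sum(!pep$is_linker))
  shuffled <- pep[c(3, 5, 1, 4, 2), ]
  expect_equal(count_copies(shuffled), tab)
  expect_equal(nrow(count_copies(pep[0, ])), 0)
})

test_that("annotate_precursor composes the full annotation", {
  aa <- paste0("MKTFLVLLLVLAVFSEA", "FMRFGKR", "FMRFGKR", "YPESAD")
  ann <- annotate_precursor(aa)
  expect_s3_class(ann, "precursor_annotation")
  expect_equal(ann$n_peptides, 3L)
  expect_equal(ann$n_rfamides, 2L)
  expect_equal(ann$copy_table$copies[1], 2L)
  expect_equal(reconstruct_precursor(ann), aa)
  expect_equal(glance(ann)$n_rfamides, 2L)
  expect_equal(nrow(tidy(ann)), 3L)

  flat <- annotate_precursor("MKTFLVLLLVLAVFSEAQQQQWWWWQQQQ")
  expect_equal(flat$n_peptides, 1L)
  expect_equal(flat$peptides$classification, "non_amide")
  expect_equal(reconstruct_precursor(flat), "MKTFLVLLLVLAVFSEAQQQQWWWWQQQQ")
})

test_that("stored classifications match recomputation and reconstruction holds", {
  withr::with_seed(12, specs <- replicate(60, random_precursor_spec(),
                                          simplify = FALSE))
  for (i in seq_along(specs)) {
    built <- build_precursor(specs[[i]], 1000 + i)
    ann <- annotate_precursor(
      built$protein, pipeline_config(signal_mode = "external"),
      external_signal = signal_call(TRUE, specs[[i]]$signal_len, 1, "external")
    )
    expect_equal(reconstruct_precursor(ann), built$protein)
    real <- ann$peptides[!ann$peptides$is_linker, ]
    expect_equal(real$classification,
                 classify_peptide(real$seq, real$amidated))
    expect_true(ann$n_rfamides <= ann$n_peptides)
  }
})

test_that("adding monobasic sites refines, never coarsens, the dibasic segmentation", {
  withr::with_seed(44, {
    seqs <- replicate(40, random_aa(80, chars = c(
      strsplit("ACDEFGHILMNPQSTVWY", "")[[1]], "R", "K", "R", "K", "G"
    )))
  })
  for (s in seqs) {
    di <- find_cleavage_sites(s, "dibasic_only")
    both <- find_cleavage_sites(s, "dibasic_and_monobasic")
    # every dibasic boundary persists
    expect_true(all(di$start %in% both$start))
    pep_di <- enumerate_peptides(s, di)
    pep_both <- enumerate_peptides(s, both)
    # refinement: each peptide under the richer rule nests inside one
    # dibasic-rule segment
    for (j in seq_len(nrow(pep_both))) {
      expect_true(any(pep_both$start[j] >= pep_di$start &
                        pep_both$end[j] <= pep_di$end |
                        pep_both$is_linker[j]))
    }
  }
})
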