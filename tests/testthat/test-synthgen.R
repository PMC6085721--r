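test_that("build_precursor mirrors tandem-repeat prohormone architecture", {
  built <- build_precursor(farp_a_spec(), 42)
  expect_equal(lengths(regmatches(built$protein,
                                  gregexpr("FMRFGKR", built$protein))), 4L)
  expect_equal(built$truth$n_peptides, 4L)
  expect_equal(built$truth$n_rfamides, 4L)
  expect_equal(built$truth$peptides$seq, rep("FMRF", 4))

  # a large mixed-cassette precursor: 42 products, only 2 of them RFamides
  pp_spec <- precursor_spec(
    data.frame(
      peptide = c("GFDRISGASDFGGF", "PLDSVYGTHGMSAW", "GSLFRF", "QDFLNSAW"),
      copies = c(20L, 18L, 2L, 2L),
      amidated = c(TRUE, TRUE, TRUE, FALSE)
    ),
    signal_len = 20L
  )
  built_pp <- build_precursor(pp_spec, 9)
  expect_equal(built_pp$truth$n_peptides, 42L)
  expect_equal(built_pp$truth$n_rfamides, 2L)

  expect_identical(build_precursor(farp_a_spec(), 7)$protein,
                   build_precursor(farp_a_spec(), 7)$protein)
  expect_false(identical(build_precursor(farp_a_spec(), 7)$protein,
                         build_precursor(farp_a_spec(), 8)$protein))

  # cassettes that would blur the planted cleavage architecture are refused
  expect_error(precursor_spec(data.frame(peptide = "FMRK", copies = 1,
                                         amidated = TRUE)), "blur")
  expect_error(precursor_spec(data.frame(peptide = "FMRFG", copies = 1,
                                         amidated = FALSE)), "blur")
})

test_that("planted proteins are regenerated exactly by the default annotation rules", {
  withr::with_seed(77, specs <- replicate(50, random_precursor_spec(),
                                          simplify = FALSE))
  for (i in seq_along(specs)) {
    built <- build_precursor(specs[[i]], 5000 + i)
    ann <- annotate_precursor(
      built$protein, pipeline_config(signal_mode = "external"),
      external_signal = signal_call(TRUE, specs[[i]]$signal_len, 1, "external")
    )
    tp <- built$truth$peptides
    expect_equal(ann$peptides$seq, tp$seq)
    expect_equal(ann$peptides$start, tp$start)
    expect_equal(ann$peptides$end, tp$end)
    expect_equal(ann$peptides$amidated, tp$amidated)
    expect_equal(ann$peptides$classification, tp$classification)
    expect_equal(ann$n_peptides, built$truth$n_peptides)
    # and the built-in heuristic finds the planted signal
    expect_true(predict_signal(built$protein)$present)
  }
})

test_that("reverse translation round-trips under uniform codon usage", {
  withr::with_seed(23, prots <- replicate(60, random_aa(sample(5:60, 1))))
  for (i in seq_along(prots)) {
    nt <- encode_to_nucleotide(prots[[i]], i)
    expect_equal(nchar(nt), 3L * nchar(prots[[i]]))
    expect_equal(translate_frame(nt), prots[[i]])
  }
  expect_identical(encode_to_nucleotide("MFRF", 3),
                   encode_to_nucleotide("MFRF", 3))
  expect_error(encode_to_nucleotide("MF*F", 1), "stops")
})

test_that("generate_transcriptome plants precursors with complete bookkeeping", {
  sim <- generate_transcriptome(50, 10, farp_a_spec(), rng_seed = 7)
  expect_equal(nrow(sim$contigs), 50)
  expect_equal(sum(sim$truth$contigs$planted), 10)
  expect_setequal(sim$truth$contigs$contig_id, sim$contigs$id)
  expect_identical(
    generate_transcriptome(20, 4, farp_a_spec(), rng_seed = 3)$contigs,
    generate_transcriptome(20, 4, farp_a_spec(), rng_seed = 3)$contigs
  )
  # the planted ORF is exactly the precursor protein
  planted <- sim$truth$contigs[sim$truth$contigs$planted, ][1, ]
  contig <- sim$contigs$seq[sim$contigs$id == planted$contig_id]
  cds <- substr(contig, planted$cds_start, planted$cds_end)
  expect_equal(translate_frame(cds), planted$protein)
})

test_that("a minus-strand plant is missed sense-only and found in six frames", {
  sim <- generate_transcriptome(8, 2, farp_a_spec(strand = -1L), rng_seed = 11)
  res3 <- run_pipeline(sim$contigs, pipeline_config(mode = "sense3"))
  res6 <- run_pipeline(sim$contigs, pipeline_config(mode = "both6"))
  expect_equal(recovery_report(sim$truth, res3$annotations)$recall, 0)
  expect_equal(recovery_report(sim$truth, res6$annotations)$recall, 1)
  strands <- vapply(res6$annotations, function(a) a$strand, integer(1))
  expect_true(all(strands == -1L))
})

test_that("recovery_report handles degenerate runs by convention", {
  sim <- generate_transcriptome(5, 1, farp_a_spec(), rng_seed = 2)
  empty <- recovery_report(sim$truth, list())
  expect_equal(empty$recall, 0)
  expect_true(is.na(empty$precision))

  none <- generate_transcriptome(5, 0, farp_a_spec(), rng_seed = 2)
  vac <- recovery_report(none$truth, list())
  expect_equal(vac$recall, 1)
  expect_equal(vac$n_candidates, 0)
})

test_that("chance signature hits on pure noise match the composition model", {
  gc <- 0.6
  p_hit <- expected_signature_rate(c(A = 0.2, C = 0.3, G = 0.3, T = 0.2))
  sim <- generate_transcriptome(300, 0, farp_a_spec(),
                                noise_len_range = c(3000L, 3000L),
                                rng_seed = 19, gc = gc)
  frames <- translate_all_frames(sim$contigs, "both6")
  n_hits <- sum(lengths(lapply(frames$aa_seq, scan_signature)))
  n_pos <- sum(pmax(0L, nchar(frames$aa_seq) - 4L))
  expected <- n_pos * p_hit
  se <- sqrt(n_pos * p_hit * (1 - p_hit))
  expect_lt(abs(n_hits - expected), 3 * se + 1e-9)
})
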