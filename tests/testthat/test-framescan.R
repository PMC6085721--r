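test_that("translate_frame follows the standard code with stops and ambiguity", {
  expect_equal(translate_frame("ATGTTTCGATTT"), "MFRF")
  expect_equal(translate_frame("CGCTTCGGAAAACGA"), "RFGKR")
  expect_equal(translate_frame("ATGTAAATG"), "M*M")
  expect_equal(translate_frame("ATGNNNTTT"), "MXF")
  expect_equal(translate_frame("ATGTTTC", frame = 1), "CF")  # remainder dropped
  expect_equal(translate_frame("AT"), "")
  expect_error(translate_frame("ATG", frame = 3), "frame")
  expect_error(translate_frame("ATG", strand = 2), "strand")
})

test_that("minus-strand translation equals plus-strand of the reverse complement", {
  withr::with_seed(21, seqs <- replicate(25, random_nt(sample(30:120, 1))))
  for (s in seqs) {
    for (f in 0:2) {
      expect_equal(translate_frame(s, -1L, f),
                   translate_frame(reverse_complement(s), 1L, f))
    }
  }
})

test_that("translate_all_frames yields 3 sense / 6 both-strand translations", {
  contig <- tibble::tibble(id = "c", desc = "", seq = "ATGTTTCGATTT",
                           alphabet = "nucleotide")
  s3 <- translate_all_frames(contig, "sense3")
  expect_equal(nrow(s3), 3)
  expect_true(all(s3$strand == 1))
  expect_equal(nchar(s3$aa_seq), c(4, 3, 3))

  b6 <- translate_all_frames(contig, "both6")
  expect_equal(nrow(b6), 6)
  # six-frame completeness: both6 = sense3(x) + sense3(revcomp(x))
  rc <- contig
  rc$seq <- reverse_complement(rc$seq)
  rc3 <- translate_all_frames(rc, "sense3")
  expect_setequal(b6$aa_seq[b6$strand == -1], rc3$aa_seq)
  expect_setequal(b6$aa_seq[b6$strand == 1], s3$aa_seq)

  nn <- tibble::tibble(id = "n", desc = "", seq = "NNNNNN",
                       alphabet = "nucleotide")
  expect_true(all(grepl("^X+$", translate_all_frames(nn, "sense3")$aa_seq[1:2])))
})

test_that("extract_orfs keeps maximal stop-free runs above the length floor", {
  run25 <- strrep("GCT", 25)                      # 25 x Ala
  contig <- tibble::tibble(
    id = "c", desc = "",
    seq = paste0("TAA", run25, "TGA", "TT"), alphabet = "nucleotide"
  )
  orfs <- extract_orfs(contig, "sense3", min_aa = 21)
  in_frame <- orfs[orfs$frame == 0 & orfs$strand == 1, ]
  expect_equal(nrow(in_frame), 1)
  expect_equal(nchar(in_frame$aa_seq), 25)
  expect_true(in_frame$has_stop)
  expect_false(in_frame$has_start)
  expect_equal(in_frame$nt_start, 4L)
  expect_equal(in_frame$nt_end, 78L)

  higher <- extract_orfs(contig, "sense3", min_aa = 26)
  expect_equal(nrow(higher[higher$frame == 0, ]), 0)

  met <- tibble::tibble(id = "m", desc = "",
                        seq = paste0("TAA", "GCTGCT", "ATG", strrep("TTT", 24)),
                        alphabet = "nucleotide")
  trimmed <- extract_orfs(met, "sense3", min_aa = 21, require_met = TRUE)
  trimmed <- trimmed[trimmed$frame == 0, ]
  expect_true(all(startsWith(trimmed$aa_seq, "M")))
  expect_equal(nchar(trimmed$aa_seq[1]), 25)
})

test_that("every ORF re-translates from its coordinates to its stored sequence", {
  withr::with_seed(99, {
    contigs <- tibble::tibble(
      id = sprintf("c%03d", 1:60), desc = "",
      seq = replicate(60, random_nt(sample(90:600, 1))),
      alphabet = "nucleotide"
    )
  })
  orfs <- extract_orfs(contigs, "both6", min_aa = 10)
  expect_gt(nrow(orfs), 0)
  retranslated <- vapply(seq_len(nrow(orfs)), function(i) {
    o <- orfs[i, ]
    nt <- substr(contigs$seq[match(o$contig_id, contigs$id)],
                 o$nt_start, o$nt_end)
    if (o$strand == -1) nt <- reverse_complement(nt)
    translate_frame(nt)
  }, character(1))
  expect_equal(retranslated, orfs$aa_seq)
  expect_equal(3L * nchar(orfs$aa_seq), orfs$nt_end - orfs$nt_start + 1L)
  expect_false(any(grepl("*", orfs$aa_seq, fixed = TRUE)))
})

test_that("raising min_aa never adds ORFs, and sense3 is a subset of both6", {
  withr::with_seed(3, {
    contigs <- tibble::tibble(
      id = sprintf("c%02d", 1:15), desc = "",
      seq = replicate(15, random_nt(300)), alphabet = "nucleotide"
    )
  })
  key <- function(o) sprintf("%s:%d:%d:%d", o$contig_id, o$strand, o$frame,
                             o$nt_start)
  lo <- extract_orfs(contigs, "both6", min_aa = 5)
  hi <- extract_orfs(contigs, "both6", min_aa = 15)
  expect_true(all(key(hi) %in% key(lo)))
  s3 <- extract_orfs(contigs, "sense3", min_aa = 5)
  expect_true(all(key(s3) %in% key(lo)))
})
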