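# Shared fixtures and independent oracles used across the suite.

random_nt <- function(n, chars = c("A", "C", "G", "T")) {
  paste(sample(chars, n, replace = TRUE), collapse = "")
}

random_aa <- function(n, chars = strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]) {
  paste(sample(chars, n, replace = TRUE), collapse = "")
}

# Position-by-position pattern check, independent of the regex scanner.
naive_scan <- function(aa_seq, core = "RFG", basics = c("R", "K")) {
  res <- strsplit(aa_seq, "")[[1]]
  k <- nchar(core)
  core_res <- strsplit(core, "")[[1]]
  hits <- integer(0)
  for (i in seq_len(max(0, length(res) - k - 1))) {
    if (all(res[i:(i + k - 1)] == core_res) &&
        res[i + k] %in% basics && res[i + k + 1] %in% basics) {
      hits <- c(hits, i)
    }
  }
  hits
}

# Exhaustive maximum global alignment score by recursion over all gapped
# alignments: match/mismatch scoring, linear gap cost per gapped residue.
brute_force_align_score <- function(a, b, match = 1, mismatch = 0, gap = 1) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  memo <- new.env(hash = TRUE)
  rec <- function(i, j) {
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    val <- if (i > length(ca) && j > length(cb)) {
      0
    } else if (i > length(ca)) {
      -gap * (length(cb) - j + 1)
    } else if (j > length(cb)) {
      -gap * (length(ca) - i + 1)
    } else {
      max(
        (if (ca[i] == cb[j]) match else mismatch) + rec(i + 1, j + 1),
        rec(i + 1, j) - gap,
        rec(i, j + 1) - gap
      )
    }
    memo[[key]] <- val
    val
  }
  rec(1, 1)
}

# A precursor spec with randomised cassette content for property tests.
random_precursor_spec <- function(strand = 1L) {
  n_cas <- sample(1:4, 1)
  peps <- vapply(seq_len(n_cas), function(i) {
    # peptide bodies avoid basics at the flanks and internal dibasics
    mid <- random_aa(sample(2:8, 1),
                     chars = strsplit("ADEFHILMNPQSTVWY", "")[[1]])
    paste0(sample(c("F", "Q", "A"), 1), mid, sample(c("RF", "F", "L"), 1))
  }, character(1))
  amid <- sample(c(TRUE, FALSE), n_cas, replace = TRUE)
  # a non-amidated cassette must not end in G (generator enforces this)
  precursor_spec(
    data.frame(peptide = peps, copies = sample(1:4, n_cas, replace = TRUE),
               amidated = amid),
    signal_len = sample(15:25, 1),
    linker_len_range = sort(sample(0:3, 2)),
    cleavage_kind = sample(c("dibasic", "multibasic"), 1),
    strand = strand
  )
}

farp_a_spec <- function(strand = 1L) {
  precursor_spec(
    data.frame(peptide = "FMRF", copies = 4L, amidated = TRUE),
    signal_len = 18L, strand = strand
  )
}
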