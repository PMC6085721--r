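# Synthetic transcriptomes with planted precursor genes and full ground
# truth, so every stage of the screen is testable without external data.
#
# A planted precursor mirrors the architecture of gastropod prohormones:
# a signal peptide, then tandem peptide cassettes each followed by an
# optional amide-donor Gly and a basic convertase run, optionally spaced by
# short linker residues, embedded in UTR/noise sequence on either strand.

.HYDROPHOBIC <- c("L", "V", "F", "I", "A")
.LINKER_ALPHABET <- c("A", "S", "T", "N", "Q", "D", "E", "P", "H", "I", "L",
                      "V", "Y", "W", "M")

#' Specify a synthetic precursor
#'
#' @param cassettes Data frame with columns `peptide`, `copies`, `amidated`:
#'   each peptide is emitted `copies` times in tandem, each copy followed by
#'   a donor Gly (when amidated) and a convertase run. Peptides may not begin
#'   or end with a basic residue, may not contain adjacent basics, and a
#'   non-amidated peptide may not end in Gly — all of which would blur the
#'   planted cleavage architecture.
#' @param signal_len Signal-peptide length, 15-30 residues.
#' @param linker_len_range Length range of the random spacer emitted after
#'   each convertase run. The default `c(0, 0)` plants back-to-back cassettes
#'   (the architecture of tandem-repeat prohormones); a non-zero spacer ends
#'   up fused to the N-terminus of the following product, exactly as a real
#'   annotation would report it.
#' @param cleavage_kind `"dibasic"` (run of 2), `"multibasic"` (run of 3) or
#'   `"monobasic"` (single basic; the upstream cassette must then provide a
#'   basic residue 2, 4 or 6 positions before the site for it to be
#'   recognised under `dibasic_and_monobasic` rules).
#' @param utr5_len,utr3_len Untranslated flank lengths in nt.
#' @param strand `+1` or `-1`: strand on which the precursor is planted.
#' @return A list of class `precursor_spec`.
#' @examples
#' precursor_spec(data.frame(peptide = "FMRF", copies = 4, amidated = TRUE))
#' @export
precursor_spec <- function(cassettes, signal_len = 18L,
                           linker_len_range = c(0L, 0L),
                           cleavage_kind = "dibasic",
                           utr5_len = 60L, utr3_len = 60L, strand = 1L) {
  cassettes <- tibble::as_tibble(cassettes)
  stopifnot(nrow(cassettes) > 0,
            all(c("peptide", "copies", "amidated") %in% names(cassettes)),
            signal_len >= 15, signal_len <= 30,
            length(linker_len_range) == 2, linker_len_range[1] >= 0,
            diff(linker_len_range) >= 0,
            cleavage_kind %in% c("dibasic", "monobasic", "multibasic"),
            strand %in% c(1L, -1L), utr5_len >= 0, utr3_len >= 0)
  validate_alphabet(cassettes$peptide, "protein")
  bad <- grepl("\\*|X", cassettes$peptide) |
    grepl("^[RK]|[RK]$", cassettes$peptide) |
    grepl("[RK][RK]", cassettes$peptide) |
    (!cassettes$amidated & grepl("G$", cassettes$peptide))
  if (any(bad)) {
    stop("cassette peptide '", cassettes$peptide[which(bad)[1]],
         "' would blur the planted cleavage architecture", call. = FALSE)
  }
  structure(
    list(cassettes = cassettes, signal_len = as.integer(signal_len),
         linker_len_range = as.integer(linker_len_range),
         cleavage_kind = cleavage_kind, utr5_len = as.integer(utr5_len),
         utr3_len = as.integer(utr3_len), strand = as.integer(strand)),
    class = "precursor_spec"
  )
}

# canonical convertase runs: Lys-Arg dibasic, Lys-Arg-Arg multibasic,
# single Arg monobasic
.sample_site <- function(kind) {
  switch(kind, dibasic = "KR", monobasic = "R", multibasic = "KRR")
}

.build_signal <- function(signal_len) {
  core <- sample(.HYDROPHOBIC, signal_len - 5L, replace = TRUE)
  paste(c("M", "K", core, "S", "V", "A"), collapse = "")
}

#' Build one synthetic precursor protein with ground truth
#'
#' Deterministic given `rng_seed`. The returned truth lists the peptide
#' products exactly as the default annotation rules would report them
#' (linker residues fused to the following product, terminal tails
#' un-amidated); site positions are validated against
#' [find_cleavage_sites()] on the finished protein, so a spec whose residues
#' would create spurious or merged sites is rejected rather than silently
#' planted.
#'
#' @param spec A [precursor_spec()].
#' @param rng_seed Integer seed.
#' @param min_peptide_aa Counted-peptide threshold used for the truth table
#'   (default 3, matching the annotator default).
#' @return A list with elements `protein` and `truth`; `truth` carries
#'   `signal_len`, `sites`, `peptides`, `n_peptides`, `n_rfamides`.
#' @export
build_precursor <- function(spec, rng_seed, min_peptide_aa = 3L) {
  stopifnot(inherits(spec, "precursor_spec"))
  withr::with_seed(rng_seed, {
    parts <- character(0)
    site_rows <- list()
    pep_rows <- list()
    pos <- spec$signal_len
    parts <- .build_signal(spec$signal_len)
    pending_prefix <- ""  # linker carried into the next product

    emit <- function(n) if (n == 0) "" else
      paste(sample(.LINKER_ALPHABET, n, replace = TRUE), collapse = "")

    copies <- spec$cassettes[rep(seq_len(nrow(spec$cassettes)),
                                 spec$cassettes$copies), , drop = FALSE]
    for (i in seq_len(nrow(copies))) {
      pep <- copies$peptide[i]
      amid <- copies$amidated[i]
      body <- paste0(pending_prefix, pep)
      start <- pos + 1L
      end <- pos + nchar(body)
      pep_rows[[length(pep_rows) + 1L]] <- tibble::tibble(
        seq = body, start = start, end = end, amidated = amid
      )
      parts <- c(parts, body, if (amid) "G" else NULL)
      pos <- end + (amid * 1L)
      site <- .sample_site(spec$cleavage_kind)
      site_rows[[length(site_rows) + 1L]] <- tibble::tibble(
        start = pos + 1L, end = pos + nchar(site),
        kind = spec$cleavage_kind
      )
      parts <- c(parts, site)
      pos <- pos + nchar(site)
      link_n <- sample(seq.int(spec$linker_len_range[1],
                               spec$linker_len_range[2]), 1)
      pending_prefix <- emit(link_n)
    }
    # whatever spacer remains becomes the C-terminal tail
    if (nzchar(pending_prefix)) {
      pep_rows[[length(pep_rows) + 1L]] <- tibble::tibble(
        seq = pending_prefix, start = pos + 1L,
        end = pos + nchar(pending_prefix), amidated = FALSE
      )
      parts <- c(parts, pending_prefix)
      pos <- pos + nchar(pending_prefix)
    }
    protein <- paste(parts, collapse = "")
    peptides <- dplyr::bind_rows(pep_rows)
    peptides$is_linker <- nchar(peptides$seq) < min_peptide_aa
    peptides$classification <- ifelse(
      peptides$is_linker, "non_amide",
      classify_peptide(peptides$seq, peptides$amidated)
    )
    peptides$amidated[peptides$is_linker] <- FALSE
    peptides$copy_group <- NA_integer_
    real <- !peptides$is_linker
    peptides$copy_group[real] <- match(peptides$seq[real],
                                       unique(peptides$seq[real]))
    sites <- dplyr::bind_rows(site_rows)

    rules <- if (spec$cleavage_kind == "monobasic") {
      "dibasic_and_monobasic"
    } else {
      "dibasic_only"
    }
    found <- find_cleavage_sites(protein, rules)
    found <- found[found$start > spec$signal_len, , drop = FALSE]
    if (nrow(found) != nrow(sites) ||
        !all(found$start == sites$start & found$end == sites$end)) {
      stop("spec residues create spurious or merged cleavage sites; ",
           "adjust cassette peptides", call. = FALSE)
    }
    list(
      protein = protein,
      truth = list(
        protein = protein, signal_len = spec$signal_len, sites = sites,
        peptides = peptides,
        n_peptides = sum(!peptides$is_linker),
        n_rfamides = sum(real & peptides$classification == "RFamide")
      )
    )
  })
}

#' Reverse-translate a protein with uniform synonymous codon usage
#'
#' Each residue's codon is drawn uniformly from its synonymous codons under
#' the standard genetic code, so the nucleotide output is codon-usage
#' agnostic; [translate_frame()] of the output recovers the input exactly.
#'
#' @param protein Protein string without stops or X.
#' @param rng_seed Integer seed (deterministic output).
#' @return Nucleotide string of length `3 * nchar(protein)`.
#' @export
encode_to_nucleotide <- function(protein, rng_seed) {
  validate_alphabet(protein, "protein")
  if (grepl("[*X]", protein)) {
    stop("protein must not contain stops or X", call. = FALSE)
  }
  code <- Biostrings::GENETIC_CODE
  by_aa <- split(names(code), unname(code))
  res <- strsplit(protein, "")[[1]]
  withr::with_seed(rng_seed, {
    codons <- vapply(res, function(a) {
      opts <- by_aa[[a]]
      opts[sample.int(length(opts), 1)]
    }, character(1), USE.NAMES = FALSE)
  })
  paste(codons, collapse = "")
}

.random_nt <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

#' Generate a synthetic transcriptome with planted precursors
#'
#' Planted contigs are built as 5'UTR + coding sequence + stop + 3'UTR, with
#' an in-frame stop codon placed immediately before the start so the planted
#' ORF is exactly the precursor protein; minus-strand plants are
#' reverse-complemented whole. The remaining contigs are i.i.d. random
#' nucleotide noise. Fully deterministic given `rng_seed`.
#'
#' @param n_contigs Total number of contigs.
#' @param n_planted Number of planted precursors (specs are recycled).
#' @param specs A [precursor_spec()] or list of them.
#' @param noise_len_range Length range (nt) of noise contigs.
#' @param rng_seed Integer seed.
#' @param gc GC fraction of noise and UTR sequence (default 0.5, i.e.
#'   uniform ACGT).
#' @return A list with elements `contigs` (sequence tibble) and `truth`
#'   (list with per-contig tibble `contigs` and per-peptide tibble
#'   `peptides`).
#' @export
generate_transcriptome <- function(n_contigs, n_planted, specs,
                                   noise_len_range = c(300L, 900L),
                                   rng_seed = 1L, gc = 0.5) {
  stopifnot(n_planted <= n_contigs, n_planted >= 0)
  if (inherits(specs, "precursor_spec")) specs <- list(specs)
  if (n_planted > 0) {
    specs <- rep_len(specs, n_planted)
  }
  ids <- sprintf("contig_%04d", seq_len(n_contigs))
  withr::with_seed(rng_seed, {
    planted_at <- if (n_planted > 0) sort(sample.int(n_contigs, n_planted)) else integer(0)
    sub_seeds <- sample.int(.Machine$integer.max - 1L, n_contigs)
  })
  seqs <- character(n_contigs)
  contig_rows <- vector("list", n_contigs)
  pep_rows <- list()
  k <- 0L
  for (i in seq_len(n_contigs)) {
    if (i %in% planted_at) {
      k <- k + 1L
      spec <- specs[[k]]
      built <- build_precursor(spec, sub_seeds[i])
      cds <- encode_to_nucleotide(built$protein, sub_seeds[i] %% 1000003L + 1L)
      withr::with_seed(sub_seeds[i] %% 2000003L + 1L, {
        utr5 <- paste0(.random_nt(spec$utr5_len, gc), "TAA")
        utr3 <- .random_nt(spec$utr3_len, gc)
        stop_codon <- sample(c("TAA", "TAG", "TGA"), 1)
      })
      fwd <- paste0(utr5, cds, stop_codon, utr3)
      seqs[i] <- if (spec$strand == -1L) reverse_complement(fwd) else fwd
      cds_start <- nchar(utr5) + 1L
      contig_rows[[i]] <- tibble::tibble(
        contig_id = ids[i], planted = TRUE, strand = spec$strand,
        protein = built$protein, signal_len = spec$signal_len,
        cds_start = cds_start, cds_end = cds_start + nchar(cds) - 1L,
        n_peptides = built$truth$n_peptides,
        n_rfamides = built$truth$n_rfamides
      )
      pep <- built$truth$peptides
      pep$contig_id <- ids[i]
      pep_rows[[length(pep_rows) + 1L]] <- pep
    } else {
      withr::with_seed(sub_seeds[i], {
        len <- sample(seq.int(noise_len_range[1], noise_len_range[2]), 1)
        seqs[i] <- .random_nt(len, gc)
      })
      contig_rows[[i]] <- tibble::tibble(
        contig_id = ids[i], planted = FALSE, strand = NA_integer_,
        protein = NA_character_, signal_len = NA_integer_,
        cds_start = NA_integer_, cds_end = NA_integer_,
        n_peptides = NA_integer_, n_rfamides = NA_integer_
      )
    }
  }
  contigs <- tibble::tibble(id = ids, desc = "", seq = seqs,
                            alphabet = "nucleotide")
  truth <- list(contigs = dplyr::bind_rows(contig_rows),
                peptides = dplyr::bind_rows(pep_rows))
  list(contigs = contigs, truth = truth)
}

#' External signal calls from ground truth
#'
#' Builds the per-contig external signal-call table that reproduces the
#' planted signal cleavage points, for annotating recovered candidates with
#' truth-matched signal boundaries.
#'
#' @param truth Ground truth from [generate_transcriptome()].
#' @return Named list of [signal_call()] objects keyed by contig id.
#' @export
truth_external_signals <- function(truth) {
  planted <- truth$contigs[truth$contigs$planted, , drop = FALSE]
  calls <- lapply(planted$signal_len, function(s) {
    signal_call(TRUE, s, 1, "external")
  })
  stats::setNames(calls, planted$contig_id)
}

#' Score a screen run against ground truth
#'
#' A planted precursor counts as recovered when some annotation on its contig
#' contains the planted protein. Recall is recovered/planted (1 by convention
#' when nothing was planted); precision is the fraction of annotations that
#' sit on planted contigs (NA when there are no annotations). Peptide-level
#' agreement is scored on recovered precursors only: `count_agreement` is the
#' fraction whose counted-peptide number matches truth, `peptide_agreement`
#' the fraction whose full (sequence, amidation, classification) product list
#' matches truth exactly, in order.
#'
#' @param truth Ground truth from [generate_transcriptome()].
#' @param annotations List of `precursor_annotation` objects from the same
#'   run.
#' @return One-row tibble: `n_planted`, `n_candidates`, `n_recovered`,
#'   `recall`, `precision`, `count_agreement`, `peptide_agreement`.
#' @export
recovery_report <- function(truth, annotations) {
  planted <- truth$contigs[truth$contigs$planted, , drop = FALSE]
  ann_contig <- vapply(annotations, function(a) a$contig_id %||% NA_character_,
                       character(1))
  recovered <- vapply(seq_len(nrow(planted)), function(i) {
    idx <- which(ann_contig == planted$contig_id[i])
    any(vapply(idx, function(j) {
      grepl(planted$protein[i], annotations[[j]]$aa_seq, fixed = TRUE)
    }, logical(1)))
  }, logical(1))
  n_planted <- nrow(planted)
  n_cand <- length(annotations)
  recall <- if (n_planted == 0) 1 else mean(recovered)
  precision <- if (n_cand == 0) NA_real_ else
    mean(ann_contig %in% planted$contig_id)

  agree <- function(i) {
    idx <- which(ann_contig == planted$contig_id[i])[1]
    ann <- annotations[[idx]]
    tp <- truth$peptides[truth$peptides$contig_id == planted$contig_id[i] &
                           !truth$peptides$is_linker, , drop = FALSE]
    ap <- ann$peptides[!ann$peptides$is_linker, , drop = FALSE]
    c(count = nrow(tp) == nrow(ap),
      full = nrow(tp) == nrow(ap) &&
        identical(tp$seq, ap$seq) &&
        identical(tp$amidated, ap$amidated) &&
        identical(tp$classification, ap$classification))
  }
  rec_idx <- which(recovered)
  if (length(rec_idx) > 0) {
    am <- vapply(rec_idx, agree, logical(2))
    count_agreement <- mean(am["count", ])
    peptide_agreement <- mean(am["full", ])
  } else {
    count_agreement <- NA_real_
    peptide_agreement <- NA_real_
  }
  tibble::tibble(
    n_planted = n_planted, n_candidates = n_cand,
    n_recovered = sum(recovered), recall = recall, precision = precision,
    count_agreement = count_agreement, peptide_agreement = peptide_agreement
  )
}

#' Expected chance rate of the signature motif
#'
#' Probability that a random codon-aligned position in a translation of
#' i.i.d. nucleotide sequence begins a signature match, computed from the
#' per-base composition through standard-code codon probabilities. Used to
#' calibrate the false-positive behaviour of the screen on pure noise.
#'
#' @param base_freq Named numeric vector of A/C/G/T frequencies (sums to 1).
#' @param motif A [rf_motif()].
#' @return Probability per amino-acid position.
#' @export
expected_signature_rate <- function(base_freq = c(A = 0.25, C = 0.25,
                                                  G = 0.25, T = 0.25),
                                    motif = rf_motif()) {
  stopifnot(abs(sum(base_freq) - 1) < 1e-8)
  code <- Biostrings::GENETIC_CODE
  codon_p <- vapply(names(code), function(cd) {
    prod(base_freq[strsplit(cd, "")[[1]]])
  }, numeric(1))
  aa_p <- vapply(unique(unname(code)), function(a) {
    sum(codon_p[code == a])
  }, numeric(1))
  names(aa_p) <- unique(unname(code))
  core <- strsplit(motif$core, "")[[1]]
  prod(aa_p[core]) * sum(aa_p[motif$basic1]) * sum(aa_p[motif$basic2])
}
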