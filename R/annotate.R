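# Prohormone annotation: signal peptide, convertase cleavage sites,
# Gly-dependent C-terminal amidation, peptide enumeration, family
# classification and tandem-copy counting.

# Kyte-Doolittle hydropathy scale.
.KD <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
         G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
         P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2, X = 0,
         "*" = -4)

#' Construct a signal-peptide call
#'
#' @param present Logical flag.
#' @param cleavage_after 1-based index of the last signal residue (0 when
#'   absent); must not exceed 60.
#' @param score Confidence in `[0, 1]`.
#' @param source `"heuristic"` or `"external"`.
#' @return A one-row tibble of class `signal_call`.
#' @export
signal_call <- function(present, cleavage_after = 0L, score = 0,
                        source = "heuristic") {
  if (present && (cleavage_after < 1 || cleavage_after > 60)) {
    stop("a present signal must cleave within the first 60 residues",
         call. = FALSE)
  }
  stopifnot(score >= 0, score <= 1, source %in% c("heuristic", "external"))
  out <- tibble::tibble(
    present = present,
    cleavage_after = if (present) as.integer(cleavage_after) else 0L,
    score = as.numeric(score), source = source
  )
  class(out) <- c("signal_call", class(out))
  out
}

#' Predict an N-terminal secretory signal peptide
#'
#' The built-in heuristic follows the classical tripartite signal-peptide
#' architecture: a short n-region carrying at least one basic residue within
#' the first 6 positions, a hydrophobic h-region (some 7-residue window in the
#' first 45 residues with mean Kyte-Doolittle hydropathy >= 1.6), and a
#' cleavage context with small neutral residues (A/G/S/C) at the -1 and -3
#' positions. Among valid cleavage points the one closest to 4 residues past
#' the hydrophobic core is chosen (ties to the earlier position), mirroring
#' the typical spacing in secretory precursors. The heuristic is a
#' transparent, rule-based caller; `mode = "external"` lets a call from any
#' dedicated predictor be attached instead, and takes that call verbatim.
#'
#' @param aa_seq Protein string (>= 15 residues for heuristic mode).
#' @param mode `"heuristic"` or `"external"`.
#' @param external_call A [signal_call()] to pass through in external mode.
#' @return A [signal_call()].
#' @examples
#' predict_signal("MKTFLVLLLVLAVFSEAFMRFGKRFMRFGKRY")
#' @export
predict_signal <- function(aa_seq, mode = c("heuristic", "external"),
                           external_call = NULL) {
  mode <- match.arg(mode)
  if (mode == "external") {
    if (is.null(external_call)) {
      stop("external mode requires an external_call", call. = FALSE)
    }
    out <- external_call
    out$source <- "external"
    return(out)
  }
  n <- nchar(aa_seq)
  if (n < 15) stop("heuristic signal prediction needs >= 15 residues", call. = FALSE)
  head_len <- min(45L, n)
  res <- strsplit(substr(aa_seq, 1L, head_len), "")[[1]]
  kd <- unname(.KD[res])

  n_ok <- any(res[seq_len(min(6L, head_len))] %in% c("R", "K"))

  # best 7-residue hydrophobic window (earliest on ties)
  if (head_len >= 7) {
    win_means <- vapply(seq_len(head_len - 6L), function(i) mean(kd[i:(i + 6L)]),
                        numeric(1))
    best <- which.max(win_means)
    h_mean <- win_means[best]
    h_end <- best + 6L
  } else {
    h_mean <- -Inf
    h_end <- NA_integer_
  }
  h_ok <- is.finite(h_mean) && h_mean >= 1.6

  small <- c("A", "G", "S", "C")
  valid_c <- integer(0)
  if (h_ok) {
    cand <- seq.int(h_end + 1L, min(head_len, n - 1L))
    cand <- cand[cand >= 3L]
    valid_c <- cand[res[cand] %in% small & res[cand - 2L] %in% small]
  }
  ctx_ok <- length(valid_c) > 0

  score <- 0.25 * n_ok + 0.25 * ctx_ok +
    0.5 * max(0, min(if (is.finite(h_mean)) h_mean else 0, 4.5)) / 4.5
  if (n_ok && h_ok && ctx_ok) {
    target <- h_end + 4L
    cleave <- valid_c[order(abs(valid_c - target), valid_c)][1]
    signal_call(TRUE, cleave, score, "heuristic")
  } else {
    signal_call(FALSE, 0L, score, "heuristic")
  }
}

#' Find convertase cleavage sites
#'
#' Maximal runs of basic residues (R/K) of length >= 2 are sites: length 2 is
#' dibasic, length >= 3 multibasic (a KRR-type run is one site, not two
#' overlapping ones). Under `"dibasic_and_monobasic"`, an isolated single R or
#' K is additionally a site when another basic residue lies 2, 4 or 6
#' positions upstream — the spacing convention under which monobasic
#' processing is considered likely. Sites are non-overlapping and ascending.
#'
#' @param aa_seq Protein string.
#' @param rules `"dibasic_only"` (default) or `"dibasic_and_monobasic"`.
#' @return Tibble with columns `start`, `end`, `kind`.
#' @examples
#' find_cleavage_sites("FMRFGKRFLRFGRK")
#' @export
find_cleavage_sites <- function(aa_seq,
                                rules = c("dibasic_only", "dibasic_and_monobasic")) {
  rules <- match.arg(rules)
  m <- gregexpr("[RK]+", aa_seq)[[1]]
  empty <- tibble::tibble(start = integer(), end = integer(), kind = character())
  if (m[1] == -1) return(empty)
  start <- as.integer(m)
  len <- attr(m, "match.length")
  runs <- tibble::tibble(start = start, end = start + len - 1L, len = len)
  multi <- runs[runs$len >= 2L, , drop = FALSE]
  multi$kind <- character(nrow(multi))
  multi$kind[multi$len == 2L] <- "dibasic"
  multi$kind[multi$len >= 3L] <- "multibasic"
  sites <- multi
  if (rules == "dibasic_and_monobasic") {
    res <- strsplit(aa_seq, "")[[1]]
    mono <- runs[runs$len == 1L, , drop = FALSE]
    if (nrow(mono) > 0) {
      ok <- vapply(mono$start, function(p) {
        up <- p - c(2L, 4L, 6L)
        any(up >= 1L & res[pmax(up, 1L)] %in% c("R", "K"))
      }, logical(1))
      mono <- mono[ok, , drop = FALSE]
      if (nrow(mono) > 0) {
        mono$kind <- "monobasic"
        sites <- dplyr::bind_rows(sites, mono)
      }
    }
  }
  sites <- dplyr::arrange(sites[, c("start", "end", "kind")], .data$start)
  sites
}

#' Classify a predicted peptide
#'
#' A peptide is an RFamide iff it is amidated and its mature C-terminus is
#' ...Arg-Phe. Amidated peptides matching the Phe-X-Arg-Ile pattern (F at -4,
#' R at -2, I at -1) belong to the FxRIamide family and are labelled
#' `excluded_FxRIamide` rather than silently dropped, so the exclusion is
#' auditable. Other amidated peptides are `other_amide`; everything else is
#' `non_amide`.
#'
#' @param seq Peptide sequence(s), without the donor Gly. Vectorised.
#' @param amidated Logical flag(s), recycled against `seq`.
#' @return Character vector of classifications.
#' @examples
#' classify_peptide("GSLFRF", TRUE)
#' @export
classify_peptide <- function(seq, amidated) {
  stopifnot(all(nzchar(seq)))
  n <- max(length(seq), length(amidated))
  seq <- rep_len(seq, n)
  amidated <- rep_len(amidated, n)
  len <- nchar(seq)
  rf <- len >= 2 & substr(seq, len - 1L, len) == "RF"
  fxri <- len >= 4 &
    substr(seq, len - 3L, len - 3L) == "F" &
    substr(seq, len - 1L, len - 1L) == "R" &
    substr(seq, len, len) == "I"
  dplyr::case_when(
    amidated & rf ~ "RFamide",
    amidated & fxri ~ "excluded_FxRIamide",
    amidated ~ "other_amide",
    TRUE ~ "non_amide"
  )
}

#' Enumerate the peptide products of a precursor
#'
#' The mature region (everything after the signal cleavage point, or the whole
#' protein when no signal is called) is split at each cleavage site. A segment
#' whose final residue is Gly and which abuts a downstream cleavage site loses
#' that Gly to amidation (`amidated = TRUE`); a terminal Gly at the precursor
#' C-terminus has no convertase context and is retained un-amidated. Segments
#' shorter than `min_peptide_aa` are kept as linker fragments (`is_linker =
#' TRUE`) so that the precursor reconstructs exactly from its parts, but they
#' are not counted as peptides. `copy_group` numbers identical peptide
#' sequences by first appearance.
#'
#' @param aa_seq Precursor protein string.
#' @param sites Cleavage-site tibble from [find_cleavage_sites()] on the same
#'   sequence; sites inside the signal region are ignored.
#' @param signal A [signal_call()]; defaults to no signal.
#' @param min_peptide_aa Minimum counted peptide length (default 3).
#' @return Peptide tibble with columns `seq`, `start`, `end`, `amidated`,
#'   `classification`, `is_linker`, `copy_group`.
#' @export
enumerate_peptides <- function(aa_seq, sites, signal = signal_call(FALSE),
                               min_peptide_aa = 3L) {
  n <- nchar(aa_seq)
  if (nrow(sites) > 0) {
    if (any(sites$start < 1 | sites$end > n | sites$start > sites$end)) {
      stop("cleavage site out of bounds", call. = FALSE)
    }
    o <- order(sites$start)
    sites <- sites[o, , drop = FALSE]
    if (nrow(sites) > 1 && any(sites$start[-1] <= sites$end[-nrow(sites)])) {
      stop("overlapping cleavage sites", call. = FALSE)
    }
  }
  m_start <- if (signal$present) signal$cleavage_after + 1L else 1L
  sites <- sites[sites$start >= m_start, , drop = FALSE]

  seg_start <- c(m_start, sites$end + 1L)
  seg_end <- c(sites$start - 1L, n)
  abuts_site <- c(rep(TRUE, nrow(sites)), FALSE)
  keep <- seg_end >= seg_start
  seg_start <- seg_start[keep]
  seg_end <- seg_end[keep]
  abuts_site <- abuts_site[keep]

  empty <- tibble::tibble(
    seq = character(), start = integer(), end = integer(),
    amidated = logical(), classification = character(),
    is_linker = logical(), copy_group = integer()
  )
  if (length(seg_start) == 0) return(empty)

  rows <- purrr::pmap(list(seg_start, seg_end, abuts_site), function(s, e, ab) {
    seg <- substr(aa_seq, s, e)
    amid <- ab && substr(seg, nchar(seg), nchar(seg)) == "G"
    body <- if (amid) substr(seg, 1L, nchar(seg) - 1L) else seg
    body_end <- if (amid) e - 1L else e
    if (nchar(body) < min_peptide_aa) {
      # too short to count: keep the raw segment for reconstruction
      tibble::tibble(seq = seg, start = s, end = e, amidated = FALSE,
                     classification = "non_amide", is_linker = TRUE)
    } else {
      tibble::tibble(seq = body, start = s, end = body_end, amidated = amid,
                     classification = classify_peptide(body, amid),
                     is_linker = FALSE)
    }
  })
  pep <- dplyr::bind_rows(rows)
  pep$copy_group <- NA_integer_
  real <- !pep$is_linker
  pep$copy_group[real] <- match(pep$seq[real], unique(pep$seq[real]))
  pep
}

#' Tabulate tandem copies of identical peptides
#'
#' Gastropod prohormones often encode the same peptide in many tandem copies;
#' this tabulates exact-sequence copy counts for the non-linker peptides of
#' one precursor, most-repeated first.
#'
#' @param peptides Peptide tibble from [enumerate_peptides()].
#' @return Tibble with columns `seq`, `copies`, `classification`, sorted by
#'   descending `copies` then `seq`.
#' @export
count_copies <- function(peptides) {
  real <- peptides[!peptides$is_linker, , drop = FALSE]
  if (nrow(real) == 0) {
    return(tibble::tibble(seq = character(), copies = integer(),
                          classification = character()))
  }
  out <- dplyr::summarise(
    dplyr::group_by(real, .data$seq, .data$classification),
    copies = dplyr::n(), .groups = "drop"
  )
  out <- dplyr::arrange(out, dplyr::desc(.data$copies), .data$seq)
  out[, c("seq", "copies", "classification")]
}

#' Annotate a candidate precursor
#'
#' Composes the full prohormone annotation: signal-peptide call, cleavage
#' sites, peptide enumeration with amidation and classification, and copy
#' counting. The annotation always reconstructs the precursor exactly:
#' signal + peptides + donor Gly residues + cleavage-site residues + linker
#' fragments, in coordinate order, equal the input protein.
#'
#' @param candidate Either a protein string or a one-row candidate tibble
#'   from [screen_candidates()] (its `aa_seq` is annotated and the ORF
#'   metadata carried along).
#' @param config A [pipeline_config()]; the annotation options used are
#'   `cleavage_rules`, `min_peptide_aa`, `signal_mode`.
#' @param external_signal Optional [signal_call()] used when
#'   `config$signal_mode == "external"`.
#' @return An object of class `precursor_annotation`: a list with elements
#'   `contig_id`, `strand`, `frame`, `aa_seq`, `signal`, `sites`, `peptides`,
#'   `copy_table`, `n_peptides`, `n_rfamides`.
#' @examples
#' ann <- annotate_precursor("MKTFLVLLLVLAVFSEAFMRFGKRFMRFGKRYPE")
#' ann$n_rfamides
#' @export
annotate_precursor <- function(candidate, config = pipeline_config(),
                               external_signal = NULL) {
  if (is.character(candidate)) {
    meta <- list(contig_id = NA_character_, strand = NA_integer_,
                 frame = NA_integer_, aa_seq = candidate,
                 n_signatures = NA_integer_)
  } else {
    stopifnot(nrow(candidate) == 1)
    meta <- list(contig_id = candidate$contig_id, strand = candidate$strand,
                 frame = candidate$frame, aa_seq = candidate$aa_seq,
                 n_signatures = candidate$n_signatures %||% NA_integer_)
  }
  aa_seq <- meta$aa_seq
  signal <- if (config$signal_mode == "external") {
    predict_signal(aa_seq, "external", external_call = external_signal)
  } else {
    predict_signal(aa_seq)
  }
  sites <- find_cleavage_sites(aa_seq, config$cleavage_rules)
  peptides <- enumerate_peptides(aa_seq, sites, signal, config$min_peptide_aa)
  structure(
    list(
      contig_id = meta$contig_id, strand = meta$strand, frame = meta$frame,
      n_signatures = meta$n_signatures, aa_seq = aa_seq,
      signal = signal, sites = sites, peptides = peptides,
      copy_table = count_copies(peptides),
      n_peptides = sum(!peptides$is_linker),
      n_rfamides = sum(peptides$classification == "RFamide" & !peptides$is_linker)
    ),
    class = "precursor_annotation"
  )
}

#' Reassemble a precursor from its annotation parts
#'
#' Concatenates, in coordinate order, the signal region, each peptide (with
#' its donor Gly when amidated), every cleavage-site run and every linker
#' fragment. Equality with the original protein is the structural invariant
#' of the annotation.
#'
#' @param ann A `precursor_annotation`.
#' @return The reassembled protein string.
#' @export
reconstruct_precursor <- function(ann) {
  pieces <- tibble::tibble(start = integer(), text = character())
  if (ann$signal$present) {
    pieces <- dplyr::bind_rows(pieces, tibble::tibble(
      start = 1L, text = substr(ann$aa_seq, 1L, ann$signal$cleavage_after)
    ))
  }
  if (nrow(ann$peptides) > 0) {
    pep_text <- ifelse(ann$peptides$amidated, paste0(ann$peptides$seq, "G"),
                       ann$peptides$seq)
    pieces <- dplyr::bind_rows(pieces, tibble::tibble(
      start = ann$peptides$start, text = pep_text
    ))
  }
  m_start <- if (ann$signal$present) ann$signal$cleavage_after + 1L else 1L
  mature_sites <- ann$sites[ann$sites$start >= m_start, , drop = FALSE]
  if (nrow(mature_sites) > 0) {
    pieces <- dplyr::bind_rows(pieces, tibble::tibble(
      start = mature_sites$start,
      text = substr(rep(ann$aa_seq, nrow(mature_sites)),
                    mature_sites$start, mature_sites$end)
    ))
  }
  paste(pieces$text[order(pieces$start)], collapse = "")
}

#' @export
print.precursor_annotation <- function(x, ...) {
  cat(sprintf(
    "<precursor_annotation> %s (%d aa)\n  signal: %s  sites: %d  peptides: %d (%d RFamide)\n",
    ifelse(is.na(x$contig_id), "<unnamed>", x$contig_id), nchar(x$aa_seq),
    ifelse(x$signal$present, sprintf("1-%d", x$signal$cleavage_after), "none"),
    nrow(x$sites), x$n_peptides, x$n_rfamides
  ))
  invisible(x)
}

#' Tidy a precursor annotation into its peptide table
#'
#' @param x A `precursor_annotation`.
#' @param ... Unused.
#' @return The peptide tibble with the contig id attached.
#' @importFrom generics tidy
#' @method tidy precursor_annotation
#' @export
tidy.precursor_annotation <- function(x, ...) {
  dplyr::mutate(x$peptides, contig_id = x$contig_id, .before = 1)
}

#' One-row summary of a precursor annotation
#'
#' @param x A `precursor_annotation`.
#' @param ... Unused.
#' @return A one-row tibble: contig metadata, ORF length, signature count,
#'   signal call, peptide and RFamide counts.
#' @importFrom generics glance
#' @method glance precursor_annotation
#' @export
glance.precursor_annotation <- function(x, ...) {
  tibble::tibble(
    contig_id = x$contig_id, strand = x$strand, frame = x$frame,
    orf_len_aa = nchar(x$aa_seq), n_signatures = x$n_signatures,
    signal_present = x$signal$present,
    signal_cleavage_after = x$signal$cleavage_after,
    n_peptides = x$n_peptides, n_rfamides = x$n_rfamides
  )
}
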