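# The discovery filter: scan frame translations for the convertase signature
# of an encoded, amidated RFamide and keep candidate precursors.

#' Define an amidated-peptide signature motif
#'
#' The genomic fingerprint of an encoded amidated RFamide is the mature
#' C-terminus, the Gly amide donor, and the downstream convertase site:
#' Arg-Phe-Gly followed by two basic residues, i.e. `RFG(R/K)(R/K)`. The motif
#' is data, not code, so related signatures (other amidated families) can be
#' scanned by swapping the core; the default core `RFG` deliberately does not
#' match FxRIamide-type cassettes, which belong to a different family.
#'
#' @param core Residues that must immediately precede the basic pair
#'   (default `"RFG"`: the RF terminus plus the amide-donor Gly).
#' @param basic1,basic2 Allowed residues at the two convertase positions;
#'   must be drawn from R and K.
#' @return An object of class `signature_motif`.
#' @examples
#' rf_motif()
#' @export
rf_motif <- function(core = "RFG", basic1 = c("R", "K"), basic2 = c("R", "K")) {
  stopifnot(nzchar(core))
  if (!all(c(basic1, basic2) %in% c("R", "K"))) {
    stop("basic positions must be drawn from R and K", call. = FALSE)
  }
  structure(
    list(core = toupper(core), basic1 = unique(basic1), basic2 = unique(basic2)),
    class = "signature_motif"
  )
}

#' @export
print.signature_motif <- function(x, ...) {
  cat(sprintf("<signature_motif> %s[%s][%s]\n", x$core,
              paste(x$basic1, collapse = ""), paste(x$basic2, collapse = "")))
  invisible(x)
}

.motif_regex <- function(motif) {
  sprintf("(?=%s[%s][%s])",
          motif$core,
          paste(motif$basic1, collapse = ""),
          paste(motif$basic2, collapse = ""))
}

#' Scan a protein sequence for the signature motif
#'
#' Returns all (possibly overlapping) 1-based start positions of the motif,
#' in ascending order. X never matches: an ambiguous codon is never taken as
#' evidence of a signature.
#'
#' @param aa_seq Protein string.
#' @param motif A [rf_motif()].
#' @return Integer vector of match start positions.
#' @examples
#' scan_signature("AAAARFGKRAAAA")
#' @export
scan_signature <- function(aa_seq, motif = rf_motif()) {
  m <- gregexpr(.motif_regex(motif), aa_seq, perl = TRUE)[[1]]
  if (m[1] == -1) integer(0) else as.integer(m)
}

#' Screen ORFs for candidate precursors
#'
#' Keeps every ORF that carries at least one signature and has meaningful
#' length (more than 20 residues under the default `min_aa = 21`).
#'
#' @param orfs ORF tibble from [extract_orfs()].
#' @param motif A [rf_motif()].
#' @param min_aa Minimum ORF length in residues (default 21).
#' @return Candidate tibble: the ORF columns plus `motif_positions`
#'   (list-column of integer vectors) and `n_signatures`, sorted by
#'   descending `n_signatures`, then contig id, strand, frame and start.
#' @export
screen_candidates <- function(orfs, motif = rf_motif(), min_aa = 21L) {
  hits <- orfs[nchar(orfs$aa_seq) >= min_aa, , drop = FALSE]
  pos <- lapply(hits$aa_seq, scan_signature, motif = motif)
  hits$motif_positions <- pos
  hits$n_signatures <- lengths(pos)
  hits <- hits[hits$n_signatures >= 1L, , drop = FALSE]
  dplyr::arrange(tibble::as_tibble(hits), dplyr::desc(.data$n_signatures),
                 .data$contig_id, dplyr::desc(.data$strand), .data$frame,
                 .data$nt_start)
}

#' Drop candidates contained in longer candidates
#'
#' De-novo assemblies carry redundant isoform contigs; a candidate whose
#' protein is a substring of a longer retained candidate's protein adds
#' nothing and is dropped. Ties (identical proteins) keep the
#' lexicographically lower contig id.
#'
#' @param hits Candidate tibble from [screen_candidates()].
#' @return Filtered candidate tibble, original ordering of retained rows.
#' @export
deduplicate_candidates <- function(hits) {
  if (nrow(hits) <= 1) return(hits)
  ord <- order(-nchar(hits$aa_seq), hits$contig_id)
  keep_seqs <- character(0)
  keep_idx <- logical(nrow(hits))
  for (i in ord) {
    s <- hits$aa_seq[i]
    contained <- any(vapply(keep_seqs, function(k) {
      grepl(s, k, fixed = TRUE)
    }, logical(1)))
    if (!contained) {
      keep_seqs <- c(keep_seqs, s)
      keep_idx[i] <- TRUE
    }
  }
  hits[keep_idx, , drop = FALSE]
}
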