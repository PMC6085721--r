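# Conceptual translation and ORF extraction.
#
# The screen translates each contig in three sense frames by default, matching
# how transcriptome mining for secreted peptides is usually run on oriented
# assemblies; the both-strand six-frame mode exists because antisense contigs
# do occur in de-novo assemblies and a sense-only scan can miss them.

#' Translate one reading frame of a nucleotide sequence
#'
#' Standard genetic code. Stop codons are rendered as `*`; any codon
#' containing N is rendered as X (no attempt to resolve ambiguity). A trailing
#' 1-2 nt remainder is ignored.
#'
#' @param seq Nucleotide string.
#' @param strand `+1` (given strand) or `-1` (reverse complement).
#' @param frame Offset 0, 1 or 2 on the reading strand.
#' @return Protein string (possibly empty).
#' @examples
#' translate_frame("ATGTTTCGATTT")
#' translate_frame("CGCTTCGGAAAACGA")  # encodes the RFamide signature RFGKR
#' @export
translate_frame <- function(seq, strand = 1L, frame = 0L) {
  if (!strand %in% c(1L, -1L)) stop("strand must be +1 or -1", call. = FALSE)
  if (!frame %in% 0:2) stop("frame must be 0, 1 or 2", call. = FALSE)
  validate_alphabet(seq, "nucleotide")
  if (strand == -1L) seq <- reverse_complement(seq)
  n_codon <- (nchar(seq) - frame) %/% 3L
  if (n_codon <= 0) return("")
  sub <- substr(seq, frame + 1L, frame + 3L * n_codon)
  aa <- Biostrings::translate(Biostrings::DNAString(sub),
                              if.fuzzy.codon = "X", no.init.codon = TRUE)
  as.character(aa)
}

#' Translate a set of contigs in all frames
#'
#' @param contigs Sequence tibble (nucleotide), as from [read_fasta()].
#' @param mode `"sense3"` (three frames on the given strand, the default) or
#'   `"both6"` (six frames). The sense3 output is always a subset of both6.
#' @return Tibble with columns `contig_id`, `strand`, `frame`, `aa_seq`.
#' @export
translate_all_frames <- function(contigs, mode = c("sense3", "both6")) {
  mode <- match.arg(mode)
  strands <- if (mode == "both6") c(1L, -1L) else 1L
  grid <- tidyr::expand_grid(
    contig_id = contigs$id, strand = strands, frame = 0:2
  )
  grid$aa_seq <- purrr::pmap_chr(grid, function(contig_id, strand, frame) {
    translate_frame(contigs$seq[match(contig_id, contigs$id)], strand, frame)
  })
  grid
}

# Map an aa run [aa_from, aa_to] (1-based on a frame translation) back to
# 1-based inclusive forward-strand nucleotide coordinates.
.orf_nt_coords <- function(aa_from, aa_to, frame, strand, contig_len) {
  r_start <- frame + 3L * (aa_from - 1L) + 1L  # on the reading strand
  r_end <- frame + 3L * aa_to
  if (strand == 1L) c(r_start, r_end)
  else c(contig_len - r_end + 1L, contig_len - r_start + 1L)
}

#' Extract open reading frames from contigs
#'
#' ORFs are maximal stop-free runs within each frame translation, optionally
#' trimmed to the first Met. Partial contigs are the norm in assemblies, so an
#' initiator Met is not required by default. Coordinates always refer to the
#' forward strand of the contig, 1-based inclusive.
#'
#' @inheritParams translate_all_frames
#' @param min_aa Minimum ORF length in residues; the screen's default of 21
#'   keeps only polypeptides longer than 20 amino acids.
#' @param require_met If `TRUE`, trim each run to its first Met and drop runs
#'   without one.
#' @return Tibble with columns `contig_id`, `strand`, `frame`, `aa_seq`,
#'   `nt_start`, `nt_end`, `has_start`, `has_stop`, sorted by
#'   (contig, strand, frame, nt_start). `has_stop` marks runs bounded on the
#'   right by a genuine stop codon rather than the contig end.
#' @export
extract_orfs <- function(contigs, mode = c("sense3", "both6"), min_aa = 21L,
                         require_met = FALSE) {
  mode <- match.arg(mode)
  stopifnot(min_aa >= 1)
  frames <- translate_all_frames(contigs, mode)
  len <- nchar(contigs$seq)[match(frames$contig_id, contigs$id)]

  rows <- purrr::pmap(
    list(frames$contig_id, frames$strand, frames$frame, frames$aa_seq, len),
    function(contig_id, strand, frame, aa_seq, contig_len) {
      if (!nzchar(aa_seq)) return(NULL)
      m <- gregexpr("[^*]+", aa_seq)[[1]]
      if (m[1] == -1) return(NULL)
      run_start <- as.integer(m)
      run_len <- attr(m, "match.length")
      run_end <- run_start + run_len - 1L
      followed_by_stop <- run_end < nchar(aa_seq)
      out <- purrr::pmap(
        list(run_start, run_end, followed_by_stop),
        function(s, e, stopped) {
          aa <- substr(aa_seq, s, e)
          if (require_met) {
            met <- regexpr("M", aa, fixed = TRUE)
            if (met == -1) return(NULL)
            s <- s + as.integer(met) - 1L
            aa <- substr(aa_seq, s, e)
          }
          if (nchar(aa) < min_aa) return(NULL)
          nt <- .orf_nt_coords(s, e, frame, strand, contig_len)
          tibble::tibble(
            contig_id = contig_id, strand = strand, frame = frame,
            aa_seq = aa, nt_start = nt[1], nt_end = nt[2],
            has_start = startsWith(aa, "M"), has_stop = stopped
          )
        }
      )
      dplyr::bind_rows(out)
    }
  )
  orfs <- dplyr::bind_rows(rows)
  if (nrow(orfs) == 0) {
    return(tibble::tibble(
      contig_id = character(), strand = integer(), frame = integer(),
      aa_seq = character(), nt_start = integer(), nt_end = integer(),
      has_start = logical(), has_stop = logical()
    ))
  }
  dplyr::arrange(orfs, .data$contig_id, dplyr::desc(.data$strand),
                 .data$frame, .data$nt_start)
}
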