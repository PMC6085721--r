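# FASTA I/O and nucleotide utilities shared by all pipeline stages.
#
# Sequence tables ("seq_tbl") are plain tibbles with columns id, desc, seq,
# alphabet; one row per record. Ids are the first whitespace-delimited token
# of the FASTA header (Trinity-style), the description is the verbatim
# remainder.

.NT_CHARS <- "ACGTN"
.AA_CHARS <- "ACDEFGHIKLMNPQRSTVWYX*"

.alphabet_regex <- function(alphabet) {
  switch(alphabet,
    nucleotide = sprintf("[^%s]", .NT_CHARS),
    protein    = sprintf("[^%s]", gsub("\\*", "\\\\*", .AA_CHARS)),
    stop("unknown alphabet: ", alphabet, call. = FALSE)
  )
}

#' Validate residues against an alphabet
#'
#' Nucleotide sequences may contain only A, C, G, T and N; protein sequences
#' the 20 standard one-letter codes plus X (unknown) and `*` (stop). IUPAC
#' ambiguity codes other than N are rejected: the screen's motif logic is
#' exact-residue, so silently recoding ambiguity would hide information loss.
#'
#' @param seq Character vector of sequences (uppercase).
#' @param alphabet `"nucleotide"` or `"protein"`.
#' @param id Optional identifiers used in error messages.
#' @return Invisibly, `seq`.
#' @keywords internal
validate_alphabet <- function(seq, alphabet, id = NULL) {
  bad <- stringr::str_extract(seq, .alphabet_regex(alphabet))
  hit <- which(!is.na(bad))
  if (length(hit) > 0) {
    who <- if (is.null(id)) paste0("sequence ", hit[1]) else id[hit[1]]
    stop(sprintf("record '%s' contains character '%s' not in the %s alphabet",
                 who, bad[hit[1]], alphabet), call. = FALSE)
  }
  invisible(seq)
}

#' Read a FASTA file into a sequence tibble
#'
#' Sequences are uppercased; whitespace and gap characters (`-`) inside
#' sequence lines are stripped; CRLF and LF line endings are both accepted.
#' Record order is preserved.
#'
#' @param path Path to a plain-text FASTA file.
#' @param alphabet `"nucleotide"` or `"protein"`; every record is validated
#'   against it.
#' @return A tibble with columns `id`, `desc`, `seq`, `alphabet`.
#' @examples
#' tf <- tempfile(fileext = ".fasta")
#' writeLines(c(">contig1 demo", "ACGTACGT"), tf)
#' read_fasta(tf, "nucleotide")
#' @export
read_fasta <- function(path, alphabet = c("nucleotide", "protein")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("empty FASTA file: ", path, call. = FALSE)
  hdr <- startsWith(lines, ">")
  if (!hdr[1]) stop("not FASTA: first line is not a header in ", path, call. = FALSE)
  grp <- cumsum(hdr)
  headers <- sub("^>", "", lines[hdr])
  id <- stringr::str_extract(headers, "^\\S+")
  desc <- trimws(stringr::str_remove(headers, "^\\S+\\s*"))
  seq <- vapply(split(lines[!hdr], grp[!hdr]), paste0, character(1), collapse = "")
  seq_full <- rep("", length(id))
  seq_full[as.integer(names(seq))] <- seq
  seq_full <- toupper(gsub("[-\\s]", "", seq_full, perl = TRUE))
  if (any(!nzchar(seq_full))) {
    stop("record '", id[which(!nzchar(seq_full))[1]], "' has an empty sequence",
         call. = FALSE)
  }
  if (anyDuplicated(id)) {
    stop("duplicate FASTA id: '", id[duplicated(id)][1], "'", call. = FALSE)
  }
  validate_alphabet(seq_full, alphabet, id)
  tibble::tibble(id = id, desc = desc, seq = seq_full, alphabet = alphabet)
}

#' Write a sequence tibble to FASTA
#'
#' Round-trip safe: `read_fasta()` on the written file reproduces ids,
#' descriptions and sequences exactly.
#'
#' @param records Tibble with columns `id`, `desc`, `seq` (as from
#'   [read_fasta()]; `desc` may be absent).
#' @param path Output path.
#' @param width Residues per sequence line (default 60).
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(records, path, width = 60L) {
  stopifnot(nrow(records) > 0, width >= 1)
  desc <- if ("desc" %in% names(records)) records$desc else rep("", nrow(records))
  header <- ifelse(nzchar(desc), paste0(">", records$id, " ", desc),
                   paste0(">", records$id))
  body <- vapply(records$seq, function(s) {
    n <- nchar(s)
    starts <- seq.int(1L, n, by = width)
    paste(substring(s, starts, pmin(starts + width - 1L, n)), collapse = "\n")
  }, character(1), USE.NAMES = FALSE)
  con <- file(path, open = "wb")  # LF endings on every platform
  on.exit(close(con))
  writeLines(as.vector(rbind(header, body)), con, sep = "\n")
  invisible(path)
}

#' Reverse complement of nucleotide sequences
#'
#' Standard Watson-Crick complement, reversed; N maps to N. Vectorised over
#' `seq`. Applying it twice returns the input.
#'
#' @param seq Character vector of nucleotide sequences (A/C/G/T/N only).
#' @return Character vector of reverse complements.
#' @examples
#' reverse_complement("ATGC")
#' @export
reverse_complement <- function(seq) {
  if (length(seq) == 0) return(character(0))
  out <- character(length(seq))
  empty <- !nzchar(seq)
  out[empty] <- ""
  if (any(!empty)) {
    validate_alphabet(seq[!empty], "nucleotide")
    out[!empty] <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAStringSet(seq[!empty]))
    )
  }
  out
}
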