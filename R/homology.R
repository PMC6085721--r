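# Precursor-level homology: optimal global pairwise protein alignment and
# percent identity, used to name candidates by their best reference match.

#' Alignment parameters
#'
#' Default scoring is BLOSUM62 with affine gaps (open 10, extend 0.5), the
#' customary setting for global protein alignment; identity is always counted
#' as exact residue matches regardless of the scoring scheme. A simple
#' match/mismatch scheme can be requested instead by giving `match` and
#' `mismatch`, in which case gap costs are typically linear
#' (`gap_open = 0`, `gap_extend` = per-residue cost).
#'
#' @param substitution Name of a substitution matrix (`"BLOSUM62"`) or `NULL`
#'   when using `match`/`mismatch`.
#' @param match,mismatch Scores used when `substitution` is `NULL`.
#' @param gap_open,gap_extend Affine gap penalties (positive costs).
#' @return A list of class `align_params`.
#' @export
align_params <- function(substitution = "BLOSUM62", match = 1, mismatch = 0,
                         gap_open = 10, gap_extend = 0.5) {
  structure(list(substitution = substitution, match = match,
                 mismatch = mismatch, gap_open = gap_open,
                 gap_extend = gap_extend),
            class = "align_params")
}

.substitution_matrix <- function(params) {
  if (!is.null(params$substitution)) {
    name <- params$substitution
    env <- new.env()
    utils::data(list = name, package = "Biostrings", envir = env)
    get(name, envir = env)
  } else {
    letters <- c(Biostrings::AA_STANDARD, "X", "*")
    m <- matrix(params$mismatch, length(letters), length(letters),
                dimnames = list(letters, letters))
    diag(m) <- params$match
    m
  }
}

#' Optimal global pairwise protein alignment
#'
#' End-to-end (Needleman-Wunsch) alignment under affine gap scoring, via
#' [Biostrings::pairwiseAlignment()]. Identity is the fraction of alignment
#' columns (including gap columns) in which the two residues are identical.
#'
#' @param a,b Protein strings (non-empty).
#' @param params An [align_params()].
#' @return A list of class `alignment_result` with elements `aligned_a`,
#'   `aligned_b`, `score`, `matches`, `columns`, `identity_pct`.
#' @examples
#' global_align("MFRF", "MRRF")$identity_pct
#' @export
global_align <- function(a, b, params = align_params()) {
  if (!nzchar(a) || !nzchar(b)) stop("empty sequence", call. = FALSE)
  pa <- Biostrings::pairwiseAlignment(
    a, b, type = "global",
    substitutionMatrix = .substitution_matrix(params),
    gapOpening = params$gap_open, gapExtension = params$gap_extend
  )
  aligned_a <- as.character(Biostrings::alignedPattern(pa))
  aligned_b <- as.character(Biostrings::alignedSubject(pa))
  ca <- strsplit(aligned_a, "")[[1]]
  cb <- strsplit(aligned_b, "")[[1]]
  matches <- sum(ca == cb & ca != "-")
  columns <- length(ca)
  structure(
    list(aligned_a = aligned_a, aligned_b = aligned_b,
         score = as.numeric(Biostrings::score(pa)),
         matches = matches, columns = columns,
         identity_pct = 100 * matches / columns),
    class = "alignment_result"
  )
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf("<alignment_result> %d columns, %d matches, %.1f%% identity, score %.1f\n",
              x$columns, x$matches, x$identity_pct, x$score))
  cat(" ", x$aligned_a, "\n ", x$aligned_b, "\n")
  invisible(x)
}

#' Percent identity between two proteins
#'
#' Identity of the optimal global alignment, under a choice of denominator:
#' all alignment columns (default), the shorter input, or the longer input.
#' Symmetric in its two arguments.
#'
#' @inheritParams global_align
#' @param denominator `"columns"`, `"shorter"` or `"longer"`.
#' @return Percent identity in `[0, 100]`.
#' @examples
#' percent_identity("MFRF", "MFRF")
#' @export
percent_identity <- function(a, b, params = align_params(),
                             denominator = c("columns", "shorter", "longer")) {
  denominator <- match.arg(denominator)
  al <- global_align(a, b, params)
  denom <- switch(denominator,
    columns = al$columns,
    shorter = min(nchar(a), nchar(b)),
    longer = max(nchar(a), nchar(b))
  )
  100 * al$matches / denom
}

#' Best reference match for a query precursor
#'
#' Scores the query against every reference by global percent identity and
#' returns the best, ties broken by reference id. There is no threshold: the
#' argmax is always returned, and low identities simply indicate a novel
#' precursor.
#'
#' @param query Protein string.
#' @param references Protein sequence tibble (as from
#'   `read_fasta(..., "protein")`).
#' @param params An [align_params()].
#' @param denominator Passed to [percent_identity()].
#' @return A one-row tibble with columns `reference_id`, `identity_pct`.
#' @export
best_reference_match <- function(query, references, params = align_params(),
                                 denominator = "columns") {
  if (nrow(references) == 0) stop("empty reference set", call. = FALSE)
  ident <- vapply(references$seq, function(r) {
    percent_identity(query, r, params, denominator)
  }, numeric(1), USE.NAMES = FALSE)
  ord <- order(-ident, references$id)
  tibble::tibble(reference_id = references$id[ord[1]],
                 identity_pct = ident[ord[1]])
}
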