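# Plots: precursor architecture diagrams in the style of the classical
# prohormone figures (signal in yellow, cleavage sites in red, donor Gly in
# green, RFamides in blue).

.ANN_FILL <- c(signal = "#f2d43d", RFamide = "#4f81bd",
               other_amide = "#8fbc8f", non_amide = "grey75",
               excluded_FxRIamide = "#c49bd6", linker = "grey90",
               `donor Gly` = "#4cae4c", `cleavage site` = "#d9534f")

#' Plot a precursor annotation as an architecture diagram
#'
#' Draws the precursor as a residue-scaled bar: signal region, peptide
#' products coloured by family classification, amide-donor Gly residues and
#' basic cleavage-site runs.
#'
#' @param object A `precursor_annotation`.
#' @param ... Unused.
#' @return A ggplot object.
#' @importFrom ggplot2 autoplot
#' @method autoplot precursor_annotation
#' @export
autoplot.precursor_annotation <- function(object, ...) {
  seg <- list()
  if (object$signal$present) {
    seg$signal <- tibble::tibble(start = 1L, end = object$signal$cleavage_after,
                                 role = "signal")
  }
  if (nrow(object$peptides) > 0) {
    p <- object$peptides
    seg$pep <- tibble::tibble(
      start = p$start, end = p$end,
      role = ifelse(p$is_linker, "linker", p$classification)
    )
    amid <- p[p$amidated, , drop = FALSE]
    if (nrow(amid) > 0) {
      seg$gly <- tibble::tibble(start = amid$end + 1L, end = amid$end + 1L,
                                role = "donor Gly")
    }
  }
  if (nrow(object$sites) > 0) {
    seg$sites <- tibble::tibble(start = object$sites$start,
                                end = object$sites$end, role = "cleavage site")
  }
  df <- dplyr::bind_rows(seg)
  ggplot2::ggplot(df) +
    ggplot2::geom_rect(ggplot2::aes(
      xmin = .data$start - 0.5, xmax = .data$end + 0.5,
      ymin = 0, ymax = 1, fill = .data$role
    ), colour = "grey30", linewidth = 0.2) +
    ggplot2::scale_fill_manual(values = .ANN_FILL, name = NULL) +
    ggplot2::scale_y_continuous(breaks = NULL) +
    ggplot2::labs(
      x = "residue",
      title = ifelse(is.na(object$contig_id), "precursor", object$contig_id),
      subtitle = sprintf("%d peptides, %d RFamide", object$n_peptides,
                         object$n_rfamides)
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.title.y = ggplot2::element_blank())
}

#' Plot tandem-copy counts across candidates
#'
#' Bar chart of exact-copy counts of each distinct peptide, coloured by
#' classification — the quickest view of tandem-repeat architecture across
#' a screen's output.
#'
#' @param peptides Peptide tibble from [run_pipeline()].
#' @param top Show at most this many distinct peptides (by copy count).
#' @return A ggplot object.
#' @export
plot_copy_counts <- function(peptides, top = 20L) {
  real <- peptides[!peptides$is_linker, , drop = FALSE]
  tab <- dplyr::count(real, .data$seq, .data$classification,
                      name = "copies", sort = TRUE)
  tab <- utils::head(tab, top)
  tab$seq <- factor(tab$seq, levels = rev(tab$seq))
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$copies, y = .data$seq,
                                    fill = .data$classification)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = .ANN_FILL, name = NULL) +
    ggplot2::labs(x = "tandem copies", y = NULL) +
    ggplot2::theme_minimal()
}
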