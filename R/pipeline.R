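# Pipeline orchestration and reporting: configuration, the end-to-end
# screen, and machine- and human-readable outputs.

ANNOTATION_SCHEMA_VERSION <- "1.0"

#' Pipeline configuration
#'
#' Every screening parameter as one document. Defaults reproduce the
#' canonical screen: sense-strand three-frame translation, the RFG(R/K)(R/K)
#' signature, a 21-residue minimum polypeptide length (strictly more than 20
#' amino acids), dibasic-only cleavage, a 3-residue counted-peptide
#' threshold, the heuristic signal caller, and BLOSUM62 global alignment
#' with all-columns identity.
#'
#' @param mode Frame mode, `"sense3"` or `"both6"`.
#' @param motif A [rf_motif()].
#' @param min_aa Minimum ORF length in residues.
#' @param require_met Require an initiator Met on ORFs.
#' @param cleavage_rules `"dibasic_only"` or `"dibasic_and_monobasic"`.
#' @param min_peptide_aa Minimum counted peptide length.
#' @param signal_mode `"heuristic"` or `"external"`.
#' @param align An [align_params()].
#' @param identity_denominator Passed to [percent_identity()].
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(mode = c("sense3", "both6"), motif = rf_motif(),
                            min_aa = 21L, require_met = FALSE,
                            cleavage_rules = c("dibasic_only",
                                               "dibasic_and_monobasic"),
                            min_peptide_aa = 3L,
                            signal_mode = c("heuristic", "external"),
                            align = align_params(),
                            identity_denominator = "columns") {
  mode <- match.arg(mode)
  cleavage_rules <- match.arg(cleavage_rules)
  signal_mode <- match.arg(signal_mode)
  stopifnot(min_aa >= 1, min_peptide_aa >= 1)
  structure(
    list(mode = mode, motif = motif, min_aa = as.integer(min_aa),
         require_met = require_met, cleavage_rules = cleavage_rules,
         min_peptide_aa = as.integer(min_peptide_aa),
         signal_mode = signal_mode, align = align,
         identity_denominator = identity_denominator),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' Recognised keys mirror the [pipeline_config()] arguments; the motif is
#' given as `motif: {core: RFG, basic1: [R, K], basic2: [R, K]}` and
#' alignment as `align: {substitution: BLOSUM62, gap_open: 10,
#' gap_extend: 0.5}`. Missing keys keep their defaults.
#'
#' @param path Path to a YAML file.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  for (k in c("mode", "min_aa", "require_met", "cleavage_rules",
              "min_peptide_aa", "signal_mode", "identity_denominator")) {
    if (!is.null(y[[k]])) args[[k]] <- y[[k]]
  }
  if (!is.null(y$motif)) {
    args$motif <- do.call(rf_motif, y$motif)
  }
  if (!is.null(y$align)) {
    args$align <- do.call(align_params, y$align)
  }
  do.call(pipeline_config, args)
}

.config_fingerprint <- function(config) {
  tf <- tempfile()
  on.exit(unlink(tf))
  dput(unclass(rapply(config, unclass, how = "replace")), file = tf)
  unname(tools::md5sum(tf))
}

#' Run the full precursor-mining pipeline
#'
#' read -> translate/ORF -> signature screen -> de-duplication -> prohormone
#' annotation -> optional homology naming. Deterministic for fixed inputs
#' and configuration.
#'
#' @param contigs Path to a nucleotide FASTA file, or a sequence tibble from
#'   [read_fasta()].
#' @param config A [pipeline_config()].
#' @param references Optional protein sequence tibble (or FASTA path) of
#'   reference precursors for homology naming.
#' @param external_signals Optional named list of [signal_call()] objects
#'   keyed by contig id, used when `config$signal_mode == "external"`.
#' @param out_dir Optional output directory; when given, the candidate TSV,
#'   annotation JSON, peptide FASTA and run manifest are written there
#'   (atomically: each file is staged and then renamed into place).
#' @param quiet Suppress progress messages (default TRUE).
#' @return A list of class `pipeline_result`: `candidates` (tibble),
#'   `annotations` (list of `precursor_annotation`), `peptides` (tibble),
#'   `manifest` (list).
#' @export
run_pipeline <- function(contigs, config = pipeline_config(),
                         references = NULL, external_signals = NULL,
                         out_dir = NULL, quiet = TRUE) {
  say <- function(...) if (!quiet) message("[rfamine] ", ...)
  input_md5 <- NA_character_
  if (is.character(contigs)) {
    input_md5 <- unname(tools::md5sum(contigs))
    say("reading ", contigs)
    contigs <- read_fasta(contigs, "nucleotide")
  }
  if (nrow(contigs) == 0) stop("no sequences", call. = FALSE)
  if (is.character(references)) references <- read_fasta(references, "protein")

  say("extracting ORFs (", config$mode, ", min ", config$min_aa, " aa)")
  orfs <- extract_orfs(contigs, config$mode, config$min_aa, config$require_met)
  say(nrow(orfs), " ORFs")
  cands <- screen_candidates(orfs, config$motif, config$min_aa)
  cands <- deduplicate_candidates(cands)
  say(nrow(cands), " candidates after de-duplication")

  annotations <- lapply(seq_len(nrow(cands)), function(i) {
    row <- cands[i, , drop = FALSE]
    ext <- if (config$signal_mode == "external") {
      external_signals[[row$contig_id]] %||%
        stop("no external signal call for contig ", row$contig_id,
             call. = FALSE)
    }
    annotate_precursor(row, config, external_signal = ext)
  })

  summary_tbl <- if (length(annotations) > 0) {
    dplyr::bind_rows(lapply(annotations, glance))
  } else {
    glance(annotate_precursor(strrep("A", 21)))[0, ]
  }
  if (!is.null(references) && length(annotations) > 0) {
    say("homology naming against ", nrow(references), " references")
    best <- dplyr::bind_rows(lapply(annotations, function(a) {
      best_reference_match(a$aa_seq, references, config$align,
                           config$identity_denominator)
    }))
    summary_tbl$best_reference <- best$reference_id
    summary_tbl$identity_pct <- best$identity_pct
  } else {
    summary_tbl$best_reference <- NA_character_
    summary_tbl$identity_pct <- NA_real_
  }

  peptides <- if (length(annotations) > 0) {
    dplyr::bind_rows(lapply(annotations, tidy))
  } else {
    tidy(annotate_precursor(strrep("A", 21)))[0, ]
  }

  manifest <- list(
    tool = "rfamine", version = as.character(utils::packageVersion("rfamine")),
    config = .serialize_config(config),
    config_md5 = .config_fingerprint(config),
    input_md5 = input_md5, n_contigs = nrow(contigs),
    n_orfs = nrow(orfs), n_candidates = nrow(cands),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  result <- structure(
    list(candidates = summary_tbl, annotations = annotations,
         peptides = peptides, manifest = manifest),
    class = "pipeline_result"
  )
  if (!is.null(out_dir)) write_pipeline_outputs(result, out_dir)
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> %d candidates, %d peptides (%d RFamide)\n",
              nrow(x$candidates), sum(!x$peptides$is_linker),
              sum(x$peptides$classification == "RFamide")))
  invisible(x)
}

.serialize_config <- function(config) {
  list(
    mode = config$mode,
    motif = list(core = config$motif$core, basic1 = config$motif$basic1,
                 basic2 = config$motif$basic2),
    min_aa = config$min_aa, require_met = config$require_met,
    cleavage_rules = config$cleavage_rules,
    min_peptide_aa = config$min_peptide_aa,
    signal_mode = config$signal_mode,
    align = unclass(config$align),
    identity_denominator = config$identity_denominator
  )
}

.atomic_write <- function(writer, path) {
  tmp <- paste0(path, ".tmp")
  writer(tmp)
  file.rename(tmp, path)
  invisible(path)
}

#' Write the candidate table as TSV
#'
#' One row per annotated candidate; 11 columns: `contig_id`, `strand`,
#' `frame`, `orf_len_aa`, `n_signatures`, `signal_present`,
#' `signal_cleavage_after`, `n_peptides`, `n_rfamides`, `best_reference`,
#' `identity_pct`. Tab-separated, header row, UTF-8, LF endings; missing
#' homology columns are rendered as NA. All coordinates in reports are
#' 1-based inclusive.
#'
#' @param candidates Candidate summary tibble from [run_pipeline()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
render_tsv <- function(candidates, path) {
  cols <- c("contig_id", "strand", "frame", "orf_len_aa", "n_signatures",
            "signal_present", "signal_cleavage_after", "n_peptides",
            "n_rfamides", "best_reference", "identity_pct")
  tbl <- candidates[, cols, drop = FALSE]
  .atomic_write(function(tmp) {
    con <- file(tmp, open = "wb", encoding = "UTF-8")
    on.exit(close(con))
    utils::write.table(tbl, con, sep = "\t", quote = FALSE, na = "NA",
                       row.names = FALSE, eol = "\n")
  }, path)
}

.annotation_to_list <- function(ann) {
  list(
    contig_id = ann$contig_id, strand = ann$strand, frame = ann$frame,
    n_signatures = ann$n_signatures, aa_seq = ann$aa_seq,
    signal = as.list(ann$signal),
    sites = lapply(seq_len(nrow(ann$sites)), function(i) as.list(ann$sites[i, ])),
    peptides = lapply(seq_len(nrow(ann$peptides)), function(i) {
      as.list(ann$peptides[i, ])
    })
  )
}

.annotation_from_list <- function(x) {
  na_fill <- function(row) {
    row[vapply(row, is.null, logical(1))] <- NA
    tibble::as_tibble(row)
  }
  sites <- if (length(x$sites) > 0) {
    dplyr::bind_rows(lapply(x$sites, na_fill))
  } else {
    tibble::tibble(start = integer(), end = integer(), kind = character())
  }
  sites$start <- as.integer(sites$start)
  sites$end <- as.integer(sites$end)
  peptides <- if (length(x$peptides) > 0) {
    dplyr::bind_rows(lapply(x$peptides, na_fill))
  } else {
    tibble::tibble(seq = character(), start = integer(), end = integer(),
                   amidated = logical(), classification = character(),
                   is_linker = logical(), copy_group = integer())
  }
  if (is.null(peptides$copy_group)) peptides$copy_group <- NA
  peptides <- peptides[, c("seq", "start", "end", "amidated",
                           "classification", "is_linker", "copy_group")]
  peptides$amidated <- as.logical(peptides$amidated)
  peptides$is_linker <- as.logical(peptides$is_linker)
  peptides$start <- as.integer(peptides$start)
  peptides$end <- as.integer(peptides$end)
  peptides$copy_group <- as.integer(peptides$copy_group)
  sig <- signal_call(x$signal$present, x$signal$cleavage_after,
                     x$signal$score, x$signal$source)
  structure(
    list(
      contig_id = x$contig_id %||% NA_character_,
      strand = if (is.null(x$strand)) NA_integer_ else as.integer(x$strand),
      frame = if (is.null(x$frame)) NA_integer_ else as.integer(x$frame),
      n_signatures = if (is.null(x$n_signatures)) NA_integer_ else
        as.integer(x$n_signatures),
      aa_seq = x$aa_seq, signal = sig, sites = sites, peptides = peptides,
      copy_table = count_copies(peptides),
      n_peptides = sum(!peptides$is_linker),
      n_rfamides = sum(peptides$classification == "RFamide" &
                         !peptides$is_linker)
    ),
    class = "precursor_annotation"
  )
}

#' Serialize annotations to JSON
#'
#' Schema-versioned full serialization of every annotation, including
#' peptide coordinates, amidation flags, classifications and copy groups;
#' key order is stable, so identical runs produce byte-identical files.
#' [read_annotations_json()] is its exact inverse.
#'
#' @param annotations List of `precursor_annotation` objects.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
render_json <- function(annotations, path) {
  doc <- list(
    schema_version = ANNOTATION_SCHEMA_VERSION,
    coordinates = "1-based inclusive",
    annotations = lapply(annotations, .annotation_to_list)
  )
  .atomic_write(function(tmp) {
    jsonlite::write_json(doc, tmp, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, na = "null")
  }, path)
}

#' Read annotations back from JSON
#'
#' @param path Path written by [render_json()].
#' @return List of `precursor_annotation` objects.
#' @export
read_annotations_json <- function(path) {
  doc <- jsonlite::read_json(path)
  lapply(doc$annotations, .annotation_from_list)
}

#' Write predicted peptides as FASTA
#'
#' Non-linker peptides only. Headers follow the fixed contract
#' `contig|start-end|amide:{0,1}|class`, with start/end 1-based inclusive on
#' the precursor protein.
#'
#' @param peptides Peptide tibble from [run_pipeline()] (column `contig_id`
#'   plus the [enumerate_peptides()] columns).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_peptides_fasta <- function(peptides, path) {
  real <- peptides[!peptides$is_linker, , drop = FALSE]
  recs <- tibble::tibble(
    id = sprintf("%s|%d-%d|amide:%d|%s", real$contig_id, real$start,
                 real$end, as.integer(real$amidated), real$classification),
    desc = "", seq = real$seq
  )
  .atomic_write(function(tmp) write_fasta(recs, tmp), path)
}

#' Write all pipeline outputs to a directory
#'
#' Writes `candidates.tsv`, `annotations.json`, `peptides.fasta` and
#' `manifest.json` (timestamps live only in the manifest, so the data files
#' of identical runs are byte-identical).
#'
#' @param result A `pipeline_result`.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, `out_dir`.
#' @export
write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  render_tsv(result$candidates, file.path(out_dir, "candidates.tsv"))
  render_json(result$annotations, file.path(out_dir, "annotations.json"))
  if (nrow(result$peptides) > 0) {
    write_peptides_fasta(result$peptides, file.path(out_dir, "peptides.fasta"))
  }
  .atomic_write(function(tmp) {
    jsonlite::write_json(result$manifest, tmp, auto_unbox = TRUE,
                         pretty = TRUE, na = "null")
  }, file.path(out_dir, "manifest.json"))
  invisible(out_dir)
}
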