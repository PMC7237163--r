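# End-to-end orchestration: ingest -> internal enrichment -> peak calling ->
# intersection -> annotation -> summary, with every tunable parameter carried
# in one params list that is echoed into the output directory.

#' Pipeline parameters with published defaults
#'
#' @param max_fragment_length IE fragment-length cap (nt).
#' @param alpha Per-replicate empirical p-value ceiling.
#' @param min_reads IE count floor.
#' @param match_dist IE replicate matching distance (nt).
#' @param window,step,z_min,min_stops,min_frac Peak-caller settings.
#' @param max_dist IE/PC intersection distance (nt).
#' @param min_sep Minimum spacing of reported TTS (nt).
#' @param dsm_max_insert,dsm_min_cov Baseline-caller settings.
#' @param geometry Library geometry for SAM ingest.
#' @param flank,motif_up,motif_down,upstream_length Profiling windows (nt).
#' @return A named list of parameters.
#' @export
pipeline_params <- function(max_fragment_length = 100, alpha = 0.05,
                            min_reads = 1, match_dist = 0,
                            window = 150, step = 100, z_min = 2,
                            min_stops = 5, min_frac = 0.10,
                            max_dist = 10, min_sep = 10,
                            dsm_max_insert = 500, dsm_min_cov = 4,
                            geometry = "reverse",
                            flank = 45, motif_up = 15, motif_down = 5,
                            upstream_length = 100) {
  as.list(environment())
}

#' Run the TTS-calling pipeline
#'
#' Input is either a fragment tibble (with a `replicate` column) or a vector
#' of per-replicate SAM/BAM paths. Stages: fragment-length filtering,
#' internal enrichment with replicate intersection, pooled-track peak
#' calling, IE/PC intersection and merging, annotation-based ranking,
#' classification and UTR measurement, and (if an annotation is given) the
#' baseline downstream-region caller for comparison.
#'
#' @param fragments Fragment tibble; mutually exclusive with `sam_paths`.
#' @param sam_paths Character vector of per-replicate SAM/BAM files.
#' @param replicons Replicon tibble.
#' @param genes Optional annotation tibble; enables ranking, classification,
#'   UTRs and the baseline caller.
#' @param tss Optional TSS tibble.
#' @param rnaseq_coverage Optional independent coverage `tts_tracks` for UTR
#'   continuity validation.
#' @param params [pipeline_params()] list.
#' @param out_dir Optional directory; when given, all stage outputs, the
#'   resolved configuration and the summary are written there.
#' @return A `tts_run` object (list with `tts`, `ie`, `pc`, `dsm`, `tracks`,
#'   `summary`, `params`, `counters`); `tidy()` returns the TTS table,
#'   `glance()` the one-row summary.
#' @export
run_pipeline <- function(fragments = NULL, sam_paths = NULL, replicons,
                         genes = NULL, tss = NULL, rnaseq_coverage = NULL,
                         params = pipeline_params(), out_dir = NULL) {
  if (is.null(fragments) == is.null(sam_paths)) {
    stop("supply exactly one of `fragments` or `sam_paths`", call. = FALSE)
  }
  counters <- list()
  if (!is.null(sam_paths)) {
    fragments <- purrr::map_dfr(seq_along(sam_paths), function(r) {
      fr <- read_fragments(sam_paths[r], geometry = params$geometry,
                           replicate = r)
      counters[[paste0("replicate", r)]] <<- attr(fr, "counters")
      fr
    })
  }
  fr_ie <- filter_fragments(fragments, max_len = params$max_fragment_length)
  counters$length_filtered <- attr(fr_ie, "n_removed")

  ie <- ie_sites(fr_ie, alpha = params$alpha, min_reads = params$min_reads,
                 match_dist = params$match_dist)
  tracks <- build_tracks(fr_ie, replicons)
  pc <- call_peaks(tracks, window = params$window, step = params$step,
                   z_min = params$z_min, min_stops = params$min_stops,
                   min_frac = params$min_frac)
  tts <- call_tts(ie, pc, tracks, genes = genes, tss = tss,
                  rnaseq_coverage = rnaseq_coverage,
                  max_dist = params$max_dist, min_sep = params$min_sep)
  dsm <- if (!is.null(genes)) {
    dsm_call(fragments, genes, max_insert = params$dsm_max_insert,
             min_cov = params$dsm_min_cov)
  }
  run <- structure(list(tts = tts, ie = ie, pc = pc, dsm = dsm,
                        tracks = tracks, params = params,
                        counters = counters,
                        summary = summarize_tts(tts)),
                   class = "tts_run")
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

#' @noRd
summarize_tts <- function(tts) {
  has_ann <- "location" %in% names(tts)
  tibble::tibble(
    total = nrow(tts),
    intergenic = if (has_ann) sum(tts$location == "intergenic") else NA_integer_,
    coding = if (has_ann) sum(tts$location == "coding") else NA_integer_,
    first = if (has_ann) sum(tts$rank == "first", na.rm = TRUE) else NA_integer_,
    secondary = if (has_ann) sum(tts$rank == "secondary", na.rm = TRUE) else NA_integer_,
    unassigned = if (has_ann) sum(is.na(tts$rank)) else NA_integer_,
    antisense = if (has_ann) sum(tts$antisense) else NA_integer_,
    median_utr_first = if (has_ann)
      median(tts$utr_length[!is.na(tts$rank) & tts$rank == "first"]) else NA_real_
  )
}

#' @export
print.tts_run <- function(x, ...) {
  cat("<tts_run>\n")
  print(x$summary)
  invisible(x)
}

#' @rdname run_pipeline
#' @param x A `tts_run`.
#' @param ... Unused.
#' @method tidy tts_run
#' @export
tidy.tts_run <- function(x, ...) x$tts

#' @rdname run_pipeline
#' @method glance tts_run
#' @export
glance.tts_run <- function(x, ...) x$summary

#' @noRd
write_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(run$params, file.path(out_dir, "config.yaml"))
  readr::write_tsv(run$tts, file.path(out_dir, "tts.tsv"), progress = FALSE)
  write_bed(run$tts, file.path(out_dir, "tts.bed"), score = "ie_combined_score")
  readr::write_tsv(run$ie, file.path(out_dir, "ie_sites.tsv"), progress = FALSE)
  if (nrow(run$ie)) write_bed(run$ie, file.path(out_dir, "ie_sites.bed"),
                              score = "combined_score")
  readr::write_tsv(run$pc, file.path(out_dir, "pc_peaks.tsv"), progress = FALSE)
  if (nrow(run$pc)) write_bed(run$pc, file.path(out_dir, "pc_peaks.bed"),
                              score = "zscore")
  if (!is.null(run$dsm)) {
    readr::write_tsv(run$dsm, file.path(out_dir, "dsm.tsv"), progress = FALSE)
  }
  readr::write_tsv(run$summary, file.path(out_dir, "summary.tsv"), progress = FALSE)
  write_bedgraph(run$tracks, file.path(out_dir, "tracks"))
  invisible(out_dir)
}

#' Histogram of first-TTS 3' UTR lengths
#'
#' @param tts Annotated TTS tibble.
#' @param binwidth Histogram bin width (nt).
#' @param max_len Truncate the x axis at this UTR length.
#' @return A ggplot object.
#' @export
plot_utr_histogram <- function(tts, binwidth = 20, max_len = 800) {
  df <- tts[!is.na(tts$rank) & tts$rank == "first" & !is.na(tts$utr_length), ]
  df <- df[df$utr_length <= max_len, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$utr_length)) +
    ggplot2::geom_histogram(binwidth = binwidth, boundary = 0,
                            fill = "steelblue", colour = "white") +
    ggplot2::labs(x = "3' UTR length (nt)", y = "number of first TTS") +
    ggplot2::theme_minimal()
}
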