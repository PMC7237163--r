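# Sequence context around termination sites: per-offset nucleotide
# frequencies (intrinsic terminators in archaea show a T stretch ending at
# the TTS in intergenic regions) and FASTA export of the windows consumed by
# external motif- and structure-discovery tools.

#' @noRd
revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# transcript-oriented window [off_lo, off_hi] (offsets relative to `position`,
# negative = upstream); returns NA when the window leaves the replicon
#' @noRd
extract_window <- function(seqs, lens, replicon, strand, position, off_lo, off_hi) {
  L <- lens[[replicon]]
  if (strand == "+") { lo <- position + off_lo; hi <- position + off_hi }
  else { lo <- position - off_hi; hi <- position - off_lo }
  if (lo < 0 || hi >= L) return(NA_character_)
  s <- substr(seqs[[replicon]], lo + 1L, hi + 1L)
  if (strand == "-") revcomp_chr(s) else s
}

#' Nucleotide frequency profile around TTS
#'
#' Extracts transcript-oriented windows of `2 * flank + 1` nt centred on each
#' TTS (offset 0 = the TTS base; negative offsets upstream) and tabulates
#' per-offset base frequencies. Windows truncated by replicon edges contribute
#' only their defined offsets; ambiguous bases (N) are excluded from the
#' denominator at their offset.
#'
#' @param tts TTS tibble (with `location` column when `subset` is not
#'   `"all"`).
#' @param replicons Replicon tibble including sequences.
#' @param flank Half-window size in nt.
#' @param subset Restrict to intergenic or coding TTS, or use all.
#' @return A `tts_profile` tibble: `offset`, `base`, `count`, `n_defined`,
#'   `freq`, with attribute `n_sites`. [ggplot2::autoplot()] draws the
#'   classic frequency-by-offset figure.
#' @export
nucleotide_profile <- function(tts, replicons, flank = 45,
                               subset = c("all", "intergenic", "coding")) {
  subset <- match.arg(subset)
  if (subset != "all") tts <- tts[tts$location == subset, ]
  if (nrow(tts) == 0) stop("no TTS in subset '", subset, "'", call. = FALSE)
  seqs <- setNames(replicons$sequence, replicons$id)
  lens <- setNames(replicons$length, replicons$id)
  offsets <- -flank:flank
  counts <- matrix(0L, nrow = length(offsets), ncol = 5,
                   dimnames = list(NULL, c("A", "C", "G", "T", "N")))
  for (k in seq_len(nrow(tts))) {
    L <- lens[[tts$replicon[k]]]
    p <- tts$position[k]
    d <- strand_dir(tts$strand[k])
    gpos <- p + d * offsets
    ok <- gpos >= 0 & gpos < L
    if (!any(ok)) next
    bases <- strsplit(seqs[[tts$replicon[k]]], "", fixed = TRUE)[[1]][gpos[ok] + 1L]
    if (tts$strand[k] == "-") bases <- chartr("ACGTN", "TGCAN", bases)
    ii <- cbind(which(ok), match(bases, colnames(counts)))
    for (r in seq_len(nrow(ii))) counts[ii[r, 1], ii[r, 2]] <-
      counts[ii[r, 1], ii[r, 2]] + 1L
  }
  n_def <- rowSums(counts[, c("A", "C", "G", "T"), drop = FALSE])
  out <- tidyr::pivot_longer(
    tibble::tibble(offset = offsets,
                   A = counts[, "A"], C = counts[, "C"],
                   G = counts[, "G"], T = counts[, "T"],
                   n_defined = n_def),
    cols = c("A", "C", "G", "T"), names_to = "base", values_to = "count"
  )
  out$freq <- ifelse(out$n_defined > 0, out$count / out$n_defined, NA_real_)
  out <- out[, c("offset", "base", "count", "n_defined", "freq")]
  class(out) <- c("tts_profile", class(out))
  attr(out, "n_sites") <- nrow(tts)
  out
}

#' @rdname nucleotide_profile
#' @param object A `tts_profile`.
#' @param ... Unused.
#' @method autoplot tts_profile
#' @export
autoplot.tts_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$offset, y = .data$freq,
                                       colour = .data$base)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed", colour = "grey40") +
    ggplot2::labs(x = "offset from TTS (nt, transcript orientation)",
                  y = "base frequency", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @noRd
export_windows <- function(tts, replicons, off_lo, off_hi, path) {
  seqs <- setNames(replicons$sequence, replicons$id)
  lens <- setNames(replicons$length, replicons$id)
  rec <- purrr::map_chr(seq_len(nrow(tts)), function(k) {
    extract_window(seqs, lens, tts$replicon[k], tts$strand[k],
                   tts$position[k], off_lo, off_hi)
  })
  skipped <- is.na(rec)
  if (any(skipped)) {
    warning(sum(skipped), " window(s) skipped at replicon edges", call. = FALSE)
  }
  out <- tibble::tibble(
    name = sprintf("%s:%d:%s", tts$replicon, tts$position, tts$strand),
    sequence = rec
  )[!skipped, ]
  if (!is.null(path)) {
    Biostrings::writeXStringSet(
      Biostrings::DNAStringSet(setNames(out$sequence, out$name)), path)
  }
  out
}

#' Export TTS-centred windows for motif discovery
#'
#' One transcript-oriented record per TTS covering `up` nt upstream through
#' `down` nt downstream of (and including) the TTS base, i.e. `up + 1 + down`
#' nt. TTS whose window would leave the replicon are skipped with a warning.
#'
#' @inheritParams nucleotide_profile
#' @param up,down Window extent upstream/downstream of the TTS (nt).
#' @param path Optional FASTA output path.
#' @return Tibble of `name`, `sequence` records (also written to `path` if
#'   given).
#' @export
export_motif_windows <- function(tts, replicons, up = 15, down = 5, path = NULL) {
  export_windows(tts, replicons, -up, down, path)
}

#' Export upstream windows for structure analysis
#'
#' One transcript-oriented record per TTS covering the `length` nt ending at
#' (and including) the TTS base — the input expected by secondary-structure
#' clustering of terminator candidates.
#'
#' @inheritParams export_motif_windows
#' @param length Window length in nt.
#' @export
export_upstream_windows <- function(tts, replicons, length = 100, path = NULL) {
  export_windows(tts, replicons, -(length - 1L), 0L, path)
}
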