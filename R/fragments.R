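# Fragment reconstruction from mate-pair alignments.
#
# A "fragment" is one sequenced cDNA insert oriented in transcript space: its
# 3' edge (`end3`) is the natural RNA 3' end preserved by 3'-adapter ligation,
# its 5' edge (`start5`) is a random first-strand-cDNA break point. Many
# fragments sharing `end3` but scattered in `start5` are the signature of a
# real RNA 3' terminus; this table is the substrate for both the internal
# enrichment score and the peak caller.

#' Reconstruct transcript-oriented fragments from paired-end alignments
#'
#' Reads a coordinate-sorted SAM or BAM file of mate pairs and reconstructs one
#' fragment per concordant pair, spanning the outermost mate coordinates.
#' Which fragment edge is the natural RNA 3' end, and on which strand the
#' transcript lies, is fixed by the library `geometry`:
#'
#' * `"reverse"` (default, first-strand cDNA sequencing): mate 1 maps antisense
#'   to the transcript and its 5' alignment edge marks the RNA 3' end.
#' * `"forward"`: the mirror convention — mate 2 is the antisense mate whose 5'
#'   alignment edge marks the RNA 3' end.
#'
#' Discordant pairs (mates on different replicons or on the same strand) are
#' skipped and counted, not an error; secondary and supplementary alignments
#' are ignored.
#'
#' @param path SAM or BAM file (SAM is converted on the fly).
#' @param geometry Library geometry, `"reverse"` or `"forward"`.
#' @param min_mapq Minimum mapping quality required of both mates.
#' @param dedup If `TRUE`, collapse fragments with identical
#'   `(replicon, strand, end3, start5)`. Off by default: the internal
#'   enrichment score relies on PCR duplicates keeping their identical
#'   coordinates so that they do not inflate the score.
#' @param replicate Integer replicate label attached to every fragment.
#' @return A tibble with columns `replicon`, `strand` (transcript strand),
#'   `end3`, `start5` (0-based genomic positions), `length` and `replicate`.
#'   Ingest counters are attached as attribute `counters`.
#' @export
read_fragments <- function(path, geometry = c("reverse", "forward"),
                           min_mapq = 0, dedup = FALSE, replicate = 1L) {
  geometry <- match.arg(geometry)
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    path <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                             indexDestination = TRUE)
  }
  param <- Rsamtools::ScanBamParam(
    what = "mapq",
    flag = Rsamtools::scanBamFlag(isPaired = TRUE,
                                  isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE)
  )
  pairs <- GenomicAlignments::readGAlignmentPairs(path, param = param)
  m1 <- GenomicAlignments::first(pairs)
  m2 <- GenomicAlignments::second(pairs)
  repl1 <- as.character(GenomeInfoDb::seqnames(m1))
  repl2 <- as.character(GenomeInfoDb::seqnames(m2))
  s1 <- as.character(BiocGenerics::strand(m1))
  s2 <- as.character(BiocGenerics::strand(m2))
  concordant <- repl1 == repl2 & s1 != s2
  mq <- pmin(S4Vectors::mcols(m1)$mapq, S4Vectors::mcols(m2)$mapq)
  mq[is.na(mq)] <- 255L
  keep <- concordant & mq >= min_mapq

  # 1-based inclusive alignment spans -> 0-based
  st1 <- BiocGenerics::start(m1) - 1L; en1 <- BiocGenerics::end(m1) - 1L
  st2 <- BiocGenerics::start(m2) - 1L; en2 <- BiocGenerics::end(m2) - 1L

  # the anchor mate maps antisense to the transcript; its 5' alignment edge is
  # the RNA 3' end (for a minus-strand alignment the 5' edge is the right end)
  if (geometry == "reverse") {
    anchor_strand <- s1
  } else {
    anchor_strand <- s2
  }
  tx_strand <- other_strand(anchor_strand)
  anchor5 <- if (geometry == "reverse") {
    ifelse(s1 == "+", st1, en1)
  } else {
    ifelse(s2 == "+", st2, en2)
  }
  far_edge <- ifelse(tx_strand == "+", pmin(st1, st2), pmax(en1, en2))

  out <- tibble::tibble(
    replicon = repl1, strand = tx_strand,
    end3 = as.integer(anchor5), start5 = as.integer(far_edge)
  )[keep, ]
  out$length <- abs(out$end3 - out$start5) + 1L
  out$replicate <- as.integer(replicate)
  counters <- c(pairs_read = length(pairs),
                discordant_skipped = sum(!concordant),
                mapq_filtered = sum(concordant & mq < min_mapq))
  if (dedup) {
    n0 <- nrow(out)
    out <- dplyr::distinct(out, .data$replicon, .data$strand, .data$end3,
                           .data$start5, .keep_all = TRUE)
    counters <- c(counters, duplicates_collapsed = n0 - nrow(out))
  }
  attr(out, "counters") <- counters
  out
}

#' Drop over-long fragments
#'
#' Long inserts are uninformative for end calling and add outlier start
#' positions; the published analysis caps fragment length at 100 nt.
#'
#' @param fragments Fragment tibble.
#' @param max_len Maximum fragment length retained (inclusive).
#' @return Filtered fragment tibble with attribute `n_removed`.
#' @export
filter_fragments <- function(fragments, max_len = 100) {
  keep <- fragments$length <= max_len
  out <- fragments[keep, ]
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Build per-strand count tracks from fragments
#'
#' For every (replicon, strand) three integer arrays over all positions are
#' built: `end` (fragment 3' ends per position, the "read stop" statistic),
#' `start` (fragment 5' break points per position) and `span` (fragments whose
#' insert overlaps the position). `span` counts the full insert span, not only
#' read-covered bases.
#'
#' @param fragments Fragment tibble (replicates are pooled; pre-filter if
#'   per-replicate tracks are wanted).
#' @param replicons Replicon tibble with `id` and `length`.
#' @return A `tts_tracks` object; see [tidy.tts_tracks()] for a tabular view.
#' @export
build_tracks <- function(fragments, replicons) {
  check_strand(fragments$strand)
  lens <- setNames(as.integer(replicons$length), replicons$id)
  bad <- setdiff(unique(fragments$replicon), names(lens))
  if (length(bad)) stop("fragments on unknown replicons: ",
                        paste(bad, collapse = ", "), call. = FALSE)
  tracks <- list()
  for (rep_id in names(lens)) {
    L <- lens[[rep_id]]
    for (s in c("+", "-")) {
      fr <- fragments[fragments$replicon == rep_id & fragments$strand == s, ]
      end_c <- tabulate(fr$end3 + 1L, nbins = L)
      start_c <- tabulate(fr$start5 + 1L, nbins = L)
      lo <- pmin(fr$end3, fr$start5); hi <- pmax(fr$end3, fr$start5)
      delta <- integer(L + 1L)
      if (nrow(fr)) {
        add <- tabulate(lo + 1L, nbins = L + 1L)
        rem <- tabulate(hi + 2L, nbins = L + 1L)
        delta <- add - rem
      }
      span <- cumsum(delta)[seq_len(L)]
      tracks[[paste0(rep_id, "|", s)]] <-
        list(end = end_c, start = start_c, span = as.integer(span))
    }
  }
  structure(list(tracks = tracks, replicon_lengths = lens),
            class = "tts_tracks")
}

#' @noRd
track_slot <- function(tracks, replicon, strand) {
  tracks$tracks[[paste0(replicon, "|", strand)]]
}

#' @export
print.tts_tracks <- function(x, ...) {
  cat("<tts_tracks> ", length(x$replicon_lengths), " replicon(s), ",
      sum(vapply(x$tracks, function(t) sum(t$end), 0)), " fragment ends\n", sep = "")
  invisible(x)
}

#' Tidy view of count tracks
#'
#' @param x A `tts_tracks` object.
#' @param ... Unused.
#' @return A tibble with one row per position where any track is non-zero:
#'   `replicon`, `strand`, `position`, `end_count`, `start_count`,
#'   `span_coverage`.
#' @method tidy tts_tracks
#' @export
tidy.tts_tracks <- function(x, ...) {
  purrr::map_dfr(names(x$tracks), function(key) {
    parts <- strsplit(key, "|", fixed = TRUE)[[1]]
    t <- x$tracks[[key]]
    nz <- which(t$end > 0L | t$start > 0L | t$span > 0L)
    tibble::tibble(replicon = parts[1], strand = parts[2], position = nz - 1L,
                   end_count = t$end[nz], start_count = t$start[nz],
                   span_coverage = t$span[nz])
  })
}

#' Write count tracks as strand-split bedGraph files
#'
#' Six files are produced: `<prefix>.<track>.plus.bedgraph` and
#' `...minus.bedgraph` for the end, start and span tracks, with zero runs
#' omitted.
#'
#' @param tracks A `tts_tracks` object.
#' @param prefix Output path prefix.
#' @return Character vector of files written, invisibly.
#' @export
write_bedgraph <- function(tracks, prefix) {
  files <- character()
  for (type in c("end", "start", "span")) {
    for (s in c("+", "-")) {
      path <- sprintf("%s.%s.%s.bedgraph", prefix, type,
                      if (s == "+") "plus" else "minus")
      rows <- purrr::map_dfr(names(tracks$replicon_lengths), function(rep_id) {
        v <- track_slot(tracks, rep_id, s)[[type]]
        r <- rle(v)
        ends <- cumsum(r$lengths)
        starts <- ends - r$lengths
        keep <- r$values != 0
        tibble::tibble(chrom = rep_id, start = starts[keep], end = ends[keep],
                       value = r$values[keep])
      })
      readr::write_tsv(rows, path, col_names = FALSE, progress = FALSE)
      files <- c(files, path)
    }
  }
  invisible(files)
}
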