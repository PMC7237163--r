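# TTS calling: only positions supported by both independent lines of evidence
# (internal enrichment and peak calling) within 10 nt become termination-site
# calls, which are then merged, ranked, classified and measured.

#' Intersect internal-enrichment sites with peak calls
#'
#' Pairs IE sites and PC peaks on the same replicon and strand lying within
#' `max_dist` of each other, greedily by increasing distance so that each site
#' supports at most one call. When the two evidence positions differ, the one
#' with the higher pooled end count is reported (ties toward the transcript
#' 5'-most position).
#'
#' @param ie IE site tibble from [ie_sites()].
#' @param pc Peak tibble from [call_peaks()].
#' @param tracks Pooled `tts_tracks` used to look up end counts.
#' @param max_dist Maximum distance (nt) between the IE and PC positions.
#' @return A tibble of candidate TTS with `replicon`, `strand`, `position`,
#'   `end_count`, `ie_position`, `pc_position`, `ie_combined_score`,
#'   `pc_zscore`.
#' @export
intersect_ie_pc <- function(ie, pc, tracks, max_dist = 10) {
  res <- purrr::map_dfr(
    split_strata(ie, pc),
    function(st) {
      a <- st$a; b <- st$b
      if (nrow(a) == 0 || nrow(b) == 0) return(NULL)
      cand <- tidyr::expand_grid(i = seq_len(nrow(a)), j = seq_len(nrow(b)))
      cand$dist <- abs(a$position[cand$i] - b$position[cand$j])
      cand <- cand[cand$dist <= max_dist, ]
      if (nrow(cand) == 0) return(NULL)
      cand <- cand[order(cand$dist, a$position[cand$i], b$position[cand$j]), ]
      used_i <- logical(nrow(a)); used_j <- logical(nrow(b))
      rows <- list()
      for (k in seq_len(nrow(cand))) {
        i <- cand$i[k]; j <- cand$j[k]
        if (used_i[i] || used_j[j]) next
        used_i[i] <- TRUE; used_j[j] <- TRUE
        strand <- a$strand[i]
        slot <- track_slot(tracks, a$replicon[i], strand)
        pos2 <- c(a$position[i], b$position[j])
        cnt2 <- slot$end[pos2 + 1L]
        lead <- pick_max_count(pos2, cnt2, strand)
        rows[[length(rows) + 1L]] <- tibble::tibble(
          replicon = a$replicon[i], strand = strand,
          position = pos2[lead], end_count = as.integer(cnt2[lead]),
          ie_position = a$position[i], pc_position = b$position[j],
          ie_combined_score = a$combined_score[i], pc_zscore = b$zscore[j]
        )
      }
      dplyr::bind_rows(rows)
    }
  )
  if (nrow(res) == 0) return(empty_tts())
  dplyr::arrange(res, .data$replicon, .data$strand, .data$position)
}

#' @noRd
split_strata <- function(a, b) {
  keys <- unique(rbind(a[c("replicon", "strand")], b[c("replicon", "strand")]))
  purrr::pmap(keys, function(replicon, strand) {
    list(a = a[a$replicon == replicon & a$strand == strand, ],
         b = b[b$replicon == replicon & b$strand == strand, ])
  })
}

#' @noRd
empty_tts <- function() {
  tibble::tibble(replicon = character(), strand = character(),
                 position = integer(), end_count = integer(),
                 ie_position = integer(), pc_position = integer(),
                 ie_combined_score = double(), pc_zscore = double())
}

#' Merge very closely spaced TTS calls
#'
#' Within any chain of same-strand calls spaced less than `min_sep` nt apart
#' only the call with the highest end count survives (ties toward the
#' transcript 5'-most), so the reported set has pairwise spacing of at least
#' `min_sep`. Calls 11 nt or further apart are distinct, closely spaced TTS
#' and are both kept.
#'
#' @param calls TTS call tibble (needs `replicon`, `strand`, `position`,
#'   `end_count`).
#' @param min_sep Minimum surviving spacing in nt; calls closer than this are
#'   merged.
#' @return The merged call tibble.
#' @export
merge_close <- function(calls, min_sep = 10) {
  if (nrow(calls) == 0) return(calls)
  calls <- dplyr::arrange(calls, .data$replicon, .data$strand, .data$position)
  grp <- dplyr::group_by(calls, .data$replicon, .data$strand)
  out <- dplyr::group_modify(grp, function(df, key) {
    gap <- c(Inf, diff(df$position))
    cluster <- cumsum(gap >= min_sep)
    purrr::map_dfr(split(df, cluster), function(cl) {
      cl[pick_max_count(cl$position, cl$end_count, key$strand), ]
    })
  })
  dplyr::arrange(dplyr::ungroup(out), .data$replicon, .data$strand, .data$position)
}

#' Assign first/secondary rank and upstream gene to TTS
#'
#' Walking each replicon strand in transcript orientation: the first TTS after
#' a gene's 3' end (with no other gene end or TSS in between) is that gene's
#' `first` TTS; each following TTS whose upstream-adjacent feature is another
#' TTS is a `secondary` TTS chained to the same gene. A TSS or another gene 3'
#' end breaks the chain. TTS with no upstream same-strand gene keep rank `NA`.
#'
#' @param calls Merged TTS call tibble.
#' @param genes Gene annotation tibble.
#' @param tss Optional tibble of transcription start sites with `replicon`,
#'   `position`, `strand`; these break secondary chains.
#' @return `calls` with added `rank` (`"first"`/`"secondary"`/`NA`) and
#'   `upstream_gene` columns.
#' @export
rank_tts <- function(calls, genes, tss = NULL) {
  genes <- gene_end3(genes)
  calls$rank <- NA_character_
  calls$upstream_gene <- NA_character_
  if (nrow(calls) == 0) return(calls)
  for (key in unique(paste0(calls$replicon, "|", calls$strand))) {
    parts <- strsplit(key, "|", fixed = TRUE)[[1]]
    s <- parts[2]
    idx <- which(calls$replicon == parts[1] & calls$strand == s)
    g <- genes[genes$replicon == parts[1] & genes$strand == s, ]
    ev <- tibble::tibble(
      position = c(calls$position[idx], g$end3),
      kind = c(rep("tts", length(idx)), rep("gene", nrow(g))),
      id = c(as.character(idx), g$gene_id)
    )
    if (!is.null(tss)) {
      tpos <- tss$position[tss$replicon == parts[1] & tss$strand == s]
      ev <- dplyr::bind_rows(ev, tibble::tibble(
        position = tpos, kind = "tss", id = NA_character_))
    }
    # transcript order; at equal coordinates the gene end precedes the TTS so
    # that a TTS exactly at a gene end ranks `first` with a 0-nt UTR
    kind_prio <- c(gene = 0L, tss = 0L, tts = 1L)
    ord <- order(strand_dir(s) * ev$position, kind_prio[ev$kind])
    ev <- ev[ord, ]
    current_gene <- NA_character_
    seen_first <- FALSE
    for (r in seq_len(nrow(ev))) {
      if (ev$kind[r] == "gene") {
        current_gene <- ev$id[r]; seen_first <- FALSE
      } else if (ev$kind[r] == "tss") {
        current_gene <- NA_character_
      } else {
        ci <- as.integer(ev$id[r])
        if (!is.na(current_gene)) {
          calls$rank[ci] <- if (seen_first) "secondary" else "first"
          calls$upstream_gene[ci] <- current_gene
          seen_first <- TRUE
        }
      }
    }
  }
  calls
}

#' Classify TTS as intergenic or coding, and flag antisense sites
#'
#' A TTS is `coding` when its position falls inside any annotated gene
#' interval on either strand, else `intergenic`; it is antisense when it falls
#' inside a gene annotated on the opposite strand (evidence of antisense
#' transcription terminating there).
#'
#' @inheritParams rank_tts
#' @return `calls` with added `location` and `antisense` columns.
#' @export
classify_location <- function(calls, genes) {
  inside <- function(pos, repl, g) {
    vapply(seq_along(pos), function(k) {
      any(g$replicon == repl[k] & g$start <= pos[k] & pos[k] < g$end)
    }, logical(1))
  }
  any_gene <- vapply(seq_len(nrow(calls)), function(k) {
    any(genes$replicon == calls$replicon[k] &
          genes$start <= calls$position[k] & calls$position[k] < genes$end)
  }, logical(1))
  anti <- vapply(seq_len(nrow(calls)), function(k) {
    any(genes$replicon == calls$replicon[k] &
          genes$strand == other_strand(calls$strand[k]) &
          genes$start <= calls$position[k] & calls$position[k] < genes$end)
  }, logical(1))
  calls$location <- ifelse(any_gene, "coding", "intergenic")
  calls$antisense <- anti
  calls
}

#' 3' UTR lengths for ranked TTS
#'
#' The UTR length is the transcript-orientation distance from the 3' end of
#' the upstream annotated gene to the TTS, computed for first and secondary
#' TTS alike (a secondary TTS measures the longer 3' UTR of the read-through
#' transcript).
#'
#' @inheritParams rank_tts
#' @return `calls` with an added `utr_length` column (`NA` where no upstream
#'   gene is assigned).
#' @export
utr_lengths <- function(calls, genes) {
  genes <- gene_end3(genes)
  ge <- setNames(genes$end3, genes$gene_id)
  calls$utr_length <- ifelse(
    is.na(calls$upstream_gene), NA_integer_,
    as.integer(downstream_distance(ge[calls$upstream_gene], calls$position,
                                   calls$strand))
  )
  calls
}

#' Validate 3' UTR continuity against independent RNA-seq coverage
#'
#' A called 3' UTR belongs to the upstream gene's transcript only if
#' transcription runs uninterrupted from the gene into the UTR. Given a span
#' coverage track from an independent (whole-transcriptome) library,
#' `utr_continuous` is `TRUE` iff every position from the gene start through
#' the TTS has coverage of at least 1.
#'
#' @inheritParams rank_tts
#' @param coverage `tts_tracks` built from the independent RNA-seq library.
#' @return `calls` with an added logical `utr_continuous` column (`NA` where
#'   no upstream gene is assigned).
#' @export
validate_utr <- function(calls, coverage, genes) {
  gmap <- setNames(seq_len(nrow(genes)), genes$gene_id)
  calls$utr_continuous <- NA
  for (k in seq_len(nrow(calls))) {
    gid <- calls$upstream_gene[k]
    if (is.na(gid)) next
    g <- genes[gmap[[gid]], ]
    lo <- min(g$start, calls$position[k])
    hi <- max(g$end - 1L, calls$position[k])
    slot <- track_slot(coverage, calls$replicon[k], calls$strand[k])
    calls$utr_continuous[k] <- all(slot$span[(lo + 1L):(hi + 1L)] >= 1L)
  }
  calls
}

#' Call and annotate transcription termination sites
#'
#' End-to-end TTS calling from evidence tables: intersect IE and PC evidence,
#' merge closely spaced calls, then (if an annotation is given) rank, classify
#' and measure 3' UTRs.
#'
#' @inheritParams intersect_ie_pc
#' @inheritParams merge_close
#' @param genes Optional gene annotation tibble.
#' @param tss Optional TSS tibble (see [rank_tts()]).
#' @param rnaseq_coverage Optional independent coverage `tts_tracks` for
#'   [validate_utr()].
#' @return The annotated TTS tibble.
#' @export
call_tts <- function(ie, pc, tracks, genes = NULL, tss = NULL,
                     rnaseq_coverage = NULL, max_dist = 10, min_sep = 10) {
  calls <- intersect_ie_pc(ie, pc, tracks, max_dist = max_dist)
  calls <- merge_close(calls, min_sep = min_sep)
  if (!is.null(genes)) {
    calls <- rank_tts(calls, genes, tss = tss)
    calls <- classify_location(calls, genes)
    calls <- utr_lengths(calls, genes)
    if (!is.null(rnaseq_coverage)) {
      calls <- validate_utr(calls, rnaseq_coverage, genes)
    }
  }
  calls
}
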