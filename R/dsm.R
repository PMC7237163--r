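# Annotation-anchored baseline caller ("downstream-region maximum" method).
#
# For each annotated gene, the inserts overlapping it define a downstream
# target region whose length is their mean insert length; the position with
# the highest fragment-end coverage inside that region is reported as the
# gene's RNA 3' end. The method is bound to its regions: a true end lying
# beyond the mean-insert window is missed and a minor internal pile-up is
# reported instead, and at most one end per gene can ever be found. These
# failure modes motivate annotation-independent calling.

#' Call RNA 3' ends downstream of annotated genes (baseline method)
#'
#' @param fragments Fragment tibble (replicates pooled; do not pre-apply the
#'   100-nt internal-enrichment cap — this method has its own insert cap).
#' @param genes Gene annotation tibble.
#' @param max_insert Inserts longer than this (nt) are excluded.
#' @param min_cov Minimum fragment-end count for a position to be a valid
#'   candidate.
#' @return A tibble with one row per gene that yields a call: `gene_id`,
#'   `replicon`, `strand`, `region_start`, `region_end` (0-based half-open),
#'   `region_length` (rounded mean insert length), `position`, `end_count`.
#'   Ties on end count resolve toward the position closest to the gene end.
#' @export
dsm_call <- function(fragments, genes, max_insert = 500, min_cov = 4) {
  genes <- gene_end3(genes)
  fr <- fragments[fragments$length <= max_insert, ]
  lo <- pmin(fr$end3, fr$start5); hi <- pmax(fr$end3, fr$start5)
  res <- purrr::map_dfr(seq_len(nrow(genes)), function(k) {
    g <- genes[k, ]
    sel <- fr$replicon == g$replicon & fr$strand == g$strand &
      hi >= g$start & lo < g$end
    if (!any(sel)) return(NULL)
    region_len <- as.integer(round_half_up(mean(fr$length[sel])))
    if (region_len < 1L) return(NULL)
    d <- strand_dir(g$strand)
    region <- g$end3 + d * seq_len(region_len)
    cnt <- table(fr$end3[sel])
    pos <- as.integer(names(cnt))
    keep <- pos %in% region & as.integer(cnt) >= min_cov
    if (!any(keep)) return(NULL)
    pos <- pos[keep]; n <- as.integer(cnt)[keep]
    best <- which(n == max(n))
    best <- best[which.min(abs(pos[best] - g$end3))]
    tibble::tibble(
      gene_id = g$gene_id, replicon = g$replicon, strand = g$strand,
      region_start = min(region), region_end = max(region) + 1L,
      region_length = region_len, position = pos[best], end_count = n[best]
    )
  })
  if (nrow(res) == 0) {
    return(tibble::tibble(gene_id = character(), replicon = character(),
                          strand = character(), region_start = integer(),
                          region_end = integer(), region_length = integer(),
                          position = integer(), end_count = integer()))
  }
  dplyr::arrange(res, .data$replicon, .data$strand, .data$position)
}

#' Compare baseline and IE-PC calls inside baseline regions
#'
#' Annotation-independent calls can only be compared with the baseline inside
#' the regions the baseline examined: IE-PC TTS are first restricted to the
#' union of the per-gene downstream regions (same strand), then matched 1:1
#' greedily by distance against the baseline calls.
#'
#' @param dsm Baseline call tibble from [dsm_call()].
#' @param tts IE-PC TTS tibble.
#' @param max_dist Two calls within this distance (nt, inclusive) count as
#'   overlapping.
#' @return A tibble with one row per replicon plus a `Total` row, columns
#'   `iepc_only`, `overlapping`, `dsm_only`.
#' @export
compare_dsm_iepc <- function(dsm, tts, max_dist = 10) {
  in_region <- vapply(seq_len(nrow(tts)), function(k) {
    any(dsm$replicon == tts$replicon[k] & dsm$strand == tts$strand[k] &
          dsm$region_start <= tts$position[k] & tts$position[k] < dsm$region_end)
  }, logical(1))
  tts_in <- tts[in_region, ]
  per_repl <- purrr::map_dfr(
    unique(c(dsm$replicon, tts_in$replicon)),
    function(rep_id) {
      d <- dsm[dsm$replicon == rep_id, ]
      t <- tts_in[tts_in$replicon == rep_id, ]
      matched <- 0L
      for (s in c("+", "-")) {
        dp <- d$position[d$strand == s]
        tp <- t$position[t$strand == s]
        if (!length(dp) || !length(tp)) next
        cand <- expand.grid(i = seq_along(dp), j = seq_along(tp))
        cand$dist <- abs(dp[cand$i] - tp[cand$j])
        cand <- cand[cand$dist <= max_dist, ]
        cand <- cand[order(cand$dist, cand$i, cand$j), ]
        used_i <- logical(length(dp)); used_j <- logical(length(tp))
        for (k in seq_len(nrow(cand))) {
          if (used_i[cand$i[k]] || used_j[cand$j[k]]) next
          used_i[cand$i[k]] <- TRUE; used_j[cand$j[k]] <- TRUE
          matched <- matched + 1L
        }
      }
      tibble::tibble(replicon = rep_id,
                     iepc_only = nrow(t) - matched,
                     overlapping = matched,
                     dsm_only = nrow(d) - matched)
    }
  )
  dplyr::bind_rows(
    per_repl,
    tibble::tibble(replicon = "Total",
                   iepc_only = sum(per_repl$iepc_only),
                   overlapping = sum(per_repl$overlapping),
                   dsm_only = sum(per_repl$dsm_only))
  )
}
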