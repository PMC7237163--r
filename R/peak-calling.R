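# Sliding-window peak calling (PC).
#
# Complementary to internal enrichment: a position is a putative RNA 3' end if
# its fragment-end count ("read stops") spikes above the local background. The
# genome is tiled with 150-nt windows advanced in 100-nt steps (50-nt overlap);
# within each window the mean and standard deviation of the end counts give a
# per-position z-score. Overlapping windows evaluate interior positions in
# more than one local context, and passing in any one context suffices.

#' Call fragment-end peaks with a sliding-window z-score
#'
#' A position is reported when, in at least one covering window, its z-score
#' reaches `z_min`, and it carries at least `min_stops` fragment ends, and
#' those ends amount to at least `min_frac` of the span coverage at the
#' transcript-upstream neighbour (genomic `i - 1` on `+`, `i + 1` on `-`).
#' Windows with zero standard deviation contribute no calls; trailing partial
#' windows at replicon ends are evaluated as-is. The window standard deviation
#' is the population (not sample) estimator.
#'
#' @param tracks A `tts_tracks` object (replicates pooled).
#' @param window Window size in nt.
#' @param step Window advance in nt (`window - step` is the overlap).
#' @param z_min Minimum z-score.
#' @param min_stops Minimum fragment-end count at the position.
#' @param min_frac Minimum fraction of upstream span coverage that must end at
#'   the position (inclusive comparison). Positions at the replicon edge with
#'   no upstream neighbour have upstream coverage 0 and pass the fraction
#'   filter vacuously.
#' @return A tibble with `replicon`, `strand`, `position`, `stops`, `zscore`
#'   (the maximum over qualifying windows), `window_mean`, `window_sd` (from
#'   that window), `upstream_coverage` and `stop_fraction`.
#' @export
call_peaks <- function(tracks, window = 150, step = 100, z_min = 2,
                       min_stops = 5, min_frac = 0.10) {
  stopifnot(window > 0, step > 0, step <= window)
  res <- purrr::map_dfr(names(tracks$tracks), function(key) {
    parts <- strsplit(key, "|", fixed = TRUE)[[1]]
    strand <- parts[2]
    t <- tracks$tracks[[key]]
    end <- t$end
    L <- length(end)
    if (L == 0 || sum(end) == 0) return(NULL)
    up_cov <- if (strand == "+") c(0L, t$span[-L]) else c(t$span[-1L], 0L)
    gate <- which(end >= min_stops & end >= min_frac * up_cov)
    if (length(gate) == 0) return(NULL)

    best_z <- rep(-Inf, length(gate))
    best_m <- best_s <- rep(NA_real_, length(gate))
    for (w0 in seq(1L, L, by = step)) {
      w1 <- min(w0 + window - 1L, L)
      in_w <- which(gate >= w0 & gate <= w1)
      if (length(in_w) == 0) next
      x <- end[w0:w1]
      m <- mean(x)
      s <- sqrt(mean((x - m)^2))
      if (s <= 0) next
      z <- (end[gate[in_w]] - m) / s
      upd <- in_w[z >= z_min & z > best_z[in_w]]
      if (length(upd)) {
        best_z[upd] <- (end[gate[upd]] - m) / s
        best_m[upd] <- m
        best_s[upd] <- s
      }
    }
    hit <- is.finite(best_z)
    if (!any(hit)) return(NULL)
    pos <- gate[hit]
    tibble::tibble(
      replicon = parts[1], strand = strand, position = pos - 1L,
      stops = end[pos], zscore = best_z[hit],
      window_mean = best_m[hit], window_sd = best_s[hit],
      upstream_coverage = up_cov[pos],
      stop_fraction = ifelse(up_cov[pos] > 0, end[pos] / up_cov[pos], Inf)
    )
  })
  if (nrow(res) == 0) {
    return(tibble::tibble(replicon = character(), strand = character(),
                          position = integer(), stops = integer(),
                          zscore = double(), window_mean = double(),
                          window_sd = double(), upstream_coverage = integer(),
                          stop_fraction = double()))
  }
  dplyr::arrange(res, .data$replicon, .data$strand, .data$position)
}
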