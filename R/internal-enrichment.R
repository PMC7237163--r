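# Internal enrichment (IE).
#
# Random fragmentation during library preparation makes it very unlikely that
# independent cDNA clones share an exact break point, whereas a genuine RNA 3'
# end recurs across clones. A candidate end position i is therefore scored as
#
#   S_i = C_i / ( prod_{j in J(i)} C_j )^(1/n),   n = |J(i)|
#
# where C_i is the fragment-end count at i, C_j the fragment-start count at a
# break-point position j linked to i by at least one mate pair, and J(i) the
# set of such linked start positions. PCR duplicates share both coordinates,
# inflate C_i and C_j equally, and leave S_i unchanged. Because only ends, not
# starts, are biologically enriched, the reciprocally defined start scores S_j
# supply an empirical null distribution.

#' Internal enrichment scores for fragment-end positions
#'
#' Scores every end position of one replicate's fragment set. The geometric
#' mean over linked start counts is computed in log space.
#'
#' @param fragments Fragment tibble from a single replicate.
#' @param min_reads Minimum count floor: positions with `end_count` below it
#'   are not scored, and start positions with fewer fragments are excluded
#'   from the linked set.
#' @return A tibble with `replicon`, `strand`, `position` (the end
#'   coordinate), `end_count`, `n_linked` and `score`, sorted by position.
#' @examples
#' fr <- tibble::tibble(replicon = "chr", strand = "+",
#'                      end3 = c(50L, 50L, 50L), start5 = c(10L, 20L, 20L),
#'                      length = 41L, replicate = 1L)
#' ie_scores(fr)  # S = 3 / sqrt(2)
#' @export
ie_scores <- function(fragments, min_reads = 1) {
  starts <- dplyr::count(fragments, .data$replicon, .data$strand, .data$start5,
                         name = "start_count")
  ends <- dplyr::count(fragments, .data$replicon, .data$strand, .data$end3,
                       name = "end_count")
  links <- dplyr::distinct(fragments, .data$replicon, .data$strand,
                           .data$end3, .data$start5)
  links <- dplyr::inner_join(links, starts, by = c("replicon", "strand", "start5"))
  links <- dplyr::filter(links, .data$start_count >= min_reads)
  per_end <- dplyr::summarise(
    dplyr::group_by(links, .data$replicon, .data$strand, .data$end3),
    n_linked = dplyr::n(),
    log_gm = mean(log(.data$start_count)),
    .groups = "drop"
  )
  out <- dplyr::inner_join(per_end, ends, by = c("replicon", "strand", "end3"))
  out <- dplyr::filter(out, .data$end_count >= min_reads)
  out <- dplyr::mutate(out,
                       score = .data$end_count / exp(.data$log_gm),
                       position = .data$end3)
  dplyr::arrange(
    dplyr::select(out, "replicon", "strand", "position", "end_count",
                  "n_linked", "score"),
    .data$replicon, .data$strand, .data$position
  )
}

#' Reciprocal background scores for fragment-start positions
#'
#' The null distribution for [ie_scores()]: every start position j is scored
#' as `S_j = C_j / (prod_{i in I(j)} C_i)^(1/|I(j)|)` over its linked end
#' positions. Start positions are not biologically enriched, so these scores
#' describe chance-level enrichment.
#'
#' @inheritParams ie_scores
#' @return A tibble with `replicon`, `strand`, `position` (the start
#'   coordinate), `start_count`, `n_linked` and `score`, sorted by score.
#' @export
ie_background <- function(fragments, min_reads = 1) {
  if (nrow(fragments) == 0) stop("no fragments: background is undefined", call. = FALSE)
  flipped <- dplyr::rename(fragments, end3 = "start5", start5 = "end3")
  out <- ie_scores(flipped, min_reads = min_reads)
  out <- dplyr::rename(out, start_count = "end_count")
  dplyr::arrange(out, .data$score)
}

#' Empirical p-values against a background score distribution
#'
#' `p = (#background >= score + 1) / (N + 1)`: the add-one convention keeps p
#' strictly positive even above the background maximum, and p is monotone
#' non-increasing in the score.
#'
#' Scores are ratios of integer counts; equal sites must tie regardless of the
#' floating-point path that produced them, so the `>=` comparison carries a
#' small relative tolerance.
#'
#' @param score Numeric vector of observed scores.
#' @param background Numeric vector of background scores (any order).
#' @return Numeric vector of p-values in `(0, 1]`.
#' @export
empirical_pvalue <- function(score, background) {
  if (length(background) == 0) stop("empty background", call. = FALSE)
  bg <- sort(background)
  n <- length(bg)
  n_less <- findInterval(score * (1 - 1e-9), bg, left.open = TRUE)
  (n - n_less + 1) / (n + 1)
}

#' Score one replicate and attach empirical p-values
#'
#' Background scores are pooled across replicons per strand (the genome-wide
#' background maximizes background size on small genomes).
#'
#' @inheritParams ie_scores
#' @return [ie_scores()] output with an added `pvalue` column.
#' @export
ie_score_replicate <- function(fragments, min_reads = 1) {
  scored <- ie_scores(fragments, min_reads = min_reads)
  bg <- ie_background(fragments, min_reads = min_reads)
  dplyr::mutate(
    dplyr::group_by(scored, .data$strand),
    pvalue = empirical_pvalue(.data$score,
                              bg$score[bg$strand == .data$strand[1]])
  ) |> dplyr::ungroup()
}

#' Combine per-replicate IE results into consensus sites
#'
#' A site is kept only if it is present (within `match_dist`) in every
#' replicate with an empirical p-value of at most `alpha` in each. The
#' geometric mean of the matched p-values becomes the combined score, and the
#' reported position is the matched position with the highest end count
#' (ties broken toward the 5'-most position on the transcript strand).
#'
#' @param per_replicate Tibble with columns `replicate`, `replicon`, `strand`,
#'   `position`, `end_count`, `score`, `n_linked`, `pvalue` (rows from
#'   [ie_score_replicate()] bound together).
#' @param alpha Maximum empirical p-value allowed in every replicate.
#' @param match_dist Maximum distance (nt) between replicate positions
#'   regarded as the same site; 0 requires exact agreement.
#' @return A tibble of consensus IE sites with `combined_score` (geometric
#'   mean of p-values) and one `p_rep<k>` column per replicate.
#' @export
combine_replicates <- function(per_replicate, alpha = 0.05, match_dist = 0) {
  reps <- sort(unique(per_replicate$replicate))
  n_rep <- length(reps)
  passing <- dplyr::filter(per_replicate, .data$pvalue <= alpha)
  if (nrow(passing) == 0) return(empty_ie_sites(reps))

  grouped <- dplyr::group_by(passing, .data$replicon, .data$strand)
  keys <- dplyr::group_keys(grouped)
  parts <- dplyr::group_split(grouped)
  out <- purrr::map2_dfr(parts, seq_len(nrow(keys)), function(df, k) {
    df <- dplyr::arrange(df, .data$position)
    gap <- c(Inf, diff(df$position))
    cluster <- cumsum(gap > match_dist)
    purrr::map_dfr(split(df, cluster), function(cl) {
      if (length(unique(cl$replicate)) < n_rep) return(NULL)
      # one site per replicate: its best (lowest-p, then highest-count) match
      best <- dplyr::slice(
        dplyr::group_by(cl, .data$replicate),
        order(.data$pvalue, -.data$end_count)[1]
      ) |> dplyr::ungroup()
      lead <- pick_max_count(best$position, best$end_count, best$strand[1])
      tibble::tibble(
        replicon = cl$replicon[1], strand = cl$strand[1],
        position = best$position[lead],
        end_count = best$end_count[lead],
        score = best$score[lead], n_linked = best$n_linked[lead],
        combined_score = geom_mean(best$pvalue),
        pvals = list(setNames(best$pvalue[order(best$replicate)],
                              paste0("p_rep", sort(best$replicate))))
      )
    })
  })
  if (nrow(out) == 0) return(empty_ie_sites(reps))
  out <- tidyr::unnest_wider(out, "pvals")
  dplyr::arrange(out, .data$replicon, .data$strand, .data$position)
}

#' @noRd
empty_ie_sites <- function(reps) {
  base <- tibble::tibble(replicon = character(), strand = character(),
                         position = integer(), end_count = integer(),
                         score = double(), n_linked = integer(),
                         combined_score = double())
  for (r in reps) base[[paste0("p_rep", r)]] <- double()
  base
}

# index of the maximal-count element; ties go to the transcript 5'-most
#' @noRd
pick_max_count <- function(position, count, strand) {
  cand <- which(count == max(count))
  if (strand == "+") cand[which.min(position[cand])]
  else cand[which.max(position[cand])]
}

#' Call internal-enrichment sites across replicates
#'
#' Convenience wrapper: scores each replicate in `fragments` (split on the
#' `replicate` column), assigns empirical p-values against the strand-pooled
#' reciprocal background, and intersects the replicates.
#'
#' @param fragments Fragment tibble covering one or more replicates.
#' @inheritParams combine_replicates
#' @inheritParams ie_scores
#' @return Consensus IE site tibble; see [combine_replicates()].
#' @export
ie_sites <- function(fragments, alpha = 0.05, min_reads = 1, match_dist = 0) {
  per_rep <- purrr::map_dfr(
    split(fragments, fragments$replicate),
    function(fr) dplyr::mutate(ie_score_replicate(fr, min_reads = min_reads),
                               replicate = fr$replicate[1])
  )
  combine_replicates(per_rep, alpha = alpha, match_dist = match_dist)
}
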