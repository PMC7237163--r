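# Shared helpers. All coordinates in the package are 0-based half-open on the
# forward genomic strand; single positions (fragment ends, TTS) are 0-based.

#' @noRd
other_strand <- function(strand) ifelse(strand == "+", "-", "+")

# +1 when moving downstream (3'-ward) on the transcript strand
#' @noRd
strand_dir <- function(strand) ifelse(strand == "+", 1L, -1L)

# round-half-up to an integer (base round() is round-half-even)
#' @noRd
round_half_up <- function(x) floor(x + 0.5)

# geometric mean in log space; x must be positive
#' @noRd
geom_mean <- function(x) exp(mean(log(x)))

#' @noRd
check_strand <- function(strand) {
  if (!all(strand %in% c("+", "-"))) {
    stop("strand must be '+' or '-'", call. = FALSE)
  }
  invisible(strand)
}

# transcript-orientation distance from a 3' gene end to a downstream position
#' @noRd
downstream_distance <- function(from, to, strand) {
  strand_dir(strand) * (to - from)
}

#' Write single-position intervals as BED6
#'
#' Positions are written as 1-nt intervals (`start = position`,
#' `end = position + 1`, 0-based half-open per the BED convention).
#'
#' @param x A data frame with columns `replicon`, `position`, `strand`, plus
#'   the column named by `score` and optionally `name`.
#' @param path Output file.
#' @param score Column to place in the BED score field.
#' @return `x`, invisibly.
#' @export
write_bed <- function(x, path, score = "score") {
  name <- if ("name" %in% names(x)) x$name else
    sprintf("%s:%d:%s", x$replicon, x$position, x$strand)
  sc <- if (score %in% names(x)) x[[score]] else 0
  bed <- tibble::tibble(
    chrom = x$replicon, start = x$position, end = x$position + 1L,
    name = name, score = sc, strand = x$strand
  )
  readr::write_tsv(bed, path, col_names = FALSE, progress = FALSE)
  invisible(x)
}
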