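# Independent brute-force oracles. These recompute the scoring definitions by
# direct enumeration (explicit products, explicit windows) and deliberately
# share no code with the package implementations they check.

# end score at every end position by direct product over linked start counts
oracle_ie_scores <- function(fragments) {
  out <- list()
  for (key in unique(paste(fragments$replicon, fragments$strand))) {
    fr <- fragments[paste(fragments$replicon, fragments$strand) == key, ]
    for (i in unique(fr$end3)) {
      sub <- fr[fr$end3 == i, ]
      ci <- nrow(sub)
      js <- unique(sub$start5)
      cj <- vapply(js, function(j) sum(fr$start5 == j), numeric(1))
      out[[length(out) + 1]] <- data.frame(
        replicon = fr$replicon[1], strand = fr$strand[1], position = i,
        end_count = ci, n_linked = length(js),
        score = ci / prod(cj)^(1 / length(js))
      )
    }
  }
  do.call(rbind, out)
}

# reciprocal start scores
oracle_ie_background <- function(fragments) {
  flipped <- fragments
  flipped$end3 <- fragments$start5
  flipped$start5 <- fragments$end3
  oracle_ie_scores(flipped)
}

# empirical p by direct counting; scores are exact rationals, so equality up
# to floating-point noise counts as a tie
oracle_pvalue <- function(score, background) {
  vapply(score, function(s) {
    (sum(background >= s * (1 - 1e-9)) + 1) / (length(background) + 1)
  }, numeric(1))
}

# naive window-materializing peak caller over a single end/span vector pair;
# returns qualifying 0-based positions (the union over window contexts)
oracle_peaks <- function(end, span, strand, window = 150, step = 100,
                         z_min = 2, min_stops = 5, min_frac = 0.10) {
  L <- length(end)
  up <- if (strand == "+") c(0, span[-L]) else c(span[-1], 0)
  hits <- integer(0)
  w0 <- 1
  while (w0 <= L) {
    w <- w0:min(w0 + window - 1, L)
    x <- end[w]
    m <- mean(x)
    s <- sqrt(sum((x - m)^2) / length(x))
    if (s > 0) {
      for (p in w) {
        z <- (end[p] - m) / s
        if (z >= z_min && end[p] >= min_stops && end[p] >= min_frac * up[p]) {
          hits <- c(hits, p - 1L)
        }
      }
    }
    w0 <- w0 + step
  }
  sort(unique(hits))
}

# random fragment set with position collisions (valid plus-strand fragments)
random_fragment_set <- function(n, span = 60L, replicate = 1L) {
  end3 <- sample.int(span, n, replace = TRUE) + 100L
  len <- sample.int(40L, n, replace = TRUE)
  start5 <- pmax(end3 - len, 0L)
  tibble::tibble(replicon = "chr", strand = "+", end3 = end3,
                 start5 = start5, length = end3 - start5 + 1L,
                 replicate = replicate)
}
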