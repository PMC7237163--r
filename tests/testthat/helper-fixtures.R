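# Deterministic fixtures shared between unit and acceptance tests.

# build a tts_tracks object directly from per-strand vectors
make_tracks <- function(end_plus, span_plus = NULL, end_minus = NULL,
                        span_minus = NULL, start_plus = NULL,
                        replicon = "chr") {
  L <- length(end_plus)
  zero <- integer(L)
  if (is.null(span_plus)) span_plus <- end_plus
  if (is.null(end_minus)) end_minus <- zero
  if (is.null(span_minus)) span_minus <- end_minus
  if (is.null(start_plus)) start_plus <- zero
  structure(list(
    tracks = setNames(list(
      list(end = as.integer(end_plus), start = as.integer(start_plus),
           span = as.integer(span_plus)),
      list(end = as.integer(end_minus), start = zero,
           span = as.integer(span_minus))
    ), paste0(replicon, c("|+", "|-"))),
    replicon_lengths = setNames(as.integer(L), replicon)
  ), class = "tts_tracks")
}

frag_row <- function(end3, start5, n = 1, strand = "+", replicate = 1L,
                     replicon = "chr") {
  tibble::tibble(replicon = replicon, strand = strand,
                 end3 = as.integer(end3), start5 = as.integer(start5),
                 length = abs(end3 - start5) + 1L,
                 replicate = as.integer(replicate))[rep(1, n), ]
}

replicate3 <- function(fragments) {
  dplyr::bind_rows(lapply(1:3, function(r) dplyr::mutate(fragments, replicate = r)))
}

# One plus-strand gene [100, 200) whose true 3' end lies at +80 (position 279),
# beyond the mean-insert downstream region (~60 nt), plus a minor internal
# pile-up of 5 PCR-duplicate-like fragments at +30 (position 229). The
# region-bound baseline reports the internal false position; evidence-based
# calling rejects it (duplicates share one start, so the enrichment score is 1)
# and finds the true end.
fig4_fixture <- function() {
  genes <- tibble::tibble(gene_id = "geneA", replicon = "chr", start = 100L,
                          end = 200L, strand = "+", feature_type = "gene")
  body_ends <- seq(120L, 198L, by = 3L)            # scattered gene-body ends
  body <- dplyr::bind_rows(lapply(body_ends, function(e)
    frag_row(e, e - 59L)))                          # length 60, overlap gene
  minor <- frag_row(229L, 170L, n = 5)              # 5 duplicates, one start
  true_end <- dplyr::bind_rows(lapply(40:79, function(len)
    frag_row(279L, 279L - len + 1L)))               # 40 distinct break points
  fragments <- dplyr::bind_rows(body, minor, true_end)
  list(genes = genes,
       fragments = replicate3(fragments),
       replicons = tibble::tibble(id = "chr", length = 600L,
                                  sequence = strrep("A", 600)),
       true_tts = 279L, false_tts = 229L)
}

# One plus-strand gene with two genuine closely spaced ends downstream
# (+40 and +70); a per-gene caller can report only one of them.
fig5_fixture <- function() {
  genes <- tibble::tibble(gene_id = "geneB", replicon = "chr", start = 100L,
                          end = 200L, strand = "+", feature_type = "gene")
  body_ends <- seq(120L, 198L, by = 3L)
  body <- dplyr::bind_rows(lapply(body_ends, function(e) frag_row(e, e - 59L)))
  end1 <- dplyr::bind_rows(lapply(30:49, function(len)
    frag_row(239L, 239L - len + 1L)))
  end2 <- dplyr::bind_rows(lapply(30:49, function(len)
    frag_row(269L, 269L - len + 1L)))
  fragments <- dplyr::bind_rows(body, end1, end2)
  list(genes = genes,
       fragments = replicate3(fragments),
       replicons = tibble::tibble(id = "chr", length = 600L,
                                  sequence = strrep("A", 600)),
       tts = c(239L, 269L))
}
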