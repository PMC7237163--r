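ie_row <- function(pos, strand = "+", score = 0.01) {
  tibble::tibble(replicon = "chr", strand = strand, position = as.integer(pos),
                 end_count = 10L, score = 5, n_linked = 3L,
                 combined_score = score)
}
pc_row <- function(pos, strand = "+") {
  tibble::tibble(replicon = "chr", strand = strand, position = as.integer(pos),
                 stops = 10L, zscore = 5, window_mean = 0.1, window_sd = 1,
                 upstream_coverage = 50L, stop_fraction = 0.2)
}
tracks_with_ends <- function(counts, L = 2000L, strand = "+") {
  end <- integer(L); end[as.integer(names(counts)) + 1L] <- as.integer(counts)
  if (strand == "+") make_tracks(end, rep(100L, L), integer(L), integer(L))
  else make_tracks(integer(L), integer(L), end, rep(100L, L))
}

test_that("IE and PC evidence within 10 nt yields one call at the higher-count position", {
  tr <- tracks_with_ends(c("1000" = 5, "1007" = 9))
  out <- intersect_ie_pc(ie_row(1000), pc_row(1007), tr)
  expect_equal(nrow(out), 1)
  expect_equal(out$position, 1007L)
  expect_equal(out$end_count, 9L)
  expect_equal(out$ie_position, 1000L)
  expect_equal(out$pc_position, 1007L)

  # distance 11 exceeds the tolerance
  expect_equal(nrow(intersect_ie_pc(ie_row(1000), pc_row(1011), tr)), 0)
  # strands never mix
  expect_equal(nrow(intersect_ie_pc(ie_row(1000), pc_row(1000, strand = "-"), tr)), 0)
})

test_that("greedy nearest-first pairing uses each evidence site once", {
  tr <- tracks_with_ends(c("1000" = 5, "1002" = 7, "1008" = 3))
  ie <- dplyr::bind_rows(ie_row(1000), ie_row(1008))
  pc <- pc_row(1002)
  out <- intersect_ie_pc(ie, pc, tr)
  expect_equal(nrow(out), 1)            # one PC peak supports one call
  expect_equal(out$ie_position, 1000L)  # the nearer IE site wins
  expect_equal(out$position, 1002L)
})

test_that("closely spaced calls merge to the highest-coverage position", {
  calls <- tibble::tibble(replicon = "chr", strand = "+",
                          position = c(100L, 105L),
                          end_count = c(20L, 50L))
  expect_equal(merge_close(calls)$position, 105L)

  calls$position <- c(100L, 111L)       # spacing 11: distinct closely spaced TTS
  expect_equal(merge_close(calls)$position, c(100L, 111L))

  calls$position <- c(100L, 105L); calls$end_count <- c(30L, 30L)
  expect_equal(merge_close(calls)$position, 100L)  # tie: transcript 5'-most
  calls$strand <- "-"
  expect_equal(merge_close(calls)$position, 105L)

  # chains collapse transitively and the survivor set is >= 10 nt apart
  calls <- tibble::tibble(replicon = "chr", strand = "+",
                          position = c(100L, 108L, 116L, 140L),
                          end_count = c(5L, 9L, 7L, 2L))
  out <- merge_close(calls)
  expect_equal(out$position, c(108L, 140L))
  expect_true(all(diff(out$position) >= 10))
})

test_that("first and secondary ranks follow the downstream chain rules", {
  genes <- tibble::tibble(gene_id = "gA", replicon = "chr", start = 500L,
                          end = 1001L, strand = "+", feature_type = "gene")
  calls <- tibble::tibble(replicon = "chr", strand = "+",
                          position = c(1097L, 1250L), end_count = c(30L, 10L))
  out <- rank_tts(calls, genes)
  expect_equal(out$rank, c("first", "secondary"))
  expect_equal(out$upstream_gene, c("gA", "gA"))

  # an intervening gene end resets the chain
  genes2 <- dplyr::bind_rows(genes, tibble::tibble(
    gene_id = "gB", replicon = "chr", start = 1150L, end = 1200L,
    strand = "+", feature_type = "gene"))
  out <- rank_tts(calls, genes2)
  expect_equal(out$rank, c("first", "first"))
  expect_equal(out$upstream_gene, c("gA", "gB"))

  # a TSS between two TTS breaks the secondary chain
  tss <- tibble::tibble(replicon = "chr", position = 1150L, strand = "+")
  out <- rank_tts(calls, genes, tss = tss)
  expect_equal(out$rank, c("first", NA))

  # no upstream gene on the strand: rank stays unassigned
  calls_min <- tibble::tibble(replicon = "chr", strand = "-",
                              position = 300L, end_count = 5L)
  out <- rank_tts(calls_min, genes)
  expect_true(is.na(out$rank))
})

test_that("minus-strand ranking walks leftward in transcript orientation", {
  genes <- tibble::tibble(gene_id = "gM", replicon = "chr", start = 2000L,
                          end = 2600L, strand = "-", feature_type = "gene")
  calls <- tibble::tibble(replicon = "chr", strand = "-",
                          position = c(1903L, 1700L), end_count = c(30L, 10L))
  out <- rank_tts(calls, genes)
  expect_equal(out$rank[out$position == 1903], "first")
  expect_equal(out$rank[out$position == 1700], "secondary")
})

test_that("location and antisense classification follow gene overlap by strand", {
  genes <- tibble::tibble(gene_id = c("gP", "gM"), replicon = "chr",
                          start = c(100L, 400L), end = c(200L, 500L),
                          strand = c("+", "-"), feature_type = "gene")
  calls <- tibble::tibble(replicon = "chr", strand = "+",
                          position = c(150L, 450L, 300L), end_count = 10L)
  out <- classify_location(calls, genes)
  expect_equal(out$location, c("coding", "coding", "intergenic"))
  expect_equal(out$antisense, c(FALSE, TRUE, FALSE))
})

test_that("UTR length is the transcript-orientation distance from the gene 3' end", {
  genes <- tibble::tibble(gene_id = c("gP", "gM"), replicon = "chr",
                          start = c(500L, 2000L), end = c(1000L, 2600L),
                          strand = c("+", "-"), feature_type = "gene")
  calls <- tibble::tibble(replicon = "chr", strand = c("+", "-", "+"),
                          position = c(1096L, 1903L, 999L),
                          end_count = 10L,
                          upstream_gene = c("gP", "gM", "gP"),
                          rank = "first")
  out <- utr_lengths(calls, genes)
  expect_equal(out$utr_length, c(97L, 97L, 0L))
})

test_that("UTR continuity requires unbroken coverage from gene start to TTS", {
  genes <- tibble::tibble(gene_id = "gP", replicon = "chr", start = 100L,
                          end = 200L, strand = "+", feature_type = "gene")
  calls <- tibble::tibble(replicon = "chr", strand = "+", position = 260L,
                          end_count = 10L, upstream_gene = "gP", rank = "first")
  span <- integer(400); span[101:261] <- 1L
  cov <- make_tracks(integer(400), span)
  expect_true(validate_utr(calls, cov, genes)$utr_continuous)
  span[230] <- 0L                      # a single gap inside the UTR
  cov <- make_tracks(integer(400), span)
  expect_false(validate_utr(calls, cov, genes)$utr_continuous)
})

test_that("rank and location are invariant under coordinate translation", {
  withr::with_seed(5, {
    genes <- tibble::tibble(gene_id = c("g1", "g2"), replicon = "chr",
                            start = c(100L, 700L), end = c(300L, 900L),
                            strand = "+", feature_type = "gene")
    calls <- tibble::tibble(replicon = "chr", strand = "+",
                            position = c(350L, 420L, 950L),
                            end_count = c(9L, 4L, 7L))
    base <- classify_location(rank_tts(calls, genes), genes)
    sh <- 1234L
    shifted <- classify_location(
      rank_tts(dplyr::mutate(calls, position = position + sh),
               dplyr::mutate(genes, start = start + sh, end = end + sh)),
      dplyr::mutate(genes, start = start + sh, end = end + sh))
    expect_equal(base$rank, shifted$rank)
    expect_equal(base$location, shifted$location)
  })
})
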