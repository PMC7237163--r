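small_cfg <- function(...) {
  args <- utils::modifyList(
    list(seed = 31, genome_length = 30000L, n_genes = 8L,
         fragments_per_gene = 150L),
    list(...))
  do.call(sim_config, args)
}

test_that("a fixed seed fully determines genome, truth and SAM bytes", {
  cfg <- small_cfg()
  a <- simulate_genome(cfg)
  b <- simulate_genome(cfg)
  expect_identical(a, b)
  fa <- simulate_fragments(a, cfg)
  fb <- simulate_fragments(b, cfg)
  expect_identical(fa, fb)
  s1 <- withr::local_tempfile(fileext = ".sam")
  s2 <- withr::local_tempfile(fileext = ".sam")
  write_sam(dplyr::filter(fa, replicate == 1), a$replicons, s1)
  write_sam(dplyr::filter(fb, replicate == 1), b$replicons, s2)
  expect_identical(readLines(s1), readLines(s2))
  # different seeds differ
  expect_false(identical(
    simulate_genome(small_cfg())$replicons$sequence,
    simulate_genome(sim_config(seed = 32, genome_length = 30000L,
                               n_genes = 8L))$replicons$sequence))
})

test_that("realized GC content tracks the requested value at 100 kb", {
  cfg <- sim_config(seed = 33, gc_content = 0.65)
  sim <- simulate_genome(cfg)
  bases <- strsplit(sim$replicons$sequence, "")[[1]]
  gc <- mean(bases %in% c("G", "C"))
  expect_lt(abs(gc - 0.65), 0.02)
})

test_that("truth structure matches the construction", {
  cfg <- small_cfg()
  sim <- simulate_genome(cfg)
  expect_equal(nrow(sim$truth), 2L * cfg$n_genes)
  expect_equal(sum(sim$truth$rank == "first"), cfg$n_genes)
  expect_equal(sum(sim$truth$rank == "secondary"), cfg$n_genes)
  # every truth TTS lies downstream of its gene in transcript orientation
  g3 <- gene_end3(sim$genes)
  joined <- dplyr::left_join(sim$truth, g3[c("gene_id", "end3", "strand")],
                             by = c("gene_id", "strand"))
  expect_true(all(downstream_distance(joined$end3, joined$position,
                                      joined$strand) > 0))
  # genes never overlap
  g <- sim$genes[order(sim$genes$start), ]
  expect_true(all(g$start[-1] >= head(g$end, -1)))
})

test_that("the T5C motif is planted at every TTS", {
  cfg <- small_cfg(motif = "T5C")
  sim <- simulate_genome(cfg)
  win <- export_motif_windows(sim$truth, sim$replicons, up = 5, down = 0)
  expect_true(all(win$sequence == "TTTTTC"))
})

test_that("the noise-free limit reproduces truth positions exactly", {
  cfg <- small_cfg(tts_per_gene = 1L, usage = 1.0, spurious_end_rate = 0,
                   duplicate_rate = 0)
  sim <- simulate_genome(cfg)
  fr <- simulate_fragments(sim, cfg)
  expect_true(all(fr$end3 %in% sim$truth$position))
})

test_that("end counts at two TTS follow the 0.7/0.3 usage split", {
  cfg <- small_cfg(spurious_end_rate = 0, duplicate_rate = 0,
                   fragments_per_gene = 500L)
  sim <- simulate_genome(cfg)
  fr <- dplyr::filter(simulate_fragments(sim, cfg), replicate == 1)
  for (gid in unique(sim$truth$gene_id)) {
    tr <- sim$truth[sim$truth$gene_id == gid, ]
    n1 <- sum(fr$end3 == tr$position[tr$rank == "first"])
    # binomial 3-sigma band around 0.7 * 500
    expect_lt(abs(n1 - 0.7 * 500), 3 * sqrt(500 * 0.7 * 0.3) + 1)
  }
})

test_that("PCR duplicates shrink distinct identities but not enrichment at true TTS", {
  cfg0 <- small_cfg(duplicate_rate = 0, spurious_end_rate = 0,
                    fragments_per_gene = 400L)
  cfg5 <- small_cfg(duplicate_rate = 0.5, spurious_end_rate = 0,
                    fragments_per_gene = 400L)
  sim <- simulate_genome(cfg0)     # same genome/truth (duplicate_rate unused)
  frac_distinct <- function(cfg) {
    fr <- dplyr::filter(simulate_fragments(sim, cfg), replicate == 1)
    nrow(dplyr::distinct(fr, strand, end3, start5)) / nrow(fr)
  }
  f0 <- frac_distinct(cfg0)
  f5 <- frac_distinct(cfg5)
  # duplication overwrites about half the draws, so distinct identities drop,
  # though less than twofold because independent draws also collide by chance
  expect_lt(f5, f0 * 0.95)
  expect_gt(f5, f0 * 0.5)
  # duplicates share starts as well as ends: scores at true TTS stay enriched
  fr5 <- dplyr::filter(simulate_fragments(sim, cfg5), replicate == 1)
  sc <- ie_scores(fr5)
  at_truth <- sc[sc$position %in% sim$truth$position, ]
  expect_true(all(at_truth$score > 2))
})

test_that("recovery metrics behave at the documented edges", {
  truth <- tibble::tibble(replicon = "chr", strand = "+",
                          position = c(100L, 200L, 300L),
                          usage = c(0.7, 0.3, 0.7), motif = "none")
  called <- tibble::tibble(replicon = "chr", strand = "+",
                           position = c(100L, 200L, 300L))
  ev <- evaluate_recovery(called, truth)
  expect_equal(ev$recall, 1)
  expect_equal(ev$precision, 1)
  expect_equal(ev$median_error, 0)

  ev0 <- evaluate_recovery(called[0, ], truth)
  expect_equal(ev0$recall, 0)
  expect_equal(ev0$precision, 1)
  expect_false(ev0$precision_defined)

  shifted <- dplyr::mutate(called, position = position + 3L)
  ev3 <- evaluate_recovery(shifted, truth, tol = 5)
  expect_equal(ev3$recall, 1)
  expect_equal(ev3$median_error, 3)
  expect_equal(evaluate_recovery(shifted, truth, tol = 2)$recall, 0)

  by_usage <- evaluate_recovery(called, truth, by = "usage")
  expect_equal(nrow(by_usage), 3)            # overall + two usage strata
})
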