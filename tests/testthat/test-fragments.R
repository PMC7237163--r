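# helper: write a SAM file from explicit records
write_test_sam <- function(records, path, sq = "chr\tLN:200") {
  writeLines(c("@HD\tVN:1.6\tSO:coordinate",
               paste0("@SQ\tSN:", sq)), path)
  cat(records, file = path, sep = "\n", append = TRUE)
}

test_that("mate pairs resolve to fragments under both library geometries", {
  sam <- withr::local_tempfile(fileext = ".sam")
  # mate1 on minus covering [80,100) (POS 81, 20M), mate2 on plus [10,30)
  rec <- c(
    paste("p1", 163, "chr", 11, 60, "20M", "=", 81, 90, strrep("A", 20),
          strrep("I", 20), sep = "\t"),
    paste("p1", 83, "chr", 81, 60, "20M", "=", 11, -90, strrep("A", 20),
          strrep("I", 20), sep = "\t")
  )
  write_test_sam(rec, sam)

  fr <- read_fragments(sam, geometry = "reverse")
  expect_equal(fr$strand, "+")
  expect_equal(fr$end3, 99L)
  expect_equal(fr$start5, 10L)
  expect_equal(fr$length, 90L)

  fr <- read_fragments(sam, geometry = "forward")
  expect_equal(fr$strand, "-")
  expect_equal(fr$end3, 10L)
  expect_equal(fr$start5, 99L)
})

test_that("same-strand mate pairs are skipped and counted, not an error", {
  sam <- withr::local_tempfile(fileext = ".sam")
  rec <- c(
    paste("p1", 65, "chr", 11, 60, "20M", "=", 81, 90, strrep("A", 20),
          strrep("I", 20), sep = "\t"),
    paste("p1", 129, "chr", 81, 60, "20M", "=", 11, -90, strrep("A", 20),
          strrep("I", 20), sep = "\t")
  )
  write_test_sam(rec, sam)
  fr <- read_fragments(sam)
  expect_equal(nrow(fr), 0)
  expect_equal(unname(attr(fr, "counters")["discordant_skipped"]), 1L)
})

test_that("fully overlapping mates give a fragment shorter than one read", {
  sam <- withr::local_tempfile(fileext = ".sam")
  rec <- c(
    paste("p1", 163, "chr", 51, 60, "10M", "=", 51, 10, strrep("A", 10),
          strrep("I", 10), sep = "\t"),
    paste("p1", 83, "chr", 51, 60, "10M", "=", 51, -10, strrep("A", 10),
          strrep("I", 10), sep = "\t")
  )
  write_test_sam(rec, sam)
  fr <- read_fragments(sam, geometry = "reverse")
  expect_equal(fr$length, 10L)
  expect_equal(fr$end3, 59L)
  expect_equal(fr$start5, 50L)
})

test_that("fragment length filter is inclusive at the cap", {
  fr <- dplyr::bind_rows(
    frag_row(149, 100),   # length 50
    frag_row(199, 100),   # length 100
    frag_row(200, 100)    # length 101
  )
  kept <- filter_fragments(fr, max_len = 100)
  expect_equal(sort(kept$length), c(50L, 100L))
  expect_equal(attr(kept, "n_removed"), 1L)
  expect_equal(nrow(filter_fragments(fr, max_len = Inf)), 3)

  withr::with_seed(42, {
    rnd <- random_fragment_set(300)
    expect_equal(nrow(filter_fragments(rnd, 30)), sum(rnd$length <= 30))
  })
})

test_that("count tracks match hand counts and conserve fragment totals", {
  fr <- dplyr::bind_rows(frag_row(50, 10), frag_row(50, 20, n = 2))
  repl <- tibble::tibble(id = "chr", length = 100L, sequence = NA_character_)
  tr <- build_tracks(fr, repl)
  slot <- tr$tracks[["chr|+"]]
  expect_equal(slot$end[51], 3L)
  expect_equal(slot$start[11], 1L)
  expect_equal(slot$start[21], 2L)
  expect_equal(sum(slot$end), sum(slot$start))
  # span covers the closed insert interval
  expect_equal(slot$span[11], 1L)  # position 10: one fragment
  expect_equal(slot$span[25], 3L)  # position 24: all three
  expect_equal(slot$span[51], 3L)
  expect_equal(slot$span[52], 0L)
  expect_true(all(slot$span >= slot$end))

  empty <- build_tracks(fr[0, ], repl)
  expect_true(all(empty$tracks[["chr|+"]]$end == 0))
})

test_that("tidy() and bedGraph export agree with the underlying tracks", {
  fr <- dplyr::bind_rows(frag_row(50, 10), frag_row(50, 20, n = 2),
                         frag_row(30, 60, strand = "-"))
  repl <- tibble::tibble(id = "chr", length = 100L, sequence = NA_character_)
  tr <- build_tracks(fr, repl)
  td <- tidy(tr)
  expect_equal(td$end_count[td$strand == "+" & td$position == 50], 3L)
  expect_equal(td$end_count[td$strand == "-" & td$position == 30], 1L)

  prefix <- file.path(withr::local_tempdir(), "t")
  write_bedgraph(tr, prefix)
  bg <- readr::read_tsv(paste0(prefix, ".end.plus.bedgraph"),
                        col_names = c("chrom", "start", "end", "value"),
                        show_col_types = FALSE)
  expect_equal(bg$value[bg$start <= 50 & bg$end > 50], 3)
})

test_that("simulator SAM output round-trips to the identical fragment set", {
  cfg <- sim_config(seed = 11, genome_length = 30000L, n_genes = 8L,
                    fragments_per_gene = 100L)
  sim <- simulate_genome(cfg)
  fr <- dplyr::filter(simulate_fragments(sim, cfg), replicate == 1)
  for (geom in c("reverse", "forward")) {
    sam <- withr::local_tempfile(fileext = ".sam")
    write_sam(fr, sim$replicons, sam, geometry = geom)
    back <- read_fragments(sam, geometry = geom)
    srt <- function(d) dplyr::arrange(
      tibble::tibble(replicon = d$replicon, strand = d$strand,
                     end3 = d$end3, start5 = d$start5),
      replicon, strand, end3, start5)
    expect_equal(srt(back), srt(fr))
  }
})
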