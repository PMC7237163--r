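# Seeded simulator of 3'-end-preserving mate-pair libraries.
#
# The library model: each transcript copy terminates at one of its gene's
# implanted TTS (chosen by usage fraction); 3'-adapter ligation fixes the
# fragment 3' edge at that terminus while first-strand cDNA fragmentation
# places the 5' break point at a random distance upstream. Natural 3' ends
# therefore recur across fragments while break points scatter — exactly the
# asymmetry internal enrichment exploits. Degradation noise (spurious
# uniform 3' ends) and PCR duplicates (identical re-emitted fragments) are
# the two noise channels.

#' Simulation configuration
#'
#' Defaults describe a desk-scale archaeal-like study: a 100-kb GC-rich
#' (0.65) replicon carrying 40 non-overlapping genes, two TTS per gene used
#' at 0.7/0.3, first-TTS 3' UTR lengths log-normal with median 100 nt,
#' 500 fragments per gene and replicate, three replicates, fragment lengths
#' geometric with mean ~60 nt truncated at 100 nt, 75-nt reads, 2% spurious
#' ends and 10% PCR duplicates.
#'
#' @param seed Integer seed; fully determines all outputs.
#' @param genome_length,gc_content,n_genes Genome scale parameters.
#' @param tts_per_gene Number of TTS implanted downstream of every gene.
#' @param usage Per-TTS usage fractions (first TTS first; must sum to <= 1,
#'   any remainder is read-through past the last TTS).
#' @param utr_meanlog,utr_sdlog Log-normal parameters of the first-TTS UTR
#'   length (defaults give median 100 nt); draws are clamped to
#'   `[10, 400]` nt.
#' @param tts_spacing_range Range (nt) of the spacing between consecutive
#'   TTS of one gene.
#' @param gene_length_range Range (nt) of gene lengths.
#' @param fragments_per_gene Fragments simulated per gene and replicate.
#' @param frag_len_mean,max_frag_len Geometric fragment-length mean and
#'   truncation cap (nt).
#' @param spurious_end_rate Probability that a fragment's 3' end is replaced
#'   by a uniform random position (degradation noise).
#' @param duplicate_rate Probability that a fragment is replaced by a copy of
#'   the previously emitted one (PCR duplicate).
#' @param n_replicates Number of replicate libraries.
#' @param read_length Read length (nt) used when writing SAM.
#' @param geometry Library geometry used when writing SAM (see
#'   [read_fragments()]).
#' @param motif Terminator motif planted at every TTS: `"T5C"` (TTTTT
#'   immediately upstream, C at the TTS), `"AGATC"` (motif immediately
#'   downstream) or `"none"`.
#' @param background_rate Fraction of extra uniform background fragments
#'   (0 disables).
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       genome_length = 100000L,
                       gc_content = 0.65,
                       n_genes = 40L,
                       tts_per_gene = 2L,
                       usage = c(0.7, 0.3),
                       utr_meanlog = log(100),
                       utr_sdlog = 0.35,
                       tts_spacing_range = c(30L, 120L),
                       gene_length_range = c(300L, 900L),
                       fragments_per_gene = 500L,
                       frag_len_mean = 60,
                       max_frag_len = 100L,
                       spurious_end_rate = 0.02,
                       duplicate_rate = 0.10,
                       n_replicates = 3L,
                       read_length = 75L,
                       geometry = "reverse",
                       motif = c("T5C", "AGATC", "none"),
                       background_rate = 0) {
  motif <- match.arg(motif)
  stopifnot(length(usage) == tts_per_gene, sum(usage) <= 1 + 1e-9,
            all(usage >= 0), gc_content > 0, gc_content < 1,
            spurious_end_rate >= 0, spurious_end_rate <= 1,
            duplicate_rate >= 0, duplicate_rate <= 1)
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate a genome, annotation and ground-truth TTS set
#'
#' The replicon is partitioned into one slot per gene; each slot receives a
#' gene on a random strand with its TTS chain implanted downstream in
#' transcript orientation, leaving enough intergenic room that genes never
#' overlap and TTS stay inside the slot. The requested terminator motif is
#' written into the sequence at every TTS.
#'
#' @param config A [sim_config()].
#' @return A list with `replicons` (single replicon `"sim"` with sequence),
#'   `genes` (annotation tibble) and `truth` (one row per implanted TTS:
#'   `replicon`, `strand`, `position`, `gene_id`, `usage`, `rank`, `motif`).
#' @export
simulate_genome <- function(config) {
  withr::with_seed(config$seed, simulate_genome_impl(config))
}

#' @noRd
simulate_genome_impl <- function(config) {
  L <- config$genome_length
  gc <- config$gc_content
  base <- sample(c("A", "T", "G", "C"), L, replace = TRUE,
                 prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2))
  w <- L %/% config$n_genes
  margin_up <- 150L
  down_room <- 400L + config$tts_per_gene * max(config$tts_spacing_range) + 50L
  if (w < margin_up + max(config$gene_length_range) + down_room) {
    stop("genes cannot be placed without overlap; increase genome_length ",
         "or reduce n_genes/gene_length_range", call. = FALSE)
  }
  genes <- list(); truth <- list()
  for (g in seq_len(config$n_genes)) {
    a <- (g - 1L) * w
    glen <- sample(seq(config$gene_length_range[1], config$gene_length_range[2]), 1)
    strand <- sample(c("+", "-"), 1)
    utr1 <- as.integer(pmin(400, pmax(10, round(
      rlnorm(1, config$utr_meanlog, config$utr_sdlog)))))
    spacing <- sample(seq(config$tts_spacing_range[1],
                          config$tts_spacing_range[2]),
                      max(0L, config$tts_per_gene - 1L), replace = TRUE)
    offs <- utr1 + c(0L, cumsum(spacing))[seq_len(config$tts_per_gene)]
    if (strand == "+") {
      start <- a + margin_up; end <- start + glen
      end3 <- end - 1L
      tts_pos <- end3 + offs
    } else {
      end <- a + w - margin_up; start <- end - glen
      end3 <- start
      tts_pos <- end3 - offs
    }
    gid <- sprintf("gene%03d", g)
    genes[[g]] <- tibble::tibble(
      gene_id = gid, replicon = "sim", start = as.integer(start),
      end = as.integer(end), strand = strand, feature_type = "gene")
    truth[[g]] <- tibble::tibble(
      replicon = "sim", strand = strand, position = as.integer(tts_pos),
      gene_id = gid, usage = config$usage,
      rank = c("first", rep("secondary", config$tts_per_gene - 1L)),
      motif = config$motif)
  }
  truth <- dplyr::bind_rows(truth)
  base <- plant_motifs(base, truth, config$motif)
  replicons <- tibble::tibble(id = "sim", length = L,
                              sequence = paste(base, collapse = ""))
  list(replicons = replicons, genes = dplyr::bind_rows(genes), truth = truth)
}

#' @noRd
plant_motifs <- function(base, truth, motif) {
  if (motif == "none") return(base)
  for (k in seq_len(nrow(truth))) {
    p <- truth$position[k]; d <- strand_dir(truth$strand[k])
    if (motif == "T5C") {
      up <- p - d * (5:1)          # transcript offsets -5..-1
      tx <- c(rep("T", 5), "C"); gpos <- c(up, p)
    } else {                       # AGATC immediately downstream
      gpos <- p + d * (1:5)
      tx <- c("A", "G", "A", "T", "C")
    }
    if (truth$strand[k] == "-") tx <- chartr("ACGT", "TGCA", tx)
    ok <- gpos >= 0 & gpos < length(base)
    base[gpos[ok] + 1L] <- tx[ok]
  }
  base
}

#' Simulate mate-pair fragments for all replicates
#'
#' For every gene and replicate, `fragments_per_gene` transcript copies are
#' drawn: the 3' end comes from the gene's TTS by usage fraction (a usage
#' shortfall becomes read-through ending at a far downstream position), the
#' 5' break point at a truncated-geometric distance upstream. Spurious ends
#' and PCR duplicates are applied per fragment.
#'
#' @param sim Output of [simulate_genome()].
#' @param config The same [sim_config()].
#' @return A fragment tibble covering all replicates (columns as in
#'   [read_fragments()]).
#' @export
simulate_fragments <- function(sim, config) {
  purrr::map_dfr(seq_len(config$n_replicates), function(r) {
    rep_seed <- (config$seed * 1009L + r * 7919L) %% .Machine$integer.max
    withr::with_seed(rep_seed, simulate_one_replicate(sim, config, r))
  })
}

#' @noRd
rtrunc_geom <- function(n, mean_len, cap) {
  p <- 1 / mean_len
  u <- runif(n) * stats::pgeom(cap - 1L, p)
  1L + stats::qgeom(u, p)
}

#' @noRd
simulate_one_replicate <- function(sim, config, replicate) {
  L <- sim$replicons$length[1]
  rows <- purrr::map(unique(sim$truth$gene_id), function(gid) {
    tr <- sim$truth[sim$truth$gene_id == gid, ]
    n <- config$fragments_per_gene
    d <- strand_dir(tr$strand[1])
    readthrough <- max(0, 1 - sum(tr$usage))
    idx <- sample.int(nrow(tr) + 1L, n, replace = TRUE,
                      prob = c(tr$usage, readthrough))
    end3 <- ifelse(idx <= nrow(tr), tr$position[idx],
                   tr$position[nrow(tr)] + d * sample(150:400, n, replace = TRUE))
    spurious <- runif(n) < config$spurious_end_rate
    end3[spurious] <- sample.int(L, sum(spurious), replace = TRUE) - 1L
    len <- rtrunc_geom(n, config$frag_len_mean, config$max_frag_len)
    start5 <- pmin(pmax(end3 - d * (len - 1L), 0L), L - 1L)
    df <- tibble::tibble(replicon = "sim", strand = tr$strand[1],
                         end3 = as.integer(end3), start5 = as.integer(start5))
    dup <- which(runif(n) < config$duplicate_rate & seq_len(n) > 1L)
    for (i in dup) df[i, ] <- df[i - 1L, ]
    df
  })
  out <- dplyr::bind_rows(rows)
  if (config$background_rate > 0) {
    nb <- round(config$background_rate * nrow(out))
    if (nb > 0) {
      d <- sample(c(1L, -1L), nb, replace = TRUE)
      e <- sample.int(L, nb, replace = TRUE) - 1L
      len <- rtrunc_geom(nb, config$frag_len_mean, config$max_frag_len)
      out <- dplyr::bind_rows(out, tibble::tibble(
        replicon = "sim", strand = ifelse(d > 0, "+", "-"),
        end3 = as.integer(e), start5 = as.integer(pmin(pmax(e - d * (len - 1L), 0L), L - 1L))))
    }
  }
  out$length <- abs(out$end3 - out$start5) + 1L
  out$replicate <- as.integer(replicate)
  dplyr::arrange(out, .data$replicon, .data$strand, .data$end3, .data$start5)
}

#' Write fragments as a SAM mate-pair file
#'
#' Emits one proper mate pair per fragment under the given library geometry,
#' with fixed read length (clipped to the fragment length), real sequences
#' taken from the genome, MAPQ 60 and coordinate-sorted records — the inverse
#' of [read_fragments()].
#'
#' @param fragments Fragment tibble (single replicate).
#' @param replicons Replicon tibble (sequences used for SEQ fields; N's if
#'   absent).
#' @param path Output SAM path.
#' @param geometry Library geometry (see [read_fragments()]).
#' @param read_length Read length in nt.
#' @return `path`, invisibly.
#' @export
write_sam <- function(fragments, replicons, path, geometry = c("reverse", "forward"),
                      read_length = 75L) {
  geometry <- match.arg(geometry)
  seqs <- setNames(replicons$sequence, replicons$id)
  n <- nrow(fragments)
  rl <- pmin(read_length, fragments$length)
  s <- fragments$strand
  e <- fragments$end3; st <- fragments$start5
  # mate A maps antisense to the transcript with its 5' edge at the RNA 3' end
  a_lo <- ifelse(s == "+", e - rl + 1L, e)
  a_strand <- other_strand(s)
  b_lo <- ifelse(s == "+", st, st - rl + 1L)
  b_strand <- s
  if (geometry == "reverse") {
    p1_lo <- a_lo; p1_s <- a_strand; p2_lo <- b_lo; p2_s <- b_strand
  } else {
    p1_lo <- b_lo; p1_s <- b_strand; p2_lo <- a_lo; p2_s <- a_strand
  }
  flag <- function(is_first, self_s, mate_s) {
    1L + 2L + ifelse(is_first, 64L, 128L) +
      ifelse(self_s == "-", 16L, 0L) + ifelse(mate_s == "-", 32L, 0L)
  }
  seq_of <- function(repl, lo, len, strand) {
    out <- character(length(lo))
    for (id in unique(repl)) {
      sel <- repl == id
      full <- seqs[[id]]
      if (is.null(full) || is.na(full)) {
        out[sel] <- strrep("N", len[sel])
      } else {
        out[sel] <- substring(full, lo[sel] + 1L, lo[sel] + len[sel])
      }
    }
    rc <- strand == "-" & out != ""
    out[rc] <- revcomp_chr(out[rc])
    out
  }
  qname <- sprintf("f%07d", seq_len(n))
  span <- fragments$length
  lo_all <- pmin(p1_lo, p2_lo)
  tlen1 <- ifelse(p1_lo <= p2_lo, span, -span)
  cig <- paste0(rl, "M")
  qual <- strrep("I", rl)
  rec1 <- paste(qname, flag(TRUE, p1_s, p2_s), fragments$replicon, p1_lo + 1L,
                60L, cig, "=", p2_lo + 1L, tlen1,
                seq_of(fragments$replicon, p1_lo, rl, p1_s), qual, sep = "\t")
  rec2 <- paste(qname, flag(FALSE, p2_s, p1_s), fragments$replicon, p2_lo + 1L,
                60L, cig, "=", p1_lo + 1L, -tlen1,
                seq_of(fragments$replicon, p2_lo, rl, p2_s), qual, sep = "\t")
  recs <- c(rec1, rec2)
  ord <- order(rep(fragments$replicon, 2), c(p1_lo, p2_lo), rep(qname, 2))
  header <- c("@HD\tVN:1.6\tSO:coordinate",
              sprintf("@SQ\tSN:%s\tLN:%d", replicons$id, replicons$length))
  writeLines(c(header, recs[ord]), path)
  invisible(path)
}

#' Recovery metrics of called TTS against simulated truth
#'
#' Truth and called sites are matched 1:1, greedily by increasing distance,
#' on the same replicon and strand within `tol` nt. Precision over an empty
#' call set is reported as 1 with `precision_defined = FALSE`.
#'
#' @param called TTS tibble (needs `replicon`, `strand`, `position`).
#' @param truth Truth tibble from [simulate_genome()].
#' @param tol Matching tolerance in nt.
#' @param by Optional truth columns (e.g. `"usage"`, `"motif"`, `"rank"`) to
#'   stratify recall and positional error by.
#' @return A tibble with a row per stratum (`stratum = "all"` first):
#'   `n_truth`, `n_called`, `n_matched`, `recall`, `precision` (overall row
#'   only), `median_error`, `precision_defined`.
#' @export
evaluate_recovery <- function(called, truth, tol = 5, by = NULL) {
  truth$matched <- FALSE
  truth$error <- NA_real_
  called_used <- logical(nrow(called))
  for (key in unique(paste0(truth$replicon, "|", truth$strand))) {
    parts <- strsplit(key, "|", fixed = TRUE)[[1]]
    ti <- which(truth$replicon == parts[1] & truth$strand == parts[2])
    ci <- which(called$replicon == parts[1] & called$strand == parts[2])
    if (!length(ti) || !length(ci)) next
    cand <- expand.grid(i = ti, j = ci)
    cand$dist <- abs(truth$position[cand$i] - called$position[cand$j])
    cand <- cand[cand$dist <= tol, ]
    cand <- cand[order(cand$dist, truth$position[cand$i]), ]
    for (k in seq_len(nrow(cand))) {
      i <- cand$i[k]; j <- cand$j[k]
      if (truth$matched[i] || called_used[j]) next
      truth$matched[i] <- TRUE
      truth$error[i] <- cand$dist[k]
      called_used[j] <- TRUE
    }
  }
  overall <- tibble::tibble(
    stratum = "all",
    n_truth = nrow(truth), n_called = nrow(called),
    n_matched = sum(truth$matched),
    recall = if (nrow(truth)) mean(truth$matched) else NA_real_,
    precision = if (nrow(called)) mean(called_used) else 1,
    median_error = if (any(truth$matched)) median(truth$error[truth$matched]) else NA_real_,
    precision_defined = nrow(called) > 0
  )
  if (is.null(by)) return(overall)
  strata <- dplyr::summarise(
    dplyr::group_by(truth, dplyr::across(dplyr::all_of(by))),
    n_truth = dplyr::n(), n_matched = sum(.data$matched),
    recall = mean(.data$matched),
    median_error = if (any(.data$matched)) median(.data$error[.data$matched]) else NA_real_,
    .groups = "drop"
  )
  strata$stratum <- do.call(paste, c(purrr::map(by, ~ paste0(.x, "=", strata[[.x]])),
                                     list(sep = ",")))
  dplyr::bind_rows(overall, strata[, c("stratum", "n_truth", "n_matched",
                                       "recall", "median_error")])
}
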