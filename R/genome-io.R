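#' Read a genome FASTA into a replicon table
#'
#' Loads every record of a (multi-)FASTA file. Sequences are uppercased and any
#' character outside A/C/G/T is mapped to N. Archaeal and bacterial genomes
#' typically comprise a main chromosome plus plasmid-like replicons; each FASTA
#' record becomes one replicon row.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `id`, `length` (nt) and `sequence`.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">chr", "ACGTacgtNN"), fa)
#' read_genome(fa)
#' @export
read_genome <- function(path) {
  seqs <- Biostrings::readBStringSet(path)
  if (length(seqs) == 0) stop("FASTA file contains no records: ", path, call. = FALSE)
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA record ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  sequence <- toupper(as.character(seqs))
  sequence <- gsub("[^ACGT]", "N", sequence)
  tibble::tibble(id = ids, length = unname(nchar(sequence)),
                 sequence = unname(sequence))
}

#' Write a replicon table as FASTA
#'
#' @param replicons A tibble as returned by [read_genome()].
#' @param path Output path.
#' @return `replicons`, invisibly.
#' @export
write_genome <- function(replicons, path) {
  set <- Biostrings::DNAStringSet(setNames(replicons$sequence, replicons$id))
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(replicons)
}

#' Read gene annotation from GFF3 or BED
#'
#' Coordinates are converted to the package-internal 0-based half-open
#' convention (GFF3 is 1-based inclusive; BED already matches). For GFF3 only
#' features whose type is in `feature_types` are kept; BED has no type column
#' and is used as-is.
#'
#' @param path Path to a `.gff`/`.gff3` or `.bed` file (format is detected from
#'   the extension).
#' @param feature_types GFF3 feature types treated as annotated genes.
#' @param replicons Optional replicon table used to validate that every feature
#'   lies on a known replicon within its bounds.
#' @return A tibble with columns `gene_id`, `replicon`, `start`, `end`
#'   (0-based half-open), `strand` and `feature_type`.
#' @export
read_annotation <- function(path, feature_types = c("gene", "CDS", "tRNA", "rRNA"),
                            replicons = NULL) {
  is_bed <- grepl("\\.bed(\\.gz)?$", path, ignore.case = TRUE)
  gr <- rtracklayer::import(path)
  df <- as.data.frame(gr)
  if (is_bed) {
    gene_id <- if ("name" %in% names(df)) as.character(df$name) else
      sprintf("feature_%d", seq_len(nrow(df)))
    feature_type <- rep("region", nrow(df))
  } else {
    df$type <- as.character(df$type)
    keep <- df$type %in% feature_types
    df <- df[keep, , drop = FALSE]
    gene_id <- if ("ID" %in% names(df) && !all(is.na(df$ID))) as.character(df$ID)
      else if ("Name" %in% names(df)) as.character(df$Name)
      else sprintf("feature_%d", seq_len(nrow(df)))
    gene_id[is.na(gene_id)] <- sprintf("feature_%d", which(is.na(gene_id)))
    feature_type <- df$type
  }
  out <- tibble::tibble(
    gene_id = gene_id,
    replicon = as.character(df$seqnames),
    start = as.integer(df$start - 1L),  # rtracklayer yields 1-based inclusive
    end = as.integer(df$end),
    strand = as.character(df$strand),
    feature_type = feature_type
  )
  check_strand(out$strand)
  if (any(out$end <= out$start)) stop("annotation with end <= start after conversion", call. = FALSE)
  if (anyDuplicated(out$gene_id)) stop("gene_id values are not unique", call. = FALSE)
  if (!is.null(replicons)) {
    bad <- setdiff(out$replicon, replicons$id)
    if (length(bad)) stop("annotation references unknown replicons: ",
                          paste(bad, collapse = ", "), call. = FALSE)
    len <- setNames(replicons$length, replicons$id)
    if (any(out$end > len[out$replicon])) {
      stop("annotation extends beyond replicon end", call. = FALSE)
    }
  }
  out
}

#' Write a gene table as GFF3
#'
#' The inverse of [read_annotation()] for GFF3: internal 0-based half-open
#' coordinates are converted back to 1-based inclusive.
#'
#' @param genes Gene tibble (see [read_annotation()]).
#' @param path Output path.
#' @return `genes`, invisibly.
#' @export
write_annotation <- function(genes, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = genes$replicon,
    ranges = IRanges::IRanges(start = genes$start + 1L, end = genes$end),
    strand = genes$strand,
    type = genes$feature_type,
    ID = genes$gene_id
  )
  rtracklayer::export(gr, path, format = "gff3")
  invisible(genes)
}

#' 3' gene end positions
#'
#' The terminal transcribed base of each gene on its own strand: `end - 1` for
#' `+` genes and `start` for `-` genes (0-based).
#'
#' @param genes Gene tibble.
#' @return `genes` with an added integer column `end3`.
#' @export
gene_end3 <- function(genes) {
  dplyr::mutate(genes, end3 = ifelse(.data$strand == "+", .data$end - 1L, .data$start))
}
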