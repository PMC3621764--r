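# Reference-segment and gene-model simulation.

#' Simulate the reference segment and its gene models
#'
#' Generates a random DNA sequence for the configured segment (GC-biased per
#' `gc_fraction`) and a set of non-overlapping gene models. The default gene
#' footprint reproduces the four candidate genes of the reduced region at
#' their published coordinates (so relative gene spans match the published
#' ratios, e.g. 20,461 : 6,173 bp for the first two genes); for other segment
#' geometries the footprint is rescaled proportionally. Every gene gets at
#' least two exons, 5' and 3' UTRs, and a CDS whose total length is divisible
#' by three.
#'
#' @param config A [sim_config()].
#' @return A list of class `fs_reference`: `sequence` (single character
#'   string; offset `i` is genomic position `segment_start + i - 1`),
#'   `genes` (tibble: `gene_id`, `chrom`, `strand`, `tx_start`, `tx_end`),
#'   `features` (tibble: `gene_id`, `chrom`, `strand`, `feature`, `start`,
#'   `end` with features `exon`, `CDS`, `five_prime_UTR`, `three_prime_UTR`),
#'   and `config`.
#' @export
#' @examples
#' ref <- sim_reference(sim_config(seed = 1, segment_length = 50000,
#'                                 causative_position = 20820000))
#' ref$genes
sim_reference <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  gene_tab <- config$genes %||% scale_default_genes(config)
  check_cols(gene_tab, c("gene_id", "start", "end", "strand"), "genes")
  gene_tab <- arrange(gene_tab, .data$start)
  if (any(gene_tab$start < config$segment_start) ||
    any(gene_tab$end > config$segment_end)) {
    abort("segment too short to place the requested genes.")
  }
  if (any(gene_tab$end - gene_tab$start + 1 < 150)) {
    abort("segment too short to place the requested genes (gene span < 150 bp).")
  }
  if (nrow(gene_tab) > 1 &&
    any(gene_tab$start[-1] <= gene_tab$end[-nrow(gene_tab)])) {
    abort("gene models must not overlap.")
  }

  sequence <- with_sim_seed(config$seed + 21L, {
    paste(random_bases(config$segment_length, config$gc_fraction), collapse = "")
  })
  features <- with_sim_seed(config$seed + 22L, {
    purrr::pmap(gene_tab, function(gene_id, start, end, strand, ...) {
      make_gene_structure(gene_id, config$chrom, strand, start, end)
    }) |> bind_rows()
  })
  genes <- features |>
    group_by(.data$gene_id, .data$chrom, .data$strand) |>
    summarise(tx_start = min(.data$start), tx_end = max(.data$end), .groups = "drop") |>
    arrange(.data$tx_start)

  structure(
    list(sequence = sequence, genes = genes, features = features, config = config),
    class = "fs_reference"
  )
}

# Rescale the default four-gene footprint into the configured segment.
scale_default_genes <- function(config) {
  gt <- default_gene_table()
  gt$chrom <- config$chrom
  if (config$segment_start <= min(gt$start) && config$segment_end >= max(gt$end)) {
    return(gt)
  }
  ref_start <- 20800001
  ref_len <- 1200000
  rescale <- function(p) {
    config$segment_start + round((p - ref_start) / ref_len * config$segment_length)
  }
  gt$start <- rescale(gt$start)
  gt$end <- rescale(gt$end)
  gt
}

# Lay out exons/introns/UTRs/CDS inside [tx_start, tx_end].
# Alternating exon/intron blocks with minimum widths; UTRs at the transcript
# ends (strand-aware); CDS trimmed so its total length is divisible by 3.
make_gene_structure <- function(gene_id, chrom, strand, tx_start, tx_end) {
  span <- tx_end - tx_start + 1
  n_exons <- max(2L, min(8L, span %/% 400L))
  min_exon <- 30L
  min_intron <- 30L
  n_blocks <- 2L * n_exons - 1L
  mins <- rep(c(min_exon, min_intron), length.out = n_blocks)
  spare <- span - sum(mins)
  stopifnot(spare >= 0)
  w <- runif(n_blocks)
  extra <- floor(w / sum(w) * spare)
  extra[1L] <- extra[1L] + (spare - sum(extra))
  lens <- mins + extra
  ends <- tx_start - 1 + cumsum(lens)
  starts <- c(tx_start, head(ends, -1) + 1)
  is_exon <- rep(c(TRUE, FALSE), length.out = n_blocks)
  exons <- tibble(start = starts[is_exon], end = ends[is_exon])

  # left/right terminal exon UTR allocations in genomic orientation
  left_len <- exons$end[1] - exons$start[1] + 1
  right_len <- exons$end[n_exons] - exons$start[n_exons] + 1
  u_left <- min(60L, left_len - 6L)
  u_right <- min(120L, right_len - 6L)
  cds_total <- sum(exons$end - exons$start + 1) - u_left - u_right
  u_right <- u_right + cds_total %% 3L # keep CDS length %% 3 == 0
  stopifnot(u_left >= 1L, u_right >= 1L, u_right < right_len)

  cds <- exons
  cds$start[1] <- cds$start[1] + u_left
  cds$end[n_exons] <- cds$end[n_exons] - u_right
  utr_left <- tibble(start = exons$start[1], end = exons$start[1] + u_left - 1)
  utr_right <- tibble(start = exons$end[n_exons] - u_right + 1, end = exons$end[n_exons])

  if (strand == "+") {
    utr5 <- utr_left
    utr3 <- utr_right
  } else {
    utr5 <- utr_right
    utr3 <- utr_left
  }
  bind_rows(
    mutate(exons, feature = "exon"),
    mutate(cds, feature = "CDS"),
    mutate(utr5, feature = "five_prime_UTR"),
    mutate(utr3, feature = "three_prime_UTR")
  ) |>
    mutate(gene_id = gene_id, chrom = chrom, strand = strand) |>
    select("gene_id", "chrom", "strand", "feature", "start", "end")
}

#' @export
print.fs_reference <- function(x, ...) {
  cat(sprintf(
    "<fs_reference> %s:%s-%s (%s bp), %d genes\n",
    x$config$chrom, format(x$config$segment_start, big.mark = ","),
    format(x$config$segment_end, big.mark = ","),
    format(nchar(x$sequence), big.mark = ","), nrow(x$genes)
  ))
  invisible(x)
}

#' Extract subsequence by genomic coordinates
#'
#' @param reference An `fs_reference` (or a bare character string with
#'   `segment_start` taken as 1).
#' @param start,end 1-based inclusive genomic coordinates.
#' @return Character string.
#' @export
reference_subseq <- function(reference, start, end) {
  if (inherits(reference, "fs_reference")) {
    off <- reference$config$segment_start
    seqc <- reference$sequence
  } else {
    off <- 1
    seqc <- reference
  }
  stopifnot(end >= start, start >= off, end - off + 1 <= nchar(seqc))
  substr(seqc, start - off + 1, end - off + 1)
}
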