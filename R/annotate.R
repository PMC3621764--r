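# Gene-feature annotation: assign each variant a feature category against a
# set of gene models, with configurable splice-site and promoter windows.

# intron intervals implied by a gene's exon list
gene_introns <- function(exons) {
  exons <- exons[order(exons$start), , drop = FALSE]
  if (nrow(exons) < 2L) {
    return(tibble(start = numeric(), end = numeric()))
  }
  tibble(
    start = exons$end[-nrow(exons)] + 1,
    end = exons$start[-1] - 1
  )
}

overlaps <- function(qs, qe, ss, se) qs <= se & qe >= ss

# categories a [qs, qe] interval touches within one gene's features
gene_categories <- function(qs, qe, feats, splice_window) {
  by_type <- split(feats, feats$feature)
  hit <- function(d) {
    !is.null(d) && any(overlaps(qs, qe, d$start, d$end))
  }
  introns <- gene_introns(by_type[["exon"]])
  splice <- if (nrow(introns) > 0L && splice_window > 0L) {
    w <- splice_window
    keep <- introns$end - introns$start + 1 >= 1
    tibble(
      start = c(introns$start[keep], pmax(introns$start[keep], introns$end[keep] - w + 1)),
      end = c(pmin(introns$end[keep], introns$start[keep] + w - 1), introns$end[keep])
    )
  } else {
    tibble(start = numeric(), end = numeric())
  }
  cats <- c(
    splice_site = hit(splice),
    exon_cds = hit(by_type[["CDS"]]),
    utr5 = hit(by_type[["five_prime_UTR"]]),
    utr3 = hit(by_type[["three_prime_UTR"]]),
    intron = nrow(introns) > 0L && any(overlaps(qs, qe, introns$start, introns$end))
  )
  names(cats)[cats]
}

CATEGORY_PRECEDENCE <- c("splice_site", "exon_cds", "utr5", "utr3", "intron", "non_genic")

#' Annotate variants with gene-feature categories
#'
#' Locates each variant against a set of gene models and assigns one of
#' `exon_cds`, `utr5`, `utr3`, `splice_site`, `intron` or `non_genic`, with
#' precedence splice_site > exon/UTR > intron > non_genic. Splice sites are
#' the `splice_window` intronic bases adjacent to each exon boundary
#' (default 2, the canonical donor/acceptor dinucleotides). Point variants
#' (SNPs, anchored indels) are located by `pos`; gaps are intervals
#' `[pos, end]` and may touch several categories, all of which are reported
#' in `categories` while `category` keeps the highest-precedence one.
#' Non-genic variants within `promoter_window` bp upstream of a gene's
#' transcription start (strand-aware) are flagged `promoter_proximal`.
#'
#' @param variants Tibble with `chrom`, `pos` (1-based), optionally `end`
#'   (gaps) and `vclass`.
#' @param features Gene-model feature tibble (`gene_id`, `chrom`, `strand`,
#'   `feature` in `exon`/`CDS`/`five_prime_UTR`/`three_prime_UTR`, `start`,
#'   `end`), e.g. from [sim_reference()] or [read_gene_features()].
#' @param splice_window Intronic bases next to each exon boundary treated as
#'   splice site (nt).
#' @param promoter_window Upstream window (bp) for the promoter-proximal
#'   flag.
#' @return `variants` plus `gene_id`, `category`, `categories`
#'   (comma-joined set) and `promoter_proximal`.
#' @export
annotate_variants <- function(variants, features, splice_window = 2,
                              promoter_window = 1000) {
  check_cols(variants, c("chrom", "pos"), "variants")
  check_cols(features, c("gene_id", "chrom", "strand", "feature", "start", "end"),
    "features"
  )
  check_scalar_number(splice_window, "splice_window", min = 0)
  check_scalar_number(promoter_window, "promoter_window", min = 0)
  validate_gene_features(features)

  genes <- split(features, features$gene_id)
  gene_info <- purrr::map(genes, function(f) {
    list(
      chrom = f$chrom[1L], strand = f$strand[1L],
      tx_start = min(f$start), tx_end = max(f$end), feats = f
    )
  })

  qs <- variants$pos
  qe <- if ("end" %in% names(variants)) {
    ifelse(!is.na(variants$end), variants$end, variants$pos)
  } else {
    variants$pos
  }

  ann <- purrr::map(seq_len(nrow(variants)), function(i) {
    best <- list(gene_id = NA_character_, category = "non_genic",
                 categories = "non_genic", promoter = FALSE)
    for (gid in names(gene_info)) {
      g <- gene_info[[gid]]
      if (g$chrom != variants$chrom[i]) next
      if (overlaps(qs[i], qe[i], g$tx_start, g$tx_end)) {
        cats <- gene_categories(qs[i], qe[i], g$feats, splice_window)
        if (length(cats) == 0L) cats <- "intron" # inside gene, between features
        primary <- CATEGORY_PRECEDENCE[CATEGORY_PRECEDENCE %in% cats][1L]
        ranked <- CATEGORY_PRECEDENCE[CATEGORY_PRECEDENCE %in% cats]
        best <- list(
          gene_id = gid, category = primary,
          categories = paste(ranked, collapse = ","), promoter = FALSE
        )
        break # gene models are non-overlapping
      }
      prom <- if (g$strand == "+") {
        c(g$tx_start - promoter_window, g$tx_start - 1)
      } else {
        c(g$tx_end + 1, g$tx_end + promoter_window)
      }
      if (promoter_window > 0 && overlaps(qs[i], qe[i], prom[1L], prom[2L])) {
        best <- list(
          gene_id = gid, category = "non_genic",
          categories = "non_genic", promoter = TRUE
        )
      }
    }
    best
  })

  variants$gene_id <- purrr::map_chr(ann, "gene_id")
  variants$category <- purrr::map_chr(ann, "category")
  variants$categories <- purrr::map_chr(ann, "categories")
  variants$promoter_proximal <- purrr::map_lgl(ann, "promoter")
  variants
}

validate_gene_features <- function(features) {
  by_gene <- split(features, features$gene_id)
  for (gid in names(by_gene)) {
    f <- by_gene[[gid]]
    ex <- f[f$feature == "exon", , drop = FALSE]
    if (nrow(ex) > 0L) {
      ex <- ex[order(ex$start), , drop = FALSE]
      if (nrow(ex) > 1L && any(ex$start[-1] <= ex$end[-nrow(ex)])) {
        abort(sprintf("gene %s has overlapping exons.", gid))
      }
      cds <- f[f$feature == "CDS", , drop = FALSE]
      if (nrow(cds) > 0L) {
        in_exon <- vapply(seq_len(nrow(cds)), function(i) {
          any(cds$start[i] >= ex$start & cds$end[i] <= ex$end)
        }, logical(1))
        if (!all(in_exon)) abort(sprintf("gene %s has CDS outside its exons.", gid))
      }
    }
  }
  invisible(features)
}

#' Cross-tabulate annotation categories (gene x category x class)
#'
#' A report-shaped matrix of variant counts per gene, feature category and
#' variant class, with a non-genic margin row.
#'
#' @param annotated Output of [annotate_variants()] (needs `vclass`).
#' @return Tibble: `gene_id`, `vclass`, one column per category.
#' @export
annotation_grid <- function(annotated) {
  check_cols(annotated, c("gene_id", "category", "vclass"), "annotated")
  annotated |>
    mutate(gene_id = ifelse(is.na(.data$gene_id), "(non-genic)", .data$gene_id)) |>
    dplyr::count(.data$gene_id, .data$vclass, .data$category) |>
    tidyr::pivot_wider(
      names_from = "category", values_from = "n", values_fill = 0L
    ) |>
    arrange(.data$gene_id, .data$vclass)
}
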