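# End-to-end orchestration: simulate -> fine-map -> triage -> annotate ->
# consequence -> miRNA -> in-silico PCR -> report.

#' Run the full pipeline on simulated data
#'
#' Generates every input with the synthetic-data modules, then runs the
#' analysis stages in sequence: per-marker linkage and per-individual
#' interval inference, cohort consensus interval, recombination statistics,
#' the variant elimination cascade restricted to the consensus region,
#' gene-feature annotation and frame +1 consequence calls for the retained
#' variants, a reference-vs-mutant UTR seed-site diff for each gene, and an
#' in-silico PCR evaluation of a scaled translocation event. The whole run
#' is deterministic given `config$seed`.
#'
#' @param config A [sim_config()].
#' @param edge_allowance Passed to [infer_interval()].
#' @param splice_window,promoter_window Passed to [annotate_variants()].
#' @param seed_config A [seed_scan_config()] for the UTR scans.
#' @param n_mirnas,mirna_length Size of the simulated miRNA catalogue.
#' @param output_dir Optional directory; when given, stage artifacts
#'   (FASTA, GFF3, genotype TSV, VCF, BED, JSON report) are written there.
#' @return A list of class `fs_report` with elements `intervals`,
#'   `consensus`, `recomb`, `triage`, `annotated`, `consequences`,
#'   `frameshifts`, `mirna`, `translocation`, `truth`, `config`.
#' @export
run_pipeline <- function(config = sim_config(),
                         edge_allowance = 500001,
                         splice_window = 2, promoter_window = 1000,
                         seed_config = seed_scan_config(),
                         n_mirnas = 20L, mirna_length = 22L,
                         output_dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  founders <- sim_founders(config)
  reference <- sim_reference(config)
  genotypes <- simulate_cohort(config, founders)
  planted <- plant_variants(config, founders, reference)

  # --- fine-mapping
  statuses <- assign_linkage(
    filter(genotypes, .data$class %in% c("mutant", "carrier")),
    founders$markers
  )
  intervals <- infer_interval(statuses, edge_allowance, on_no_linked = "drop")
  consensus <- consensus_interval(intervals, edge_allowance)
  meiosis <- cohort_meiosis(genotypes) |>
    filter(.data$class %in% c("mutant", "carrier"))
  recomb <- recomb_stats(
    sum(meiosis$recombinant), nrow(meiosis),
    (max(founders$markers$pos) - min(founders$markers$pos)) / 1e6
  )

  # --- triage inside the consensus region
  focal <- filter(planted$variants, .data$line_id == "focal")
  controls <- filter(planted$variants, .data$line_id != "focal")
  region <- c(
    consensus$outer_left %||% consensus$inner_left,
    consensus$outer_right %||% consensus$inner_right
  )
  if (is.na(region[1L])) region[1L] <- config$segment_start - 1
  if (is.na(region[2L])) region[2L] <- config$segment_end
  triage <- triage_cascade(focal, controls,
    known = NULL, region = region,
    region_is_hemizygous = TRUE
  )
  retained <- filter(triage$verdicts, .data$status == "retained_unique")

  # --- annotation + consequences (frame +1, as in the headline analysis)
  annotated <- annotate_variants(retained, reference$features,
    splice_window = splice_window, promoter_window = promoter_window
  )
  snps <- filter(annotated, .data$vclass == "snp")
  consequences <- if (nrow(snps) > 0L) {
    call_consequence(snps, reference, frames = "+1")
  } else {
    NULL
  }
  micro <- filter(
    annotated,
    .data$vclass %in% c("micro_insertion", "micro_deletion", "macro_indel")
  )
  frameshifts <- if (nrow(micro) > 0L) {
    frameshift_scan(micro, reference, frame = "+1")
  } else {
    NULL
  }

  # --- UTR seed-site diff per gene
  mirnas <- with_sim_seed(config$seed + 51L, {
    tibble(
      mirna_id = sprintf("sim-miR-%02d", seq_len(n_mirnas)),
      seq = vapply(
        seq_len(n_mirnas),
        function(i) paste(random_bases(mirna_length, 0.5), collapse = ""), ""
      )
    )
  })
  utr3 <- filter(reference$features, .data$feature == "three_prime_UTR")
  mirna_tab <- purrr::pmap(utr3, function(gene_id, chrom, strand, feature, start, end) {
    utr_s <- start
    utr_e <- end
    ref_utr <- reference_subseq(reference, utr_s, utr_e)
    if (strand == "-") ref_utr <- revcomp_dna(ref_utr)
    in_utr <- filter(
      retained, .data$vclass == "snp",
      .data$pos >= .env$utr_s, .data$pos <= .env$utr_e
    )
    alt_utr_fwd <- reference_subseq(reference, utr_s, utr_e)
    for (i in seq_len(nrow(in_utr))) {
      alt_utr_fwd <- apply_variant_to_seq(
        alt_utr_fwd, in_utr$pos[i], in_utr$ref[i], in_utr$alt[i],
        segment_start = utr_s
      )
    }
    alt_utr <- if (strand == "-") revcomp_dna(alt_utr_fwd) else alt_utr_fwd
    d <- diff_sites(ref_utr, alt_utr, mirnas, seed_config)
    tibble(
      gene_id = gene_id,
      n_ref_sites = nrow(d$ref_sites), n_alt_sites = nrow(d$alt_sites),
      n_gained = nrow(d$gained), n_lost = nrow(d$lost),
      n_utr_snps = nrow(in_utr)
    )
  }) |> bind_rows()

  # --- translocation check: junction primers from the rearranged template
  # are absent on the observed (reference) template, controls present
  pcr <- with_sim_seed(config$seed + 52L, {
    event <- rearrangement_event(
      src_start = config$segment_start + round(0.1 * config$segment_length),
      src_end = config$segment_start + round(0.1 * config$segment_length) + 537,
      shift = round(0.2 * config$segment_length)
    )
    local_event <- rearrangement_event(
      event$src_start - config$segment_start + 1,
      event$src_end - config$segment_start + 1,
      event$shift
    )
    rearranged <- apply_rearrangement(reference$sequence, local_event)
    junction <- local_event$src_start + local_event$shift # fragment start on rearranged
    junction_primers <- tibble(
      set_id = "junction_1",
      fwd_seq = substr(rearranged$sequence, junction - 220, junction - 200),
      rev_seq = revcomp_dna(substr(rearranged$sequence, junction + 200, junction + 220)),
      max_product = 1000
    )
    ctrl_start <- round(0.6 * config$segment_length)
    control_primers <- tibble(
      set_id = "control_1",
      fwd_seq = substr(reference$sequence, ctrl_start, ctrl_start + 20),
      rev_seq = revcomp_dna(substr(reference$sequence, ctrl_start + 300, ctrl_start + 320)),
      max_product = 1000
    )
    evaluate_translocation(reference$sequence, local_event,
      junction_primers, control_primers,
      template = "reference"
    )
  })

  report <- structure(
    list(
      intervals = intervals, consensus = consensus, recomb = recomb,
      triage = triage, annotated = annotated, consequences = consequences,
      frameshifts = frameshifts, mirna = mirna_tab, translocation = pcr,
      truth = planted$truth, config = config
    ),
    class = "fs_report"
  )
  if (!is.null(output_dir)) write_report(report, reference, genotypes, planted, output_dir)
  report
}

write_report <- function(report, reference, genotypes, planted, output_dir) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(output_dir, ...)
  write_fasta(setNames(reference$sequence, report$config$chrom), p("reference.fa"))
  write_gene_features(reference$features, p("genes.gff3"))
  write_genotypes_tsv(genotypes, p("genotypes.tsv"))
  write_markers_tsv(sim_founders(report$config)$markers, p("markers.tsv"))
  write_variants_vcf(report$triage$verdicts, p("focal_verdicts.vcf"))
  if (nrow(planted$gaps) > 0L) write_gaps_bed(planted$gaps, p("gaps.bed"))
  readr::write_tsv(report$triage$audit, p("elimination_audit.tsv"))
  summary <- list(
    consensus = as.list(report$consensus),
    recomb = as.list(report$recomb),
    triage_counts = report$triage$counts,
    annotation_grid = annotation_grid(report$annotated),
    mirna = report$mirna,
    translocation = list(
      verdict = report$translocation$verdict,
      detail = report$translocation$detail
    )
  )
  jsonlite::write_json(summary, p("report.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(output_dir)
}

#' @export
print.fs_report <- function(x, ...) {
  cat("<fs_report>\n")
  cat(sprintf(
    "  consensus interval: cr_min %s bp, cr_max %s bp\n",
    format(x$consensus$cr_min, big.mark = ","),
    format(x$consensus$cr_max, big.mark = ",")
  ))
  cat(sprintf(
    "  recombinants: %d / %d meioses (LOD %.1f)\n",
    x$recomb$n_recombinant, x$recomb$n_meioses, x$recomb$lod
  ))
  cat(sprintf(
    "  triage: %d focal variants, %d retained unique\n",
    nrow(x$triage$verdicts),
    sum(x$triage$verdicts$status == "retained_unique")
  ))
  cat(sprintf("  translocation: %s\n", x$translocation$verdict))
  invisible(x)
}
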