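# Variant-elimination cascade: class assignment, hemizygosity filter,
# multi-line uniqueness filter, region filter, and region-level summary
# statistics.

#' Classify variants by size rules
#'
#' Adds/overwrites a `vclass` column: single-base substitutions are `snp`;
#' insertions and deletions of 1-3 nt are `micro_insertion` /
#' `micro_deletion`; indels of 4-27 nt are `macro_indel`; uncaptured
#' intervals (no alt sequence) of at least 4 nt are `gap`. Equal-length
#' multi-base substitutions and indels beyond 27 nt are outside the data
#' model and raise an error.
#'
#' @param variants Tibble with `chrom`, `pos`, `ref`, `alt` (VCF-style
#'   anchored indels) and, for gaps, `end` with `alt = ""` (or `NA`).
#' @return The input with a `vclass` column.
#' @export
#' @examples
#' classify_variants(tibble::tibble(
#'   chrom = "Z", pos = c(10, 20), ref = c("A", "ATT"), alt = c("G", "A")
#' ))
classify_variants <- function(variants) {
  check_cols(variants, c("chrom", "pos", "ref", "alt"), "variants")
  ref <- toupper(variants$ref)
  alt <- toupper(ifelse(is.na(variants$alt), "", variants$alt))
  is_gap <- alt == "" | ref == "."
  gap_len <- if ("end" %in% names(variants)) {
    variants$end - variants$pos + 1
  } else {
    rep(NA_real_, nrow(variants))
  }
  if (any(is_gap & (is.na(gap_len) | gap_len < 4))) {
    abort("gap records need an `end` column giving an interval of >= 4 nt.")
  }
  diff <- nchar(alt) - nchar(ref)
  if (any(!is_gap & diff == 0 & nchar(ref) > 1)) {
    abort("equal-length multi-base substitutions are not supported.")
  }
  if (any(!is_gap & abs(diff) > 27)) {
    abort("indels longer than 27 nt are not supported (use a gap interval).")
  }
  variants$vclass <- case_when(
    is_gap ~ "gap",
    diff == 0 ~ "snp",
    diff >= 1 & diff <= 3 ~ "micro_insertion",
    diff <= -1 & diff >= -3 ~ "micro_deletion",
    TRUE ~ "macro_indel"
  )
  variants
}

variant_key <- function(df) {
  paste(df$chrom, df$pos, toupper(df$ref), toupper(ifelse(is.na(df$alt), "", df$alt)),
    sep = ":"
  )
}

new_verdict <- function(variants, status, reason) {
  variants$status <- status
  variants$reason <- reason
  variants
}

#' Hemizygosity (zygosity) filter
#'
#' In a hemizygous region a truly linked variant cannot be heterozygous, so
#' heterozygous calls are eliminated
#' (`reason = "heterozygous_in_hemizygous_region"`); everything else is
#' retained for the next stage. With `region_is_hemizygous = FALSE` the
#' filter passes everything through.
#'
#' @param variants Tibble with a `zygosity` column
#'   (`hom` / `het` / `hemi`).
#' @param region_is_hemizygous Apply the filter? Default `TRUE`.
#' @return The input plus `status` (`retained_unique` / `eliminated`) and
#'   `reason` columns.
#' @export
zygosity_filter <- function(variants, region_is_hemizygous = TRUE) {
  if (nrow(variants) == 0L) {
    return(new_verdict(variants, character(), character()))
  }
  check_cols(variants, "zygosity", "variants")
  eliminated <- region_is_hemizygous & variants$zygosity == "het"
  new_verdict(
    variants,
    ifelse(eliminated, "eliminated", "retained_unique"),
    ifelse(eliminated, "heterozygous_in_hemizygous_region", NA_character_)
  )
}

#' Multi-line uniqueness filter
#'
#' A focal-line variant is eliminated as shared when an identical record
#' (same chromosome, position, ref and alt) exists in any other line
#' (`reason = "shared_with_line:<id>"`) or in a set of previously reported
#' variants (`reason = "previously_reported"`); otherwise it is retained as
#' unique. Gaps are never eliminated as shared, because the uncaptured
#' interval could still hide line-specific sequence variation; a matched gap
#' is instead flagged `needs_validation`. Duplicate records within the focal
#' line are de-duplicated with a warning.
#'
#' @param focal Focal-line variant tibble (`chrom`, `pos`, `ref`, `alt`,
#'   optionally `vclass`).
#' @param others A tibble with a `line_id` column, or a named list of
#'   per-line tibbles.
#' @param known Optional tibble of previously reported variants.
#' @return `focal` plus `status`, `reason` and `needs_validation` columns.
#' @export
uniqueness_filter <- function(focal, others = NULL, known = NULL) {
  if (nrow(focal) == 0L) {
    out <- new_verdict(focal, character(), character())
    out$needs_validation <- logical()
    return(out)
  }
  check_cols(focal, c("chrom", "pos", "ref", "alt"), "focal")
  if (!"vclass" %in% names(focal)) focal <- classify_variants(focal)
  key <- variant_key(focal)
  if (anyDuplicated(key)) {
    warn(sprintf("%d duplicate focal record(s) de-duplicated.", sum(duplicated(key))))
    focal <- focal[!duplicated(key), , drop = FALSE]
    key <- key[!duplicated(key)]
  }

  if (is.data.frame(others)) {
    check_cols(others, c("line_id", "chrom", "pos", "ref", "alt"), "others")
    other_list <- split(others, others$line_id)
  } else {
    other_list <- others %||% list()
  }
  match_line <- rep(NA_character_, nrow(focal))
  for (line in names(other_list)) {
    hit <- key %in% variant_key(other_list[[line]])
    match_line[is.na(match_line) & hit] <- line
  }
  known_hit <- if (!is.null(known) && nrow(known) > 0L) {
    key %in% variant_key(known)
  } else {
    rep(FALSE, nrow(focal))
  }

  is_gap <- focal$vclass == "gap"
  matched <- !is.na(match_line) | known_hit
  eliminated <- matched & !is_gap
  reason <- case_when(
    eliminated & !is.na(match_line) ~ paste0("shared_with_line:", match_line),
    eliminated & known_hit ~ "previously_reported",
    TRUE ~ NA_character_
  )
  out <- new_verdict(
    focal,
    ifelse(eliminated, "eliminated", "retained_unique"),
    reason
  )
  out$needs_validation <- is_gap & matched
  out
}

#' Region filter
#'
#' Keeps variants whose position lies inside the causative interval under
#' the `(start, end]` convention: a variant exactly at the proximal flanking
#' marker position is outside, one exactly at `end` is inside.
#'
#' @param variants Tibble with `chrom` and `pos`.
#' @param region_start,region_end Interval bounds (bp).
#' @param chrom Optional chromosome of the region; variants on other
#'   chromosomes are eliminated.
#' @return The input plus `status` and `reason` columns
#'   (`reason = "outside_region"` for eliminations).
#' @export
region_filter <- function(variants, region_start, region_end, chrom = NULL) {
  if (nrow(variants) == 0L) {
    return(new_verdict(variants, character(), character()))
  }
  check_cols(variants, c("chrom", "pos"), "variants")
  check_scalar_number(region_start, "region_start")
  check_scalar_number(region_end, "region_end")
  if (region_end < region_start) abort("`region_end` must be >= `region_start`.")
  inside <- variants$pos > region_start & variants$pos <= region_end
  if (!is.null(chrom)) inside <- inside & variants$chrom == chrom
  new_verdict(
    variants,
    ifelse(inside, "retained_unique", "eliminated"),
    ifelse(inside, NA_character_, "outside_region")
  )
}

#' Run the full elimination cascade
#'
#' Applies the zygosity, uniqueness and region filters as independent
#' predicates over the focal-line variants and combines them: a variant is
#' retained only if every stage retains it. Each variant receives exactly one
#' verdict; when several stages would eliminate it the reason follows the
#' cascade order (zygosity, then uniqueness, then region). Because the
#' filters are stateless predicates, applying them in any order yields the
#' same retained set.
#'
#' @inheritParams uniqueness_filter
#' @inheritParams region_filter
#' @param region Optional `c(start, end)` (or an `fs_intervals` row, from
#'   which `outer_left`/`outer_right` are taken) for the region stage; `NULL`
#'   skips it.
#' @param region_is_hemizygous Passed to [zygosity_filter()].
#' @return List of class `fs_triage`: `verdicts` (focal variants with
#'   `status`, `reason`, `needs_validation`), `audit` (per-variant outcome of
#'   every stage), `counts` (per-class retained/eliminated grid).
#' @export
triage_cascade <- function(focal, others = NULL, known = NULL, region = NULL,
                           region_is_hemizygous = TRUE) {
  if (!"vclass" %in% names(focal)) focal <- classify_variants(focal)
  zv <- zygosity_filter(focal, region_is_hemizygous)
  uv <- uniqueness_filter(focal, others, known)
  if (!is.null(region)) {
    if (inherits(region, "fs_intervals") || is.data.frame(region)) {
      region <- c(region$outer_left[1L], region$outer_right[1L])
    }
    rv <- region_filter(focal, region[1L], region[2L])
  } else {
    rv <- new_verdict(focal, "retained_unique", NA_character_)
  }
  stopifnot(nrow(zv) == nrow(uv), nrow(uv) == nrow(rv))

  reason <- dplyr::coalesce(zv$reason, uv$reason, rv$reason)
  status <- ifelse(is.na(reason), "retained_unique", "eliminated")
  verdicts <- focal
  verdicts$status <- status
  verdicts$reason <- reason
  verdicts$needs_validation <- uv$needs_validation

  audit <- tibble(
    key = variant_key(focal),
    vclass = focal$vclass,
    zygosity_stage = zv$status,
    uniqueness_stage = uv$status,
    region_stage = rv$status,
    status = status,
    reason = reason
  )
  counts <- verdicts |>
    dplyr::count(.data$vclass, .data$status) |>
    tidyr::pivot_wider(
      names_from = "status", values_from = "n",
      values_fill = 0L
    )
  structure(list(verdicts = verdicts, audit = audit, counts = counts),
    class = "fs_triage"
  )
}

#' @export
print.fs_triage <- function(x, ...) {
  cat("<fs_triage> ", nrow(x$verdicts), " variants, ",
    sum(x$verdicts$status == "retained_unique"), " retained\n",
    sep = ""
  )
  print(x$counts)
  invisible(x)
}

mean_or_na <- function(x) if (length(x) == 0L) NA_real_ else mean(x)

#' Region-level variant summary statistics
#'
#' Transition/transversion counts and ratio over biallelic SNPs
#' (transitions are A<->G and C<->T), per-kb densities of SNPs and
#' micro-indels over the supplied region span, micro-indel size and spacing
#' means, and gap count/size/spacing statistics. Spacing is the mean distance
#' between consecutive same-class variants ordered by position, undefined
#' (NA, with a flag) for fewer than two variants; the Ts/Tv ratio is
#' undefined when there are no transversions. Values are kept at full
#' precision; round only in a report layer.
#'
#' @param variants Tibble with `pos`, `ref`, `alt` and (or classifiable
#'   into) `vclass`; gaps need `end`.
#' @param region_span_bp Span of the surveyed region in bp (> 0).
#' @return A one-row tibble of class `variant_summary`.
#' @export
#' @examples
#' v <- classify_variants(tibble::tibble(
#'   chrom = "Z", pos = c(100, 300), ref = c("A", "C"), alt = c("G", "T")
#' ))
#' summarize_variants(v, 1000)
summarize_variants <- function(variants, region_span_bp) {
  check_scalar_number(region_span_bp, "region_span_bp", min = 1e-9)
  if (!"vclass" %in% names(variants)) variants <- classify_variants(variants)
  kb <- region_span_bp / 1000

  snp <- filter(variants, .data$vclass == "snp")
  pair <- paste0(pmin(toupper(snp$ref), toupper(snp$alt)),
                 pmax(toupper(snp$ref), toupper(snp$alt)))
  ts <- sum(pair %in% c("AG", "CT"))
  tv <- nrow(snp) - ts

  micro <- variants |>
    filter(.data$vclass %in% c("micro_insertion", "micro_deletion")) |>
    arrange(.data$pos)
  micro_sizes <- abs(nchar(micro$alt) - nchar(micro$ref))
  gaps <- variants |>
    filter(.data$vclass == "gap") |>
    arrange(.data$pos)
  gap_sizes <- if ("end" %in% names(gaps)) gaps$end - gaps$pos + 1 else numeric()

  out <- tibble(
    n_snp = nrow(snp),
    ts_count = ts, tv_count = tv,
    tstv_ratio = if (tv > 0) ts / tv else NA_real_,
    tstv_undefined = tv == 0 && ts > 0,
    snp_density_per_kb = nrow(snp) / kb,
    n_micro_indel = nrow(micro),
    indel_density_per_kb = nrow(micro) / kb,
    mean_indel_size = mean_or_na(micro_sizes),
    mean_indel_spacing = mean_or_na(diff(micro$pos)),
    indel_spacing_undefined = nrow(micro) < 2L,
    gap_count = nrow(gaps),
    mean_gap_size = mean_or_na(gap_sizes),
    gap_size_min = if (nrow(gaps)) min(gap_sizes) else NA_real_,
    gap_size_max = if (nrow(gaps)) max(gap_sizes) else NA_real_,
    mean_gap_spacing = mean_or_na(diff(gaps$pos)),
    region_span_bp = region_span_bp
  )
  class(out) <- c("variant_summary", class(out))
  out
}
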