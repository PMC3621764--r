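# Interval inference from marker genotypes: per-marker linkage status,
# per-individual minimum/maximum causative region, cohort consensus, and
# recombination statistics.

#' Assign per-marker linkage status
#'
#' Classifies every (individual, marker) call as `linked`, `recombined` or
#' `uninformative` against the founder alleles. Hemizygous mutants are linked
#' where the single call equals the mutant-haplotype allele and recombined
#' where it equals the normal-background allele; heterozygous carriers are
#' linked where the pair is heterozygous and contains the mutant allele, and
#' recombined where it is homozygous normal. Missing calls, loci with
#' identical founder alleles, and normal (non-carrier) individuals are
#' uninformative. A deleted call (`"-"`) in a hemizygote is linked when the
#' mutant haplotype carries a deletion at that locus, otherwise
#' uninformative.
#'
#' @param genotypes Long tibble with columns `individual`, `class`
#'   (`mutant`, `carrier`, `normal`), `marker`, `call`. Calls are allele
#'   strings: single base for hemizygotes, two bases for diploids, `"-"` for
#'   a deleted locus, `NA`/`"."` for missing.
#' @param markers Marker panel tibble: `marker`, `chrom`, `pos`,
#'   `normal_allele`, `mutant_allele`, optional `mutant_is_deletion`.
#' @return Tibble: `individual`, `class`, `marker`, `chrom`, `pos`, `status`,
#'   sorted by individual then position. Class `fs_linkage`.
#' @export
#' @examples
#' mk <- tibble::tibble(marker = c("m1", "m2"), chrom = "Z", pos = c(100, 200),
#'                      normal_allele = c("A", "G"), mutant_allele = c("G", "T"))
#' gt <- tibble::tibble(individual = "i1", class = "mutant",
#'                      marker = c("m1", "m2"), call = c("G", "G"))
#' assign_linkage(gt, mk)
assign_linkage <- function(genotypes, markers) {
  check_cols(genotypes, c("individual", "class", "marker", "call"), "genotypes")
  check_cols(markers, c("marker", "chrom", "pos", "normal_allele", "mutant_allele"),
    "markers"
  )
  if (!"mutant_is_deletion" %in% names(markers)) markers$mutant_is_deletion <- FALSE
  if (is.unsorted(markers$pos, strictly = TRUE)) {
    markers <- arrange(markers, .data$pos)
    if (anyDuplicated(markers$pos)) abort("marker positions must be strictly increasing.")
  }

  df <- genotypes |>
    select("individual", "class", "marker", "call") |>
    left_join(markers, by = "marker")
  if (anyNA(df$pos)) {
    abort(sprintf(
      "genotype calls at unknown marker(s): %s",
      paste(unique(df$marker[is.na(df$pos)]), collapse = ", ")
    ))
  }

  call <- toupper(ifelse(is.na(df$call) | df$call %in% c(".", ""), NA, df$call))
  a1 <- substr(call, 1L, 1L)
  a2 <- ifelse(nchar(call) >= 2L, substr(call, 2L, 2L), NA)
  # allele sanity: every called base must belong to the locus allele set
  called <- !is.na(call) & call != "-"
  locus_ok <- function(a) {
    is.na(a) | a == "-" | a == df$normal_allele | a == df$mutant_allele
  }
  bad <- called & (!locus_ok(a1) | !locus_ok(a2))
  if (any(bad)) {
    abort(sprintf(
      "call allele outside locus alphabet at marker(s): %s",
      paste(unique(df$marker[bad]), collapse = ", ")
    ))
  }
  hemi_pair <- df$class == "mutant" & !is.na(call) & nchar(call) > 1L & call != "-"
  if (any(hemi_pair)) {
    abort(sprintf(
      "hemizygous mutant with a two-allele call at marker(s): %s",
      paste(unique(df$marker[hemi_pair]), collapse = ", ")
    ))
  }

  has_mut <- (!is.na(a1) & a1 == df$mutant_allele) |
    (!is.na(a2) & a2 == df$mutant_allele)
  hom_normal <- !is.na(a1) & !is.na(a2) &
    a1 == df$normal_allele & a2 == df$normal_allele
  het <- !is.na(a1) & !is.na(a2) & a1 != a2

  status <- case_when(
    is.na(call) ~ "uninformative",
    df$normal_allele == df$mutant_allele ~ "uninformative",
    df$class == "normal" ~ "uninformative",
    df$class == "mutant" & call == "-" & df$mutant_is_deletion ~ "linked",
    df$class == "mutant" & call == "-" ~ "uninformative",
    df$class == "mutant" & a1 == df$mutant_allele ~ "linked",
    df$class == "mutant" & a1 == df$normal_allele ~ "recombined",
    df$class == "carrier" & het & has_mut ~ "linked",
    df$class == "carrier" & hom_normal ~ "recombined",
    TRUE ~ "uninformative"
  )

  out <- df |>
    mutate(status = status) |>
    select("individual", "class", "marker", "chrom", "pos", "status") |>
    arrange(.data$individual, .data$pos)
  class(out) <- c("fs_linkage", class(out))
  out
}

# Core run-finding on one individual's (pos, status), positions ascending.
# Uninformative markers are transparent; recombined markers break linked runs.
# Without an anchor, the run with most markers wins (ties resolved distally);
# with an anchor, only runs whose flank-bounded open interval contains the
# anchor are eligible.
find_linked_run <- function(pos, status, anchor = NULL) {
  informative <- status != "uninformative"
  p <- pos[informative]
  s <- status[informative]
  if (length(p) == 0L || !any(s == "linked")) {
    return(NULL)
  }
  r <- rle(s == "linked")
  run_end <- cumsum(r$lengths)
  run_start <- run_end - r$lengths + 1L
  linked_runs <- which(r$values)
  if (!is.null(anchor)) {
    lo <- ifelse(run_start[linked_runs] > 1L, p[run_start[linked_runs] - 1L], -Inf)
    hi <- ifelse(run_end[linked_runs] < length(p), p[run_end[linked_runs] + 1L], Inf)
    linked_runs <- linked_runs[lo < anchor & anchor < hi]
    if (length(linked_runs) == 0L) {
      return(NULL)
    }
  }
  lens <- r$lengths[linked_runs]
  best_set <- linked_runs[lens == max(lens)]
  best <- best_set[length(best_set)] # most distal on ties
  i1 <- run_start[best]
  i2 <- run_end[best]
  list(
    inner_left = p[i1], inner_right = p[i2],
    outer_left = if (i1 > 1L) p[i1 - 1L] else NA_real_,
    outer_right = if (i2 < length(p)) p[i2 + 1L] else NA_real_,
    n_linked_runs = sum(r$values)
  )
}

finish_interval <- function(run, chrom, edge_allowance) {
  cr_min <- run$inner_right - run$inner_left
  edge <- is.na(run$outer_left) || is.na(run$outer_right)
  cr_max <- if (edge) cr_min + edge_allowance else run$outer_right - run$outer_left - 2
  tibble(
    chrom = chrom,
    inner_left = run$inner_left, inner_right = run$inner_right,
    outer_left = run$outer_left, outer_right = run$outer_right,
    cr_min = cr_min, cr_max = cr_max,
    edge_allowance_used = edge,
    n_linked_runs = run$n_linked_runs
  )
}

#' Infer per-individual causative intervals
#'
#' For each individual, finds the maximal run of linked markers (uninformative
#' markers are transparent; with several runs the one containing the most
#' markers wins, ties resolved toward the most distal run and flagged via
#' `n_linked_runs`). The minimum causative region spans the outermost linked
#' markers, `cr_min = inner_right - inner_left`. The maximum region is bounded
#' by the nearest flanking recombined markers,
#' `cr_max = outer_right - outer_left - 2`; where a flank is absent at the
#' panel edge, `cr_max = cr_min + edge_allowance`.
#'
#' @param statuses An `fs_linkage` tibble from [assign_linkage()].
#' @param edge_allowance Padding (bp) applied when a flanking recombined
#'   marker is missing at a panel edge; default 500,001 bp.
#' @param anchor Optional position (bp) the causative element is already
#'   known to lie near (e.g. from prior mapping of the introgressed
#'   segment). When given, only linked runs whose flank-bounded open
#'   interval contains the anchor are considered; individuals with no such
#'   run are treated like individuals with no linked marker.
#' @param on_no_linked `"error"` (default) aborts when an individual has no
#'   (eligible) linked marker; `"drop"` silently skips such individuals.
#' @return Tibble of class `fs_intervals`, one row per individual:
#'   `individual`, `chrom`, `inner_left`, `inner_right`, `outer_left`,
#'   `outer_right`, `cr_min`, `cr_max`, `edge_allowance_used`,
#'   `n_linked_runs`.
#' @export
infer_interval <- function(statuses, edge_allowance = 500001, anchor = NULL,
                           on_no_linked = c("error", "drop")) {
  on_no_linked <- match.arg(on_no_linked)
  check_cols(statuses, c("individual", "chrom", "pos", "status"), "statuses")
  check_scalar_number(edge_allowance, "edge_allowance", min = 0)
  if (!is.null(anchor)) check_scalar_number(anchor, "anchor")
  ids <- factor(statuses$individual, levels = unique(statuses$individual))
  idx <- split(seq_len(nrow(statuses)), ids)
  pos_all <- statuses$pos
  status_all <- statuses$status
  chrom_all <- statuses$chrom
  res <- matrix(NA_real_, nrow = length(idx), ncol = 5L)
  chrom <- character(length(idx))
  for (g in seq_along(idx)) {
    ii <- idx[[g]]
    ord <- order(pos_all[ii])
    run <- find_linked_run(pos_all[ii][ord], status_all[ii][ord], anchor)
    chrom[g] <- chrom_all[ii[1L]]
    if (is.null(run)) {
      if (on_no_linked == "error") {
        abort(sprintf(
          "individual %s has no linked marker%s (not a mutant-haplotype carrier).",
          names(idx)[g], if (is.null(anchor)) "" else " consistent with the anchor"
        ))
      }
    } else {
      res[g, ] <- c(
        run$inner_left, run$inner_right, run$outer_left,
        run$outer_right, run$n_linked_runs
      )
    }
  }
  keep <- !is.na(res[, 1L])
  if (!any(keep)) abort("no individual with a linked marker.")
  cr_min <- res[keep, 2L] - res[keep, 1L]
  edge <- is.na(res[keep, 3L]) | is.na(res[keep, 4L])
  cr_max <- ifelse(edge, cr_min + edge_allowance, res[keep, 4L] - res[keep, 3L] - 2)
  out <- tibble(
    individual = names(idx)[keep],
    chrom = chrom[keep],
    inner_left = res[keep, 1L], inner_right = res[keep, 2L],
    outer_left = res[keep, 3L], outer_right = res[keep, 4L],
    cr_min = cr_min, cr_max = cr_max,
    edge_allowance_used = edge,
    n_linked_runs = as.integer(res[keep, 5L])
  )
  class(out) <- c("fs_intervals", class(out))
  out
}

#' Consensus causative interval across individuals
#'
#' Intersects per-individual intervals: the consensus inner bounds are the
#' outermost markers still linked in every individual (proximal bound is the
#' maximum of the individual proximal bounds, distal bound the minimum of the
#' distal bounds); the consensus outer bounds are the tightest flanking
#' recombined markers observed in any individual. `cr_min`/`cr_max` are
#' recomputed from these bounds under the [infer_interval()] conventions, so
#' the consensus is never wider than any input interval.
#'
#' When recombinants bracket the causative site between adjacent markers on
#' both flanks, no marker remains linked in every individual: the inner
#' bounds are then `NA`, `cr_min = 0`, and `inner_empty = TRUE`, while the
#' outer interval stays valid. An inconsistency error (listing the offending
#' individuals) is raised only when the flank-bounded open intervals have an
#' empty intersection, i.e. no single location is compatible with all
#' individuals.
#'
#' @param intervals An `fs_intervals` tibble (all on one chromosome).
#' @inheritParams infer_interval
#' @return A one-row `fs_intervals` tibble with `individual = "consensus"`,
#'   `n_individuals` and `inner_empty`.
#' @export
consensus_interval <- function(intervals, edge_allowance = 500001) {
  check_cols(
    intervals,
    c("chrom", "inner_left", "inner_right", "outer_left", "outer_right"),
    "intervals"
  )
  if (nrow(intervals) == 0L) abort("cannot take the consensus of zero intervals.")
  if (length(unique(intervals$chrom)) != 1L) {
    abort("all intervals must be on a single chromosome.")
  }
  all_na_min <- function(x) if (all(is.na(x))) NA_real_ else min(x, na.rm = TRUE)
  all_na_max <- function(x) if (all(is.na(x))) NA_real_ else max(x, na.rm = TRUE)
  outer_left <- all_na_max(intervals$outer_left)
  outer_right <- all_na_min(intervals$outer_right)
  # genuinely disjoint evidence: the flank-bounded open intervals have an
  # empty intersection, so no single location is compatible with every
  # individual
  lo <- ifelse(is.na(intervals$outer_left), -Inf, intervals$outer_left)
  hi <- ifelse(is.na(intervals$outer_right), Inf, intervals$outer_right)
  if (max(lo) >= min(hi)) {
    offenders <- unique(c(
      intervals$individual[lo == max(lo)],
      intervals$individual[hi == min(hi)]
    ))
    abort(sprintf(
      "disjoint linked runs; offending individuals: %s",
      paste(offenders, collapse = ", ")
    ))
  }
  inner_left <- max(intervals$inner_left)
  inner_right <- min(intervals$inner_right)
  inner_empty <- inner_right < inner_left
  if (inner_empty) {
    # recombinants bracket the causative site between adjacent markers on
    # both flanks: no marker is linked in every individual, but the outer
    # interval is still well-defined
    edge <- is.na(outer_left) || is.na(outer_right)
    out <- tibble(
      chrom = intervals$chrom[1L],
      inner_left = NA_real_, inner_right = NA_real_,
      outer_left = outer_left, outer_right = outer_right,
      cr_min = 0,
      cr_max = if (edge) edge_allowance else outer_right - outer_left - 2,
      edge_allowance_used = edge, n_linked_runs = 1L
    )
  } else {
    run <- list(
      inner_left = inner_left, inner_right = inner_right,
      outer_left = outer_left, outer_right = outer_right,
      n_linked_runs = 1L
    )
    out <- finish_interval(run, intervals$chrom[1L], edge_allowance)
  }
  out <- out |>
    mutate(
      individual = "consensus", n_individuals = nrow(intervals),
      inner_empty = inner_empty
    ) |>
    select("individual", dplyr::everything())
  class(out) <- c("fs_intervals", class(out))
  out
}

#' Span between two printed coordinates
#'
#' The span convention used for printed coordinate pairs throughout the
#' analysis: `end - start`. See [region_length()] for the inclusive
#' base count, which is one larger.
#'
#' @param start,end Coordinates (bp), `end >= start`. Vectorised.
#' @return Numeric span(s) in bp.
#' @export
#' @examples
#' region_span(20813939, 21804206) # the originally linked region
#' region_span(21628291, 21804206) # the reduced region
region_span <- function(start, end) {
  if (any(end < start)) abort("`end` must be >= `start`.")
  end - start
}

#' Inclusive length of a coordinate interval
#'
#' @inheritParams region_span
#' @return `end - start + 1`.
#' @export
region_length <- function(start, end) {
  region_span(start, end) + 1
}

#' Recombination fraction, rate and two-point LOD score
#'
#' From `n_recombinant` recombinant meioses out of `n_meioses` informative
#' meioses over a tracked region of `region_length_mb` megabases:
#' `theta = R/N`, the per-Mb rates `cm_per_mb = 100 * theta /
#' region_length_mb` and `morgans_per_mb = theta / region_length_mb` (both
#' scalings are reported), and the two-point LOD score
#' `Z = R*log10(theta) + (N-R)*log10(1-theta) - N*log10(0.5)`, equal to
#' `N*log10(2)` when `R = 0`.
#'
#' @param n_recombinant Recombinant count `R` (`0 <= R <= N`).
#' @param n_meioses Informative meioses `N` (> 0).
#' @param region_length_mb Tracked region length in Mb (> 0).
#' @return A one-row tibble of class `recomb_summary`: `n_recombinant`,
#'   `n_meioses`, `theta`, `cm_per_mb`, `morgans_per_mb`, `lod`,
#'   `region_length_mb`.
#' @export
#' @examples
#' recomb_stats(10, 263, 1.004)
recomb_stats <- function(n_recombinant, n_meioses, region_length_mb) {
  check_scalar_number(n_recombinant, "n_recombinant", min = 0)
  check_scalar_number(n_meioses, "n_meioses", min = 1)
  check_scalar_number(region_length_mb, "region_length_mb")
  if (region_length_mb <= 0) abort("`region_length_mb` must be > 0.")
  if (n_recombinant > n_meioses) abort("`n_recombinant` cannot exceed `n_meioses`.")
  theta <- n_recombinant / n_meioses
  if (theta > 0.5) {
    warn("recombination fraction exceeds 0.5; LOD will be negative.")
  }
  lod <- if (n_recombinant == 0) {
    n_meioses * log10(2)
  } else {
    n_recombinant * log10(theta) +
      (n_meioses - n_recombinant) * log10(1 - theta) -
      n_meioses * log10(0.5)
  }
  out <- tibble(
    n_recombinant = n_recombinant, n_meioses = n_meioses, theta = theta,
    cm_per_mb = 100 * theta / region_length_mb,
    morgans_per_mb = theta / region_length_mb,
    lod = lod, region_length_mb = region_length_mb
  )
  class(out) <- c("recomb_summary", class(out))
  out
}
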