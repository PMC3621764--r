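# broom-style tidiers for the package's result objects.

#' Tidy a recombination summary
#'
#' @param x A `recomb_summary` from [recomb_stats()].
#' @param ... Unused.
#' @return A term/estimate tibble.
#' @export
tidy.recomb_summary <- function(x, ...) {
  tibble(
    term = c("theta", "cm_per_mb", "morgans_per_mb", "lod"),
    estimate = c(x$theta, x$cm_per_mb, x$morgans_per_mb, x$lod)
  )
}

#' @rdname tidy.recomb_summary
#' @return `glance()`: the one-row summary tibble.
#' @export
glance.recomb_summary <- function(x, ...) {
  as_tibble(unclass(x)[names(unclass(x))])
}

#' Tidy per-individual causative intervals
#'
#' @param x An `fs_intervals` tibble.
#' @param ... Unused.
#' @return One row per individual with the interval bounds and spans.
#' @export
tidy.fs_intervals <- function(x, ...) {
  as_tibble(as.data.frame(x))
}

#' @rdname tidy.fs_intervals
#' @return `glance()`: consensus-style one-row summary (narrowest bounds,
#'   individual count).
#' @export
glance.fs_intervals <- function(x, ...) {
  tibble(
    n_individuals = nrow(x),
    inner_left = max(x$inner_left), inner_right = min(x$inner_right),
    min_cr_min = min(x$cr_min), min_cr_max = min(x$cr_max)
  )
}

#' Tidy a triage result
#'
#' @param x An `fs_triage` from [triage_cascade()].
#' @param ... Unused.
#' @return The per-variant verdict tibble.
#' @export
tidy.fs_triage <- function(x, ...) {
  as_tibble(x$verdicts)
}

#' @rdname tidy.fs_triage
#' @return `glance()`: one-row cascade summary.
#' @export
glance.fs_triage <- function(x, ...) {
  v <- x$verdicts
  tibble(
    n_input = nrow(v),
    n_retained = sum(v$status == "retained_unique"),
    n_eliminated = sum(v$status == "eliminated"),
    n_het_eliminated = sum(v$reason %in% "heterozygous_in_hemizygous_region"),
    n_shared_eliminated = sum(startsWith(
      ifelse(is.na(v$reason), "", v$reason), "shared_with_line"
    )),
    n_outside_region = sum(v$reason %in% "outside_region"),
    n_needs_validation = sum(v$needs_validation %in% TRUE)
  )
}

#' Tidy a variant summary
#'
#' @param x A `variant_summary` from [summarize_variants()].
#' @param ... Unused.
#' @return A statistic/value tibble.
#' @export
tidy.variant_summary <- function(x, ...) {
  vals <- unclass(x)
  tibble(
    statistic = names(vals),
    value = vapply(vals, as.numeric, numeric(1))
  )
}

#' @rdname tidy.variant_summary
#' @export
glance.variant_summary <- function(x, ...) {
  as_tibble(as.data.frame(unclass(x)))
}
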