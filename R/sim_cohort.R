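# Cohort genotype simulation: one informative meiosis per individual, Poisson
# crossovers (Haldane, no interference), anchored so the transmitted gamete
# carries the mutant haplotype at the causative position.

# n informative gametes over the marker panel. Returns a logical matrix
# (TRUE = marker inherited from the mutant haplotype) and crossover counts.
sim_gametes <- function(n, config, marker_pos) {
  mean_x <- config$recomb_rate * (config$segment_length / 1e6) / 100
  k <- rpois(n, mean_x)
  hap <- matrix(TRUE, nrow = n, ncol = length(marker_pos))
  for (i in which(k > 0L)) {
    x <- sort(runif(k[i], config$segment_start, config$segment_end))
    f_marker <- findInterval(marker_pos, x)
    f_causative <- findInterval(config$causative_position, x)
    hap[i, ] <- ((f_marker - f_causative) %% 2L) == 0L
  }
  list(mutant = hap, n_crossovers = k)
}

#' Simulate cohort genotypes at the marker panel
#'
#' Each individual contributes one informative meiosis from the founder cross.
#' Crossover counts per gamete are Poisson with mean
#' `recomb_rate * segment_length_Mb / 100` (no interference); crossover
#' positions are uniform on the segment. Gametes are anchored at the causative
#' position, so every mutant and carrier carries the mutant haplotype there.
#' Hemizygous mutants carry a single allele per marker (the deletion state
#' `"-"` where the mutant haplotype deletes a locus), carriers carry the
#' gamete allele plus a normal-background allele, and normals are homozygous
#' background.
#'
#' @param config A [sim_config()].
#' @param founders A [sim_founders()] result consistent with `config`.
#' @return A tibble of class `fs_genotypes` in long form: `individual`,
#'   `class` (`mutant`/`carrier`/`normal`), `marker`, `chrom`, `pos`, `call`
#'   (e.g. `"A"`, `"AG"`, `"-"`, `NA`). Attribute `meiosis` is a tibble with
#'   per-individual crossover counts and a `recombinant` flag (any crossover
#'   on the transmitted gamete).
#' @export
#' @examples
#' cfg <- sim_config(seed = 1, cohort_sizes = c(mutant = 5, carrier = 2, normal = 1))
#' geno <- simulate_cohort(cfg, sim_founders(cfg))
#' dplyr::count(geno, class)
simulate_cohort <- function(config, founders) {
  stopifnot(inherits(config, "sim_config"), inherits(founders, "fs_founders"))
  markers <- founders$markers
  if (min(markers$pos) < config$segment_start || max(markers$pos) > config$segment_end) {
    abort("founder marker panel does not fit inside the configured segment.")
  }
  sizes <- config$cohort_sizes
  with_sim_seed(config$seed + 31L, {
    out <- list()
    truth <- list()
    emit <- function(ids, class, hap, k) {
      m <- nrow(markers)
      calls <- character(length(ids) * m)
      for (j in seq_along(ids)) {
        g <- ifelse(hap[j, ], markers$mutant_allele, markers$normal_allele)
        g[hap[j, ] & markers$mutant_is_deletion] <- "-"
        if (config$genotype_error_rate > 0) {
          err <- runif(m) < config$genotype_error_rate
          if (any(err)) {
            g[err] <- vapply(
              g[err],
              function(b) sample(setdiff(DNA_BASES, b), 1L), ""
            )
          }
        }
        calls[((j - 1) * m + 1):(j * m)] <- switch(class,
          mutant = g,
          carrier = {
            pair <- rbind(g, markers$normal_allele)
            apply(pair, 2, function(p) paste(sort(p), collapse = ""))
          },
          normal = paste0(markers$normal_allele, markers$normal_allele)
        )
      }
      out[[class]] <<- tibble(
        individual = rep(ids, each = m),
        class = class,
        marker = rep(markers$marker, length(ids)),
        chrom = rep(markers$chrom, length(ids)),
        pos = rep(markers$pos, length(ids)),
        call = calls
      )
      truth[[class]] <<- tibble(
        individual = ids, class = class,
        n_crossovers = k, recombinant = k >= 1L
      )
    }
    for (class in c("mutant", "carrier", "normal")) {
      n <- as.integer(sizes[[class]])
      if (n == 0L) next
      ids <- sprintf("%s_%04d", substr(class, 1, 3), seq_len(n))
      if (class == "normal") {
        hap <- matrix(FALSE, n, nrow(markers))
        k <- integer(n)
      } else {
        gam <- sim_gametes(n, config, markers$pos)
        hap <- gam$mutant
        k <- gam$n_crossovers
      }
      emit(ids, class, hap, k)
    }
    geno <- bind_rows(out)
    attr(geno, "meiosis") <- bind_rows(truth)
    class(geno) <- c("fs_genotypes", class(geno))
    geno
  })
}

#' Per-individual meiosis truth from a simulated cohort
#'
#' @param genotypes An `fs_genotypes` tibble from [simulate_cohort()].
#' @return Tibble: `individual`, `class`, `n_crossovers`, `recombinant`.
#' @export
cohort_meiosis <- function(genotypes) {
  truth <- attr(genotypes, "meiosis")
  if (is.null(truth)) abort("no meiosis truth attached; was this simulated?")
  truth
}
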