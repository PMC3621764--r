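# Variant planting: per-line variant tables with a flagged causative SNP,
# shared/unique provenance, and a capture-gap track.

class_footprint <- function(vclass, size) {
  switch(vclass,
    snp = 1L,
    micro_insertion = 1L,
    micro_deletion = 1L + size,
    macro_indel = 1L + size,
    gap = size
  )
}

#' Plant shared and line-unique variants on the simulated segment
#'
#' Draws the requested number of variants per class (SNP, 1-3 nt micro-indel,
#' 4-27 nt macro-indel, capture gap of >= 4 nt) at non-overlapping positions.
#' Shared variants appear identically in the focal line and at least one
#' control line; unique variants appear in the focal line only. One unique SNP
#' is placed at the configured causative position and flagged. A configurable
#' fraction of focal-line SNP calls is emitted as heterozygous, emulating the
#' capture-data artifacts that the hemizygosity filter removes. Indels are
#' written VCF-style with a one-base anchor; gaps are intervals with no alt
#' sequence.
#'
#' @param config A [sim_config()].
#' @param founders A [sim_founders()] result.
#' @param reference Optional [sim_reference()] result; when given, ref alleles
#'   are read from the simulated sequence.
#' @param max_attempts Placement retry rounds before a sizing error.
#' @return A list of class `fs_variants`: `variants` (tibble, one row per
#'   line x variant: `line_id`, `chrom`, `pos`, `end`, `ref`, `alt`,
#'   `vclass`, `zygosity`), `gaps` (tibble: `chrom`, `start`, `end`,
#'   `line_id`), and `truth` (tibble with `status` shared/unique, `lines`,
#'   `is_causative`).
#' @export
#' @examples
#' cfg <- sim_config(seed = 2, variant_counts = tibble::tibble(
#'   vclass = c("snp", "micro_indel", "gap"),
#'   shared = c(10L, 2L, 0L), unique = c(5L, 2L, 3L)
#' ))
#' pv <- plant_variants(cfg, sim_founders(cfg))
#' dplyr::count(pv$truth, vclass, status)
plant_variants <- function(config, founders, reference = NULL, max_attempts = 20L) {
  stopifnot(inherits(config, "sim_config"), inherits(founders, "fs_founders"))
  counts <- config$variant_counts
  known <- c("snp", "micro_indel", "macro_indel", "gap")
  if (!all(counts$vclass %in% known)) {
    abort(sprintf("unknown vclass in variant_counts: %s",
      paste(setdiff(counts$vclass, known), collapse = ", ")))
  }
  n_snp_unique <- sum(counts$unique[counts$vclass == "snp"])
  if (n_snp_unique < 1L) {
    abort("variant_counts must request at least one unique SNP (the causative variant).")
  }
  if (config$n_control_lines < 1L && sum(counts$shared) > 0L) {
    abort("shared variants need at least one control line.")
  }

  with_sim_seed(config$seed + 41L, {
    # expand request into one row per planted variant
    req <- purrr::pmap(counts, function(vclass, shared, unique) {
      tibble(
        vclass = vclass,
        status = rep(c("shared", "unique"), c(shared, unique))
      )
    }) |> bind_rows()
    n <- nrow(req)
    # concrete subclass + size
    req <- req |>
      mutate(
        sub = case_when(
          .data$vclass == "micro_indel" ~ sample(c("micro_insertion", "micro_deletion"), n, replace = TRUE),
          .data$vclass == "macro_indel" ~ "macro_indel",
          TRUE ~ .data$vclass
        ),
        size = case_when(
          .data$sub == "snp" ~ 1L,
          .data$sub %in% c("micro_insertion", "micro_deletion") ~ sample(1:3, n, replace = TRUE),
          .data$sub == "macro_indel" ~ sample(4:27, n, replace = TRUE),
          .data$sub == "gap" ~ pmin(4L + stats::rnbinom(n, size = 1, mu = 48), 634L)
        ),
        footprint = purrr::map2_int(.data$sub, .data$size, class_footprint)
      )
    # reserve the causative slot: first unique snp
    causative_idx <- which(req$vclass == "snp" & req$status == "unique")[1L]

    pos <- place_non_overlapping(
      req$footprint, config$segment_start, config$segment_end,
      fixed = setNames(config$causative_position, causative_idx),
      max_attempts = max_attempts
    )
    req$pos <- pos
    req$is_causative <- seq_len(n) == causative_idx

    ref_at <- function(p, len) {
      if (!is.null(reference)) {
        reference_subseq(reference, p, p + len - 1L)
      } else {
        paste(random_bases(len, config$gc_fraction), collapse = "")
      }
    }
    alleles <- purrr::pmap(
      list(req$sub, req$size, req$pos, req$is_causative),
      function(sub, size, p, is_causative) {
        if (sub == "snp") {
          ref <- ref_at(p, 1L)
          alt <- if (is_causative && founders$causative$alt != ref) {
            founders$causative$alt
          } else {
            sample(setdiff(DNA_BASES, ref), 1L)
          }
          list(ref = ref, alt = alt, end = p)
        } else if (sub == "micro_insertion") {
          anchor <- ref_at(p, 1L)
          list(
            ref = anchor,
            alt = paste0(anchor, paste(random_bases(size, config$gc_fraction), collapse = "")),
            end = p
          )
        } else if (sub %in% c("micro_deletion", "macro_indel")) {
          ref <- ref_at(p, 1L + size)
          list(ref = ref, alt = substr(ref, 1L, 1L), end = p + size)
        } else { # gap
          list(ref = ".", alt = "", end = p + size - 1L)
        }
      }
    )
    req$ref <- purrr::map_chr(alleles, "ref")
    req$alt <- purrr::map_chr(alleles, "alt")
    req$end <- purrr::map_dbl(alleles, "end")

    # zygosity: focal sample is hemizygous; a fraction of SNP calls are het
    req$zygosity <- rep("hemi", n)
    snp_rows <- which(req$sub == "snp" & !req$is_causative)
    n_het <- round(config$het_fraction * sum(req$sub == "snp"))
    if (n_het > 0L && length(snp_rows) > 0L) {
      req$zygosity[sample(snp_rows, min(n_het, length(snp_rows)))] <- "het"
    }

    # line membership: shared -> focal + non-empty control subset
    ctrl <- sprintf("control_%d", seq_len(config$n_control_lines))
    req$lines <- purrr::map2_chr(req$status, seq_len(n), function(st, i) {
      if (st == "unique") {
        "focal"
      } else {
        k <- sample(config$n_control_lines, 1L)
        paste(c("focal", sort(sample(ctrl, k))), collapse = ",")
      }
    })

    truth <- req |>
      mutate(chrom = config$chrom, vclass = .data$sub) |>
      select("chrom", "pos", "end", "ref", "alt", "vclass", "zygosity",
             "status", "lines", "is_causative") |>
      arrange(.data$pos)

    variants <- truth |>
      mutate(lines_list = strsplit(.data$lines, ",", fixed = TRUE)) |>
      tidyr::unnest(cols = "lines_list") |>
      rename(line_id = "lines_list") |>
      mutate(zygosity = ifelse(.data$line_id == "focal", .data$zygosity, "hom")) |>
      select("line_id", "chrom", "pos", "end", "ref", "alt", "vclass", "zygosity") |>
      arrange(.data$line_id, .data$pos)

    gaps <- truth |>
      filter(.data$vclass == "gap") |>
      mutate(start = .data$pos, line_id = "focal") |>
      select("chrom", "start", "end", "line_id")

    structure(list(variants = variants, gaps = gaps, truth = truth),
      class = "fs_variants"
    )
  })
}

# Draw start positions so that [pos, pos + footprint - 1] never overlap.
# `fixed` pins specific request indices to given positions.
place_non_overlapping <- function(footprint, seg_start, seg_end,
                                  fixed = integer(), max_attempts = 20L) {
  n <- length(footprint)
  if (sum(footprint) + n > (seg_end - seg_start + 1)) {
    abort("requested variants do not fit in the segment.")
  }
  pos <- rep(NA_real_, n)
  fixed_idx <- as.integer(names(fixed))
  pos[fixed_idx] <- unname(fixed)
  todo <- setdiff(seq_len(n), fixed_idx)
  for (attempt in seq_len(max_attempts)) {
    pos[todo] <- floor(runif(length(todo), seg_start, seg_end - footprint[todo] + 1))
    ord <- order(pos)
    starts <- pos[ord]
    ends <- pos[ord] + footprint[ord] - 1
    clash <- c(FALSE, starts[-1] <= ends[-n] + 1) # keep a 1-bp buffer
    bad <- ord[clash | c(clash[-1], FALSE)]
    bad <- setdiff(bad, fixed_idx)
    if (length(bad) == 0L && !anyDuplicated(pos)) {
      return(pos)
    }
    todo <- bad
    if (length(todo) == 0L) todo <- setdiff(seq_len(n), fixed_idx)
  }
  abort("could not place variants without overlap; segment too crowded.")
}
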