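# miRNA seed-site scanning over 3' UTR sequences: perfect-seed matches in
# the canonical site classes, a documented stand-in duplex-energy score, and
# gap-aware diffing of reference vs mutant UTRs.

SITE_CLASS_ORDER <- c("8mer", "7mer_m8", "7mer_A1", "seed6")

#' Seed-scan configuration
#'
#' Controls the UTR seed scan. `helix_from`/`helix_to` give the miRNA
#' nucleotide span that must pair perfectly for the basic (`seed6`) site
#' (default 2-7, the canonical seed). Site classes: `seed6` = UTR reverse
#' complement of miRNA nt `helix_from`-`helix_to`; `7mer_m8` = nt
#' `helix_from`-8; `7mer_A1` = seed6 plus an `A` in the UTR opposite miRNA
#' nt 1; `8mer` = 7mer_m8 plus that `A` anchor. The energy term is a
#' documented stand-in, not a full hybridisation model: base pairs score
#' G:C -3.0, A:U -2.0, G:U -1.0 kcal/mol, summed over the seed pairs plus a
#' greedy 3'-ward extension of the duplex while bases keep pairing; a
#' different `energy_fun(mirna, utr, site)` can be plugged in.
#'
#' @param energy_cutoff Keep sites with energy <= this (kcal/mol) when
#'   `energy_filter` is on.
#' @param helix_from,helix_to Perfectly paired miRNA nt span
#'   (`helix_from < helix_to`).
#' @param site_classes Subset of `"8mer"`, `"7mer_m8"`, `"7mer_A1"`,
#'   `"seed6"` to report.
#' @param energy_filter Apply the energy cutoff (the hybridisation-screen
#'   mode)?
#' @param energy_fun Optional replacement energy function.
#' @return A `seed_scan_config` list.
#' @export
seed_scan_config <- function(energy_cutoff = -20, helix_from = 2L, helix_to = 7L,
                             site_classes = SITE_CLASS_ORDER,
                             energy_filter = FALSE, energy_fun = NULL) {
  check_scalar_number(helix_from, "helix_from", min = 1)
  check_scalar_number(helix_to, "helix_to", min = 1)
  if (helix_from >= helix_to) abort("`helix_from` must be < `helix_to`.")
  stopifnot(all(site_classes %in% SITE_CLASS_ORDER))
  structure(
    list(
      energy_cutoff = energy_cutoff, helix_from = as.integer(helix_from),
      helix_to = as.integer(helix_to), site_classes = site_classes,
      energy_filter = energy_filter, energy_fun = energy_fun
    ),
    class = "seed_scan_config"
  )
}

#' Hybridisation-screen configuration (perfect 2-7 seed, energy cutoff)
#' @inheritParams seed_scan_config
#' @return A `seed_scan_config`.
#' @export
rnahybrid_config <- function(energy_cutoff = -20, helix_from = 2L, helix_to = 7L) {
  seed_scan_config(
    energy_cutoff = energy_cutoff, helix_from = helix_from,
    helix_to = helix_to, site_classes = "seed6", energy_filter = TRUE
  )
}

#' Conserved-seed configuration (7-8mer site classes, no energy screen)
#' @return A `seed_scan_config`.
#' @export
targetscan_config <- function() {
  seed_scan_config(
    site_classes = c("8mer", "7mer_m8", "7mer_A1"),
    energy_filter = FALSE
  )
}

normalize_dna <- function(x) chartr("Uu", "TT", toupper(x))

PAIR_ENERGY <- c(GC = -3, CG = -3, AT = -2, TA = -2, GT = -1, TG = -1)

# stand-in duplex energy: seed pairs + greedy extension on the miRNA 3' side
# (UTR 5' side), scoring WC and GU pairs until the first non-pair.
standin_energy <- function(mirna, utr, site_start, seed_from, seed_to) {
  m <- strsplit(mirna, "")[[1]]
  u <- strsplit(utr, "")[[1]]
  # miRNA nt seed_from pairs with the 3'-most base of the seed match on the UTR
  seed_len <- seed_to - seed_from + 1L
  e <- 0
  # seed pairs (perfect Watson-Crick by construction)
  for (j in seq_len(seed_len)) {
    mi <- m[seed_from + j - 1L]
    ui <- u[site_start + seed_len - j]
    val <- PAIR_ENERGY[paste0(mi, ui)]
    if (!is.na(val)) e <- e + val
  }
  # extend: miRNA nt seed_to+1, ... pair with UTR bases upstream of the site
  j <- seed_to + 1L
  up <- site_start - 1L
  while (j <= length(m) && up >= 1L) {
    key <- paste0(m[j], u[up])
    if (!key %in% names(PAIR_ENERGY)) break
    e <- e + PAIR_ENERGY[[key]]
    j <- j + 1L
    up <- up - 1L
  }
  unname(e)
}

find_all <- function(text, pattern) {
  if (nchar(pattern) == 0L || nchar(pattern) > nchar(text)) {
    return(integer())
  }
  hits <- gregexpr(pattern, text, fixed = TRUE)[[1]]
  if (hits[1L] < 0) integer() else as.integer(hits)
}

as_mirna_tibble <- function(mirnas) {
  if (inherits(mirnas, "XStringSet")) {
    tibble(mirna_id = names(mirnas), seq = as.character(mirnas))
  } else if (is.character(mirnas)) {
    tibble(
      mirna_id = names(mirnas) %||% sprintf("mirna_%d", seq_along(mirnas)),
      seq = unname(mirnas)
    )
  } else {
    check_cols(mirnas, c("mirna_id", "seq"), "mirnas")
    as_tibble(mirnas[c("mirna_id", "seq")])
  }
}

#' Scan a 3' UTR for miRNA seed sites
#'
#' Reports every match of the enabled site classes (possibly overlapping and
#' nested), sorted by UTR position and then class specificity
#' (8mer > 7mer_m8 > 7mer_A1 > seed6). DNA and RNA alphabets are both
#' accepted. miRNAs shorter than the required span are skipped with a
#' warning. When `config$energy_filter` is on, sites with stand-in energy
#' above `energy_cutoff` are dropped.
#'
#' @param utr UTR sequence (single string, 5'->3').
#' @param mirnas miRNA sequences: named character vector, tibble
#'   (`mirna_id`, `seq`), or an `XStringSet`.
#' @param config A [seed_scan_config()].
#' @return Tibble of class `seed_sites`: `mirna_id`, `utr_start`, `utr_end`
#'   (1-based inclusive, including the A1 anchor where applicable),
#'   `site_class`, `energy`.
#' @export
#' @examples
#' scan_utr("AAGCACTTTA", c(miR = "UAAAGUGCUU"),
#'          seed_scan_config(site_classes = c("8mer", "seed6")))
scan_utr <- function(utr, mirnas, config = seed_scan_config()) {
  stopifnot(inherits(config, "seed_scan_config"), length(utr) == 1L)
  utr <- normalize_dna(utr)
  mirnas <- as_mirna_tibble(mirnas)
  mirnas$seq <- normalize_dna(mirnas$seq)

  rows <- purrr::pmap(mirnas, function(mirna_id, seq) {
    need <- max(config$helix_to, if (any(c("8mer", "7mer_m8") %in% config$site_classes)) 8L else 0L)
    if (nchar(seq) < need) {
      warn(sprintf("miRNA %s shorter than required span (%d nt); skipped.", mirna_id, need))
      return(NULL)
    }
    seed <- substr(seq, config$helix_from, config$helix_to)
    seed_m8 <- substr(seq, config$helix_from, 8L)
    site_seed <- revcomp_dna(seed)
    site_m8 <- revcomp_dna(seed_m8)

    hit_rows <- list()
    add <- function(starts, width, site_class, seed_to, anchor = FALSE) {
      if (anchor) {
        # require an A in the UTR immediately 3' of the complement match
        if (length(starts) > 0L) {
          keep <- starts + width <= nchar(utr) &
            substring(utr, starts + width, starts + width) == "A"
          starts <- starts[keep]
        }
        width <- width + 1L
      }
      if (length(starts) == 0L) {
        return()
      }
      e <- vapply(
        starts,
        function(s) {
          standin_energy(seq, utr, s, config$helix_from, seed_to)
        },
        numeric(1)
      )
      hit_rows[[length(hit_rows) + 1L]] <<- tibble(
        mirna_id = mirna_id, utr_start = starts,
        utr_end = starts + width - 1L, site_class = site_class, energy = e
      )
    }
    if ("seed6" %in% config$site_classes) {
      add(find_all(utr, site_seed), nchar(site_seed), "seed6", config$helix_to)
    }
    if ("7mer_m8" %in% config$site_classes) {
      add(find_all(utr, site_m8), nchar(site_m8), "7mer_m8", 8L)
    }
    if ("7mer_A1" %in% config$site_classes) {
      add(find_all(utr, site_seed), nchar(site_seed), "7mer_A1", config$helix_to,
        anchor = TRUE
      )
    }
    if ("8mer" %in% config$site_classes) {
      add(find_all(utr, site_m8), nchar(site_m8), "8mer", 8L, anchor = TRUE)
    }
    bind_rows(hit_rows)
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0L) {
    out <- tibble(
      mirna_id = character(), utr_start = integer(), utr_end = integer(),
      site_class = character(), energy = numeric()
    )
  }
  if (config$energy_filter && nrow(out) > 0L) {
    efun <- config$energy_fun
    if (!is.null(efun)) {
      out$energy <- purrr::pmap_dbl(out, function(mirna_id, utr_start, ...) {
        efun(mirnas$seq[match(mirna_id, mirnas$mirna_id)], utr, utr_start)
      })
    }
    out <- filter(out, .data$energy <= config$energy_cutoff)
  }
  out <- out |>
    mutate(class_rank = match(.data$site_class, SITE_CLASS_ORDER)) |>
    arrange(.data$utr_start, .data$class_rank, .data$mirna_id) |>
    select(-"class_rank")
  class(out) <- c("seed_sites", class(out))
  out
}

# column-wise coordinate projection alt -> ref via global alignment
align_projection <- function(ref, alt) {
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(ref), Biostrings::DNAString(alt),
    type = "global", gapOpening = 4, gapExtension = 1
  )
  p <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  s <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  ref_i <- cumsum(p != "-")
  alt_i <- cumsum(s != "-")
  # projected ref coordinate for each alt position: ref bases consumed at
  # that alignment column (0 for a leading insertion)
  proj <- ref_i[match(seq_len(nchar(alt)), alt_i)]
  proj
}

#' Diff seed sites between reference and mutant UTRs
#'
#' Scans both sequences with the same configuration and compares the site
#' sets under a gap-aware identity: a site is the same site if it has the
#' same miRNA, the same class, and its start maps to the same reference
#' coordinate after global alignment of the two UTRs. Sites present only in
#' the mutant UTR are gained; sites present only in the reference are lost.
#'
#' @param ref_utr,alt_utr Reference and mutant UTR sequences.
#' @inheritParams scan_utr
#' @return List with tibbles `gained`, `lost`, `ref_sites`, `alt_sites`.
#' @export
diff_sites <- function(ref_utr, alt_utr, mirnas, config = seed_scan_config()) {
  if (nchar(ref_utr) == 0L || nchar(alt_utr) == 0L) {
    abort("both UTR sequences must be non-empty.")
  }
  ref_utr <- normalize_dna(ref_utr)
  alt_utr <- normalize_dna(alt_utr)
  ref_sites <- scan_utr(ref_utr, mirnas, config)
  alt_sites <- scan_utr(alt_utr, mirnas, config)
  proj <- if (identical(ref_utr, alt_utr)) {
    seq_len(nchar(alt_utr))
  } else {
    align_projection(ref_utr, alt_utr)
  }
  ref_key <- paste(ref_sites$mirna_id, ref_sites$site_class, ref_sites$utr_start)
  alt_key <- paste(
    alt_sites$mirna_id, alt_sites$site_class,
    proj[alt_sites$utr_start]
  )
  list(
    gained = alt_sites[!alt_key %in% ref_key, , drop = FALSE],
    lost = ref_sites[!ref_key %in% alt_key, , drop = FALSE],
    ref_sites = ref_sites,
    alt_sites = alt_sites
  )
}
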