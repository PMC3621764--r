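# Brute-force oracles and small fixtures shared across the suite. Every
# oracle is a deliberately naive, loop-based reimplementation of the
# definition, independent of the package code paths it checks.

# ---- fixtures ---------------------------------------------------------------

# a small, fast simulation: 100 kb segment, 10 markers, light variant load
small_config <- function(seed = 1, recomb_rate = 20, ...) {
  sim_config(
    seed = seed,
    segment_start = 1, segment_length = 100000,
    n_markers = 10, recomb_rate = recomb_rate,
    cohort_sizes = c(mutant = 20, carrier = 8, normal = 4),
    variant_counts = tibble::tibble(
      vclass = c("snp", "micro_indel", "macro_indel", "gap"),
      shared = c(30L, 6L, 2L, 0L),
      unique = c(15L, 6L, 2L, 8L)
    ),
    causative_position = 50000,
    genes = tibble::tibble(
      gene_id = c("g1", "g2"), start = c(20001, 60001),
      end = c(32000, 71000), strand = c("+", "-")
    ),
    ...
  )
}

# a hand-built two-gene model set on a plus and a minus strand
toy_features <- function() {
  dplyr::bind_rows(
    tibble::tibble(
      gene_id = "gplus", chrom = "Z", strand = "+",
      feature = c("exon", "exon", "CDS", "CDS", "five_prime_UTR", "three_prime_UTR"),
      start = c(1001, 1501, 1051, 1501, 1001, 1851),
      end = c(1200, 1900, 1200, 1850, 1050, 1900)
    ),
    tibble::tibble(
      gene_id = "gminus", chrom = "Z", strand = "-",
      feature = c("exon", "exon", "CDS", "CDS", "three_prime_UTR", "five_prime_UTR"),
      start = c(3001, 3401, 3051, 3401, 3001, 3751),
      end = c(3200, 3800, 3200, 3750, 3050, 3800)
    )
  )
}

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")

# ---- interval oracle --------------------------------------------------------

# naive scan for the maximal linked run (most markers, ties distal) and its
# flanking recombined markers; statuses over positions sorted ascending
oracle_interval <- function(pos, status, edge_allowance = 500001) {
  keep <- status != "uninformative"
  p <- pos[keep]
  s <- status[keep]
  runs <- list()
  i <- 1
  while (i <= length(s)) {
    if (s[i] == "linked") {
      j <- i
      while (j + 1 <= length(s) && s[j + 1] == "linked") j <- j + 1
      runs[[length(runs) + 1]] <- c(i, j)
      i <- j + 1
    } else {
      i <- i + 1
    }
  }
  if (length(runs) == 0) {
    return(NULL)
  }
  sizes <- vapply(runs, function(r) r[2] - r[1] + 1, numeric(1))
  best <- runs[[max(which(sizes == max(sizes)))]]
  inner_left <- p[best[1]]
  inner_right <- p[best[2]]
  outer_left <- if (best[1] > 1) p[best[1] - 1] else NA_real_
  outer_right <- if (best[2] < length(p)) p[best[2] + 1] else NA_real_
  cr_min <- inner_right - inner_left
  cr_max <- if (is.na(outer_left) || is.na(outer_right)) {
    cr_min + edge_allowance
  } else {
    outer_right - outer_left - 2
  }
  list(
    inner_left = inner_left, inner_right = inner_right,
    outer_left = outer_left, outer_right = outer_right,
    cr_min = cr_min, cr_max = cr_max
  )
}

# ---- consequence oracle -----------------------------------------------------

# whole-sequence re-translation through Biostrings: mutate, translate both
# strands from the frame offset, and read off the amino acid at the codon
# containing the variant
oracle_snp_consequence <- function(sequence, pos, ref, alt, frame) {
  k <- as.integer(substr(frame, 2, 2))
  minus <- substr(frame, 1, 1) == "-"
  stopifnot(substr(sequence, pos, pos) == ref)
  mutated <- paste0(
    substr(sequence, 1, pos - 1), alt,
    substr(sequence, pos + 1, nchar(sequence))
  )
  tr <- function(s) {
    if (minus) {
      s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    }
    body <- substr(s, k, nchar(s))
    body <- substr(body, 1, 3 * (nchar(body) %/% 3))
    if (nchar(body) < 3) {
      return("")
    }
    as.character(Biostrings::translate(Biostrings::DNAString(body), no.init.codon = TRUE))
  }
  o <- if (minus) nchar(sequence) - pos + 1 else pos
  if (o < k) {
    return(list(effect = NA_character_, boundary = TRUE))
  }
  codon_idx <- (o - k) %/% 3 + 1
  aa_ref <- tr(sequence)
  aa_alt <- tr(mutated)
  if (codon_idx > nchar(aa_ref)) {
    return(list(effect = NA_character_, boundary = TRUE))
  }
  a1 <- substr(aa_ref, codon_idx, codon_idx)
  a2 <- substr(aa_alt, codon_idx, codon_idx)
  effect <- if (a1 == a2) {
    "synonymous"
  } else if (a2 == "*") {
    "nonsense"
  } else if (a1 == "*") {
    "stop_loss"
  } else {
    "missense"
  }
  list(effect = effect, boundary = FALSE)
}

# indel oracle: full re-translation of original and mutated sequence in a
# frame; the mutated first stop is novel unless the frame is preserved and
# its nt offset equals the reference first stop shifted by the indel length
oracle_indel_stop <- function(sequence, pos, ref, alt, frame = "+1") {
  k <- as.integer(substr(frame, 2, 2))
  minus <- substr(frame, 1, 1) == "-"
  mutated <- paste0(
    substr(sequence, 1, pos - 1), alt,
    substr(sequence, pos + nchar(ref), nchar(sequence))
  )
  strand <- function(s) {
    if (minus) as.character(Biostrings::reverseComplement(Biostrings::DNAString(s))) else s
  }
  pep <- function(s) {
    body <- substr(s, k, nchar(s))
    body <- substr(body, 1, 3 * (nchar(body) %/% 3))
    if (nchar(body) < 3) {
      return("")
    }
    as.character(Biostrings::translate(Biostrings::DNAString(body), no.init.codon = TRUE, if.fuzzy.codon = "X"))
  }
  edit_last <- pos + max(nchar(ref), 1) - 1
  o <- if (minus) nchar(sequence) - edit_last + 1 else pos
  codon_idx <- max(1, (o - k) %/% 3 + 1)
  stop_at <- function(s) {
    p <- pep(strand(s))
    stops <- which(strsplit(p, "")[[1]] == "*")
    stops <- stops[stops >= codon_idx]
    if (length(stops) == 0) Inf else min(stops)
  }
  diff <- nchar(alt) - nchar(ref)
  a1 <- stop_at(mutated)
  r1 <- stop_at(sequence)
  same <- diff %% 3 == 0 && is.finite(r1) && is.finite(a1) &&
    3 * (a1 - 1) == 3 * (r1 - 1) + diff
  is.finite(a1) && !same
}

# ---- seed-site oracle -------------------------------------------------------

base_complement <- c(A = "T", C = "G", G = "C", T = "A")

# sliding-window check of perfect antiparallel complementarity between a
# miRNA span and the UTR, with the optional A1 anchor
oracle_seed_sites <- function(utr, mirna, classes = c("8mer", "7mer_m8", "7mer_A1", "seed6"),
                              helix_from = 2, helix_to = 7) {
  utr <- chartr("Uu", "TT", toupper(utr))
  mirna <- chartr("Uu", "TT", toupper(mirna))
  u <- strsplit(utr, "")[[1]]
  m <- strsplit(mirna, "")[[1]]
  matches <- function(from, to, start) {
    len <- to - from + 1
    if (start < 1 || start + len - 1 > length(u)) {
      return(FALSE)
    }
    for (j in seq_len(len)) {
      if (u[start + len - j] != base_complement[[m[from + j - 1]]]) {
        return(FALSE)
      }
    }
    TRUE
  }
  out <- list()
  add <- function(start, end, cls) {
    out[[length(out) + 1]] <<- data.frame(
      utr_start = start, utr_end = end, site_class = cls
    )
  }
  for (s in seq_along(u)) {
    w6 <- helix_to - helix_from + 1
    w8 <- 8 - helix_from + 1
    if ("seed6" %in% classes && matches(helix_from, helix_to, s)) add(s, s + w6 - 1, "seed6")
    if ("7mer_m8" %in% classes && length(m) >= 8 && matches(helix_from, 8, s)) {
      add(s, s + w8 - 1, "7mer_m8")
    }
    if ("7mer_A1" %in% classes && matches(helix_from, helix_to, s) &&
      s + w6 <= length(u) && u[s + w6] == "A") {
      add(s, s + w6, "7mer_A1")
    }
    if ("8mer" %in% classes && length(m) >= 8 && matches(helix_from, 8, s) &&
      s + w8 <= length(u) && u[s + w8] == "A") {
      add(s, s + w8, "8mer")
    }
  }
  if (length(out) == 0) {
    return(data.frame(
      utr_start = integer(), utr_end = integer(), site_class = character()
    ))
  }
  do.call(rbind, out)
}

# ---- PCR oracle -------------------------------------------------------------

oracle_pcr <- function(template, fwd, rev, max_product) {
  template <- toupper(template)
  fwd <- toupper(fwd)
  rc <- function(x) {
    paste(rev(base_complement[strsplit(toupper(x), "")[[1]]]), collapse = "")
  }
  rev_site <- rc(rev)
  hits <- function(pat) {
    found <- integer()
    for (s in seq_len(nchar(template) - nchar(pat) + 1)) {
      if (substr(template, s, s + nchar(pat) - 1) == pat) found <- c(found, s)
    }
    found
  }
  f <- hits(fwd)
  r <- hits(rev_site)
  best <- NULL
  for (fp in f) {
    for (rp in r) {
      size <- rp + nchar(rev_site) - 1 - fp + 1
      if (rp > fp + nchar(fwd) - 1 && size <= max_product) {
        if (is.null(best) || size < best$size) best <- list(fwd = fp, rev = rp, size = size)
      }
    }
  }
  best # NULL when absent
}

# ---- annotation oracle ------------------------------------------------------

# per-base membership test against explicit feature intervals
oracle_point_category <- function(p, feats, splice_window = 2) {
  g <- feats[order(feats$start), ]
  tx <- range(c(g$start, g$end))
  if (p < tx[1] || p > tx[2]) {
    return("non_genic")
  }
  inside <- function(type) {
    d <- g[g$feature == type, ]
    nrow(d) > 0 && any(p >= d$start & p <= d$end)
  }
  ex <- g[g$feature == "exon", ]
  ex <- ex[order(ex$start), ]
  in_splice <- FALSE
  if (nrow(ex) > 1) {
    for (i in seq_len(nrow(ex) - 1)) {
      is_ <- ex$end[i] + 1
      ie <- ex$start[i + 1] - 1
      if (p >= is_ && p <= min(ie, is_ + splice_window - 1)) in_splice <- TRUE
      if (p <= ie && p >= max(is_, ie - splice_window + 1)) in_splice <- TRUE
    }
  }
  if (in_splice) {
    return("splice_site")
  }
  if (inside("CDS")) {
    return("exon_cds")
  }
  if (inside("five_prime_UTR")) {
    return("utr5")
  }
  if (inside("three_prime_UTR")) {
    return("utr3")
  }
  "intron"
}

# ---- category placement helper ---------------------------------------------

# deterministic positions inside a gene's CDS / 3'UTR / splice windows /
# intron interiors, used to build report-layout fixtures
place_category_positions <- function(features, gene, counts, splice_window = 2) {
  f <- features[features$gene_id == gene, ]
  ex <- f[f$feature == "exon", ]
  ex <- ex[order(ex$start), ]
  introns <- data.frame(
    start = ex$end[-nrow(ex)] + 1,
    end = ex$start[-1] - 1
  )
  take_run <- function(blocks, k, trim = 0) {
    out <- numeric()
    for (i in seq_len(nrow(blocks))) {
      lo <- blocks$start[i] + trim
      hi <- blocks$end[i] - trim
      if (hi < lo) next
      got <- seq(lo, min(hi, lo + (k - length(out)) - 1))
      out <- c(out, got)
      if (length(out) >= k) break
    }
    if (length(out) < k) stop("not enough room for category placement")
    out[seq_len(k)]
  }
  pos <- numeric()
  if (counts[["cds"]] > 0) {
    cds <- f[f$feature == "CDS", ]
    cds <- cds[order(-(cds$end - cds$start)), ]
    pos <- c(pos, take_run(cds, counts[["cds"]], trim = 1))
  }
  if (counts[["utr3"]] > 0) {
    u3 <- f[f$feature == "three_prime_UTR", ]
    pos <- c(pos, take_run(u3, counts[["utr3"]], trim = 1))
  }
  if (counts[["splice"]] > 0) {
    sp <- data.frame(
      start = c(introns$start, introns$end),
      end = c(introns$start, introns$end)
    )
    pos <- c(pos, take_run(sp[seq_len(counts[["splice"]]), , drop = FALSE],
      counts[["splice"]]))
  }
  if (counts[["intron"]] > 0) {
    pos <- c(pos, take_run(introns, counts[["intron"]], trim = splice_window + 1))
  }
  pos
}
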