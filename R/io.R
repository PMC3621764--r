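# Readers and writers: genotype TSV, minimal VCF, GFF3 gene models, BED gap
# tracks, FASTA, and coordinate-convention helpers. All coordinates are
# 1-based inclusive in memory; converters to external conventions are exact
# inverses.

#' Convert BED half-open to 1-based inclusive coordinates (and back)
#'
#' BED intervals are 0-based half-open: BED `(100, 200)` is inclusive
#' `101-200`.
#'
#' @param start0,end0 BED coordinates.
#' @param start,end 1-based inclusive coordinates.
#' @return A two-column tibble (`start`,`end` or `start0`,`end0`).
#' @export
#' @examples
#' bed_to_interval(100, 200)
bed_to_interval <- function(start0, end0) {
  if (any(end0 <= start0)) abort("BED intervals need end0 > start0.")
  tibble(start = start0 + 1, end = end0)
}

#' @rdname bed_to_interval
#' @export
interval_to_bed <- function(start, end) {
  if (any(end < start)) abort("need end >= start.")
  tibble(start0 = start - 1, end0 = end)
}

#' Write / read a wide genotype matrix TSV
#'
#' Rows are individuals with a `class` column, columns are marker ids, and a
#' `#positions:` comment line records the marker positions. Reading returns
#' the long form consumed by [assign_linkage()].
#'
#' @param genotypes Long genotype tibble (`individual`, `class`, `marker`,
#'   `pos`, `call`).
#' @param path File path.
#' @return `write_genotypes_tsv()` returns `path` invisibly;
#'   `read_genotypes_tsv()` a long tibble (`individual`, `class`, `marker`,
#'   `pos`, `call`).
#' @export
write_genotypes_tsv <- function(genotypes, path) {
  check_cols(genotypes, c("individual", "class", "marker", "pos", "call"), "genotypes")
  wide <- genotypes |>
    select("individual", "class", "marker", "call") |>
    tidyr::pivot_wider(names_from = "marker", values_from = "call")
  pos <- genotypes |>
    distinct(.data$marker, .data$pos) |>
    arrange(match(.data$marker, names(wide)))
  header <- paste0("#positions:\t\t", paste(pos$pos, collapse = "\t"))
  writeLines(header, path)
  readr::write_tsv(wide, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' @rdname write_genotypes_tsv
#' @param markers Optional marker panel supplying positions (overrides the
#'   `#positions:` comment).
#' @export
read_genotypes_tsv <- function(path, markers = NULL) {
  lines <- readr::read_lines(path)
  pos_line <- lines[startsWith(lines, "#positions:")]
  wide <- readr::read_tsv(path, comment = "#", col_types = readr::cols(
    individual = readr::col_character(), class = readr::col_character(),
    .default = readr::col_character()
  ))
  long <- wide |>
    tidyr::pivot_longer(-c("individual", "class"),
      names_to = "marker", values_to = "call"
    )
  if (!is.null(markers)) {
    long <- left_join(long, markers[c("marker", "pos")], by = "marker")
  } else if (length(pos_line) == 1L) {
    parts <- strsplit(pos_line, "\t", fixed = TRUE)[[1]]
    pos <- as.numeric(parts[-(1:2)])
    marker_names <- setdiff(names(wide), c("individual", "class"))
    if (length(pos) != length(marker_names)) {
      abort(sprintf("malformed #positions line in %s.", path))
    }
    long <- left_join(long, tibble(marker = marker_names, pos = pos), by = "marker")
  } else {
    abort(sprintf("%s: no #positions comment and no `markers` panel given.", path))
  }
  select(long, "individual", "class", "marker", "pos", "call")
}

#' Write / read a marker panel TSV
#' @param markers Marker panel tibble.
#' @param path File path.
#' @return The path (write) or the panel tibble (read).
#' @export
write_markers_tsv <- function(markers, path) {
  check_cols(markers, c("marker", "chrom", "pos", "normal_allele", "mutant_allele"),
    "markers"
  )
  readr::write_tsv(markers, path)
  invisible(path)
}

#' @rdname write_markers_tsv
#' @export
read_markers_tsv <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    marker = readr::col_character(), chrom = readr::col_character(),
    pos = readr::col_double(), normal_allele = readr::col_character(),
    mutant_allele = readr::col_character(), .default = readr::col_guess()
  ))
  check_cols(df, c("marker", "chrom", "pos", "normal_allele", "mutant_allele"), path)
  df
}

VCF_INFO_KEYS <- c("VCLASS", "ZYG", "LINE", "VERDICT", "REASON", "END")

#' Write / read minimal VCF
#'
#' The minimal dialect: `CHROM POS ID REF ALT QUAL FILTER INFO` with INFO
#' keys `VCLASS`, `ZYG`, `LINE`, `VERDICT`, `REASON` and `END` (gaps).
#' Verdicts also set FILTER (`PASS` for retained variants). Round-trips are
#' value-identical for these fields.
#'
#' @param variants Variant tibble (`chrom`, `pos`, `ref`, `alt`; optional
#'   `end`, `vclass`, `zygosity`, `line_id`, `status`, `reason`).
#' @param path File path.
#' @return The path (write) or a variant tibble (read).
#' @export
write_variants_vcf <- function(variants, path) {
  check_cols(variants, c("chrom", "pos", "ref", "alt"), "variants")
  v <- variants
  get0c <- function(col) if (col %in% names(v)) as.character(v[[col]]) else rep(NA_character_, nrow(v))
  info_field <- function(key, val) ifelse(is.na(val), NA, paste0(key, "=", val))
  parts <- rbind(
    info_field("VCLASS", get0c("vclass")),
    info_field("ZYG", get0c("zygosity")),
    info_field("LINE", get0c("line_id")),
    info_field("VERDICT", get0c("status")),
    info_field("REASON", get0c("reason")),
    info_field("END", if ("end" %in% names(v)) {
      ifelse(!is.na(v$end) & v$end != v$pos, as.character(v$end), NA)
    } else {
      rep(NA_character_, nrow(v))
    })
  )
  info <- apply(parts, 2, function(p) {
    p <- p[!is.na(p)]
    if (length(p) == 0L) "." else paste(p, collapse = ";")
  })
  filter_col <- if ("status" %in% names(v)) {
    ifelse(is.na(v$status), ".",
      ifelse(v$status == "retained_unique", "PASS", "eliminated")
    )
  } else {
    rep(".", nrow(v))
  }
  body <- data.frame(
    CHROM = v$chrom, POS = format(v$pos, scientific = FALSE, trim = TRUE),
    ID = ".", REF = ifelse(v$ref == "" | is.na(v$ref), ".", v$ref),
    ALT = ifelse(v$alt == "" | is.na(v$alt), ".", v$alt),
    QUAL = ".", FILTER = filter_col, INFO = info
  )
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=finescan",
    sprintf(
      '##INFO=<ID=%s,Number=%s,Type=%s,Description="%s">',
      c("VCLASS", "ZYG", "LINE", "VERDICT", "REASON", "END"),
      c("1", "1", "1", "1", "1", "1"),
      c("String", "String", "String", "String", "String", "Integer"),
      c(
        "Variant class", "Zygosity call", "Genetic line",
        "Triage verdict", "Elimination reason", "Gap interval end (1-based)"
      )
    ),
    paste(c(
      "#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO"
    ), collapse = "\t")
  )
  writeLines(c(header, do.call(paste, c(unname(body), sep = "\t"))), path)
  invisible(path)
}

#' @rdname write_variants_vcf
#' @export
read_variants_vcf <- function(path) {
  lines <- readr::read_lines(path)
  body <- lines[!startsWith(lines, "#")]
  if (length(body) == 0L) {
    return(tibble(
      chrom = character(), pos = numeric(), ref = character(), alt = character()
    ))
  }
  fields <- strsplit(body, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 8L)
  if (length(bad) > 0L) {
    abort(sprintf("%s: line %d has fewer than 8 VCF columns.", path, bad[1L]))
  }
  m <- do.call(rbind, fields)
  info_get <- function(info, key) {
    hit <- regmatches(info, regexpr(paste0("(?:^|;)", key, "=[^;]*"), info))
    out <- rep(NA_character_, length(info))
    found <- lengths(regmatches(info, gregexpr(paste0("(?:^|;)", key, "="), info))) > 0
    out[found] <- sub(paste0("^;?", key, "="), "", hit)
    out
  }
  info <- m[, 8L]
  pos <- as.numeric(m[, 2L])
  end <- suppressWarnings(as.numeric(info_get(info, "END")))
  tibble(
    chrom = m[, 1L], pos = pos,
    ref = ifelse(m[, 4L] == ".", ".", m[, 4L]),
    alt = ifelse(m[, 5L] == ".", "", m[, 5L]),
    end = ifelse(is.na(end), pos, end),
    vclass = info_get(info, "VCLASS"),
    zygosity = info_get(info, "ZYG"),
    line_id = info_get(info, "LINE"),
    status = info_get(info, "VERDICT"),
    reason = info_get(info, "REASON")
  )
}

#' Write / read a gap track as BED
#'
#' Gaps are stored 1-based inclusive in memory and written 0-based
#' half-open.
#'
#' @param gaps Tibble with `chrom`, `start`, `end` (1-based inclusive) and
#'   optional `line_id`.
#' @param path File path.
#' @return The path (write) or a gap tibble (read).
#' @export
write_gaps_bed <- function(gaps, path) {
  check_cols(gaps, c("chrom", "start", "end"), "gaps")
  bed <- interval_to_bed(gaps$start, gaps$end)
  name <- if ("line_id" %in% names(gaps)) gaps$line_id else "gap"
  writeLines(
    paste(gaps$chrom, format(bed$start0, scientific = FALSE, trim = TRUE),
      format(bed$end0, scientific = FALSE, trim = TRUE), name,
      sep = "\t"
    ),
    path
  )
  invisible(path)
}

#' @rdname write_gaps_bed
#' @export
read_gaps_bed <- function(path) {
  df <- readr::read_tsv(path,
    col_names = c("chrom", "start0", "end0", "line_id"),
    col_types = "cddc"
  )
  iv <- bed_to_interval(df$start0, df$end0)
  tibble(chrom = df$chrom, start = iv$start, end = iv$end, line_id = df$line_id)
}

#' Write / read gene-model features as GFF3
#'
#' One `gene` row per gene plus `exon`/`CDS`/`five_prime_UTR`/
#' `three_prime_UTR` children referencing it via `Parent`. Coordinates are
#' 1-based inclusive, as in GFF3.
#'
#' @param features Feature tibble as produced by [sim_reference()].
#' @param path File path.
#' @return The path (write) or a feature tibble (read).
#' @export
write_gene_features <- function(features, path) {
  check_cols(features, c("gene_id", "chrom", "strand", "feature", "start", "end"),
    "features"
  )
  genes <- features |>
    group_by(.data$gene_id, .data$chrom, .data$strand) |>
    summarise(start = min(.data$start), end = max(.data$end), .groups = "drop")
  fmt <- function(chrom, src, type, start, end, strand, attrs) {
    paste(chrom, src, type, format(start, scientific = FALSE, trim = TRUE),
      format(end, scientific = FALSE, trim = TRUE), ".", strand, ".", attrs,
      sep = "\t"
    )
  }
  lines <- c(
    "##gff-version 3",
    fmt(
      genes$chrom, "finescan", "gene", genes$start, genes$end, genes$strand,
      paste0("ID=", genes$gene_id)
    ),
    fmt(
      features$chrom, "finescan", features$feature, features$start,
      features$end, features$strand, paste0("Parent=", features$gene_id)
    )
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_gene_features
#' @export
read_gene_features <- function(path) {
  lines <- readr::read_lines(path)
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  fields <- strsplit(body, "\t", fixed = TRUE)
  if (any(lengths(fields) != 9L)) {
    abort(sprintf("%s: malformed GFF3 (need 9 tab-separated columns).", path))
  }
  m <- do.call(rbind, fields)
  attr_get <- function(attrs, key) {
    out <- rep(NA_character_, length(attrs))
    hit <- regmatches(attrs, regexpr(paste0(key, "=[^;]*"), attrs))
    found <- grepl(paste0(key, "="), attrs, fixed = TRUE)
    out[found] <- sub(paste0(key, "="), "", hit, fixed = TRUE)
    out
  }
  df <- tibble(
    chrom = m[, 1L], feature = m[, 3L],
    start = as.numeric(m[, 4L]), end = as.numeric(m[, 5L]),
    strand = m[, 7L],
    gene_id = dplyr::coalesce(attr_get(m[, 9L], "Parent"), attr_get(m[, 9L], "ID"))
  )
  children <- df |>
    filter(.data$feature != "gene") |>
    select("gene_id", "chrom", "strand", "feature", "start", "end")
  # child features must sit inside their parent gene span
  genes <- filter(df, .data$feature == "gene")
  if (nrow(genes) > 0L) {
    joined <- left_join(children, genes |>
      select("gene_id", g_start = "start", g_end = "end"), by = "gene_id")
    bad <- !is.na(joined$g_start) &
      (joined$start < joined$g_start | joined$end > joined$g_end)
    if (any(bad)) {
      abort(sprintf(
        "%s: feature outside its parent gene span (gene %s).",
        path, joined$gene_id[which(bad)[1L]]
      ))
    }
  }
  children
}

#' Write / read FASTA
#'
#' @param sequences Named character vector (or single string) of sequences.
#' @param path File path.
#' @return The path (write) or a named character vector (read).
#' @export
write_fasta <- function(sequences, path) {
  if (is.null(names(sequences))) {
    names(sequences) <- sprintf("seq_%d", seq_along(sequences))
  }
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(sequences), path)
  invisible(path)
}

#' @rdname write_fasta
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

#' The study marker panel
#'
#' The 15-locus Z-chromosome SNP panel used throughout the package examples
#' and fixtures, with physical positions and normal/mutant alleles.
#'
#' @return Marker panel tibble.
#' @export
study_marker_panel <- function() {
  default_marker_panel()
}

#' Bundled genotype profiles at the study marker panel
#'
#' Two informative genotype profiles shipped with the package: the
#' hemizygous mutant sample whose recombinant chromosome defines a ~1 Mb
#' interval, and the compiled overall reduced-region profile whose linked
#' run defines the final ~176 kb interval.
#'
#' @return Long genotype tibble ready for [assign_linkage()].
#' @export
study_genotype_profiles <- function() {
  path <- system.file("extdata", "panel_genotypes.tsv", package = "finescan")
  if (path == "") abort("bundled genotype fixture not found.")
  read_genotypes_tsv(path, markers = study_marker_panel())
}
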