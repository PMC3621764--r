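# Six-reading-frame coding consequences on genomic sequence: SNP codon
# effects and indel frameshift / premature-stop scanning.

FRAMES <- c("+1", "+2", "+3", "-1", "-2", "-3")

frame_offset <- function(frame) as.integer(substr(frame, 2L, 2L))
frame_is_minus <- function(frame) substr(frame, 1L, 1L) == "-"

# map a genomic position to an offset in the (possibly reverse-complemented)
# working strand of a sequence of length L starting at segment_start
strand_offset <- function(pos, segment_start, seq_len, minus) {
  o <- pos - segment_start + 1
  if (minus) seq_len - o + 1 else o
}

#' Call SNP coding consequences in a given reading frame
#'
#' For frame `+k`, codons tile the forward strand from offset `k`; for
#' `-k`, the reverse complement is tiled the same way. The SNP replaces one
#' base of its codon; both codons are translated with the standard genetic
#' code. Effects: `synonymous` (same amino acid), `nonsense` (alt is a stop,
#' ref is not), `stop_loss` (ref is a stop, alt is not), else `missense`.
#' SNPs whose codon is truncated by the sequence end get `boundary = TRUE`
#' and no call.
#'
#' @param variants Tibble of SNPs: `pos`, `ref`, `alt` (single bases).
#' @param sequence Reference segment as a character string, or an
#'   `fs_reference`.
#' @param frames Frames to evaluate, subset of
#'   `"+1","+2","+3","-1","-2","-3"`.
#' @param segment_start Genomic position of the first sequence base (taken
#'   from an `fs_reference` automatically).
#' @return Tibble: one row per variant x frame with `frame`, `ref_codon`,
#'   `alt_codon`, `ref_aa`, `alt_aa`, `effect`, `boundary`.
#' @export
#' @examples
#' call_consequence(
#'   tibble::tibble(pos = 4, ref = "A", alt = "G"),
#'   "GGGACCTTT", frames = "+1"
#' )
call_consequence <- function(variants, sequence, frames = FRAMES,
                             segment_start = NULL) {
  if (inherits(sequence, "fs_reference")) {
    segment_start <- segment_start %||% sequence$config$segment_start
    sequence <- sequence$sequence
  }
  segment_start <- segment_start %||% 1
  check_cols(variants, c("pos", "ref", "alt"), "variants")
  if (any(nchar(variants$ref) != 1L | nchar(variants$alt) != 1L)) {
    abort("call_consequence() handles single-base substitutions only.")
  }
  stopifnot(all(frames %in% FRAMES))
  seq_fwd <- toupper(sequence)
  seq_rev <- revcomp_dna(seq_fwd)
  len <- nchar(seq_fwd)
  off_fwd <- variants$pos - segment_start + 1
  if (any(off_fwd < 1 | off_fwd > len)) abort("variant position outside the sequence.")
  ref_obs <- substring(seq_fwd, off_fwd, off_fwd)
  if (any(ref_obs != toupper(variants$ref))) {
    abort("ref allele does not match the sequence at one or more positions.")
  }

  purrr::map(frames, function(fr) {
    k <- frame_offset(fr)
    minus <- frame_is_minus(fr)
    s <- if (minus) seq_rev else seq_fwd
    o <- if (minus) len - off_fwd + 1 else off_fwd
    ref_b <- if (minus) revcomp_dna(toupper(variants$ref)) else toupper(variants$ref)
    alt_b <- if (minus) revcomp_dna(toupper(variants$alt)) else toupper(variants$alt)
    codon_start <- k + 3 * floor((o - k) / 3)
    boundary <- codon_start < 1 | codon_start + 2 > len | o < k
    codon_start[boundary] <- 1 # placeholder, masked below
    ref_codon <- substring(s, codon_start, codon_start + 2)
    idx <- o - codon_start + 1
    alt_codon <- ref_codon
    substr(alt_codon, idx, idx) <- alt_b
    ref_aa <- codon_aa(ref_codon)
    alt_aa <- codon_aa(alt_codon)
    effect <- case_when(
      ref_aa == alt_aa ~ "synonymous",
      alt_aa == "*" ~ "nonsense",
      ref_aa == "*" ~ "stop_loss",
      TRUE ~ "missense"
    )
    out <- variants
    out$frame <- fr
    out$ref_codon <- ifelse(boundary, NA_character_, ref_codon)
    out$alt_codon <- ifelse(boundary, NA_character_, alt_codon)
    out$ref_aa <- ifelse(boundary, NA_character_, ref_aa)
    out$alt_aa <- ifelse(boundary, NA_character_, alt_aa)
    out$effect <- ifelse(boundary, NA_character_, effect)
    out$boundary <- boundary
    out
  }) |> bind_rows()
}

# apply one anchored indel (or SNP) to a character sequence; returns the
# modified sequence (coordinates relative to segment_start)
apply_variant_to_seq <- function(sequence, pos, ref, alt, segment_start = 1) {
  o <- pos - segment_start + 1
  stopifnot(o >= 1, o + nchar(ref) - 1 <= nchar(sequence))
  obs <- substr(sequence, o, o + nchar(ref) - 1)
  if (toupper(obs) != toupper(ref)) {
    abort("ref allele does not match the sequence at the indel position.")
  }
  paste0(
    substr(sequence, 1, o - 1), alt,
    substr(sequence, o + nchar(ref), nchar(sequence))
  )
}

first_stop_codon <- function(peptide) {
  hit <- regexpr("*", peptide, fixed = TRUE)
  if (hit < 0) Inf else as.numeric(hit)
}

#' Scan indels for frameshifts and premature stops
#'
#' An indel whose length difference is not a multiple of three is a
#' `frameshift`; otherwise it is an `inframe_indel`. In both cases the
#' mutated sequence is re-translated in the requested frame from the codon
#' containing the edit to the end of the segment, and `novel_stop` reports
#' whether the first downstream stop in the mutated translation is a stop
#' the reference did not already encode at the corresponding (indel-shifted)
#' position: for an in-frame indel the reference stop is recognised again
#' after shifting by the length difference, while any stop reached through a
#' shifted reading frame counts as novel.
#'
#' @param indels Tibble with `pos`, `ref`, `alt` (VCF-style anchored;
#'   length difference 1-27 nt).
#' @param sequence Reference segment string or `fs_reference`.
#' @param frame One frame, `"+1"` (default) ... `"-3"`.
#' @param segment_start As in [call_consequence()].
#' @return `indels` plus `frame`, `effect`, `novel_stop`,
#'   `ref_stop_codon`, `alt_stop_codon` (codon index of the first stop at or
#'   after the edit; `Inf` if none before the segment end).
#' @export
frameshift_scan <- function(indels, sequence, frame = "+1", segment_start = NULL) {
  if (inherits(sequence, "fs_reference")) {
    segment_start <- segment_start %||% sequence$config$segment_start
    sequence <- sequence$sequence
  }
  segment_start <- segment_start %||% 1
  check_cols(indels, c("pos", "ref", "alt"), "indels")
  stopifnot(length(frame) == 1L, frame %in% FRAMES)
  diff <- nchar(indels$alt) - nchar(indels$ref)
  if (any(diff == 0L)) abort("frameshift_scan() expects indels, not substitutions.")
  if (any(abs(diff) > 27L)) abort("indel length difference must be at most 27 nt.")

  seq_fwd <- toupper(sequence)
  len <- nchar(seq_fwd)
  k <- frame_offset(frame)
  minus <- frame_is_minus(frame)

  res <- purrr::map(seq_len(nrow(indels)), function(i) {
    alt_fwd <- apply_variant_to_seq(
      seq_fwd, indels$pos[i], indels$ref[i], indels$alt[i], segment_start
    )
    s_ref <- if (minus) revcomp_dna(seq_fwd) else seq_fwd
    s_alt <- if (minus) revcomp_dna(alt_fwd) else alt_fwd
    # strand offset of the first edited base (for minus, the edit's far end)
    edit_last <- indels$pos[i] + max(nchar(indels$ref[i]), 1L) - 1
    o <- if (minus) {
      strand_offset(edit_last, segment_start, len, TRUE)
    } else {
      indels$pos[i] - segment_start + 1
    }
    codon_start <- k + 3 * floor((o - k) / 3)
    if (codon_start < 1) codon_start <- k
    ref_pep <- translate_dna(substr(s_ref, codon_start, nchar(s_ref)))
    alt_pep <- translate_dna(substr(s_alt, codon_start, nchar(s_alt)))
    tibble(
      ref_stop_codon = first_stop_codon(ref_pep),
      alt_stop_codon = first_stop_codon(alt_pep)
    )
  }) |> bind_rows()

  out <- indels
  out$frame <- frame
  out$effect <- ifelse(diff %% 3L != 0L, "frameshift", "inframe_indel")
  out$ref_stop_codon <- res$ref_stop_codon
  out$alt_stop_codon <- res$alt_stop_codon
  # the mutated stop is "the same stop" as the reference one only when the
  # frame is preserved and its nt offset matches after the indel shift
  strand_diff <- diff # net nt gained on either strand
  same_stop <- diff %% 3L == 0L &
    is.finite(res$ref_stop_codon) & is.finite(res$alt_stop_codon) &
    3 * (res$alt_stop_codon - 1) == 3 * (res$ref_stop_codon - 1) + strand_diff
  out$novel_stop <- is.finite(res$alt_stop_codon) & !same_stop
  out
}
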