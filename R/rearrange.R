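# Putative-translocation modelling: apply a segmental move to a reference
# sequence with an exact coordinate map, predict junction-spanning PCR
# amplicons, and turn amplicon presence/absence into a verdict.

#' Describe a translocation event
#'
#' A fragment `[src_start, src_end]` is excised and re-inserted `shift` bp
#' away (positive = toward the 3' end), optionally inverted. Sequence length
#' is conserved: the bases between source and destination slide over to fill
#' the excision.
#'
#' @param src_start,src_end 1-based inclusive bounds of the moved fragment.
#' @param shift Signed displacement in bp.
#' @param orientation `"forward"` or `"inverted"`.
#' @return A `rearrangement_event` list.
#' @export
#' @examples
#' rearrangement_event(101, 200, shift = 300)
rearrangement_event <- function(src_start, src_end, shift,
                                orientation = c("forward", "inverted")) {
  orientation <- match.arg(orientation)
  check_scalar_number(src_start, "src_start", min = 1)
  check_scalar_number(src_end, "src_end", min = src_start)
  check_scalar_number(shift, "shift")
  structure(
    list(
      src_start = src_start, src_end = src_end,
      shift = shift, orientation = orientation
    ),
    class = "rearrangement_event"
  )
}

#' Apply a rearrangement to a sequence
#'
#' Returns the rearranged sequence together with an exact coordinate map:
#' `map[i]` is the new position of the base originally at position `i`, and
#' `inverse[j]` the original position of the base now at `j`. The map is a
#' permutation of `1:length`, so sequence content is conserved; with
#' `orientation = "inverted"` the moved fragment is reverse-complemented
#' (its bases still map one-to-one, in reversed order).
#'
#' @param sequence Template as a character string (or `fs_reference`, whose
#'   local 1-based coordinates are used).
#' @param event A [rearrangement_event()].
#' @return List of class `fs_rearrangement`: `sequence`, `map`, `inverse`,
#'   `event`.
#' @export
apply_rearrangement <- function(sequence, event) {
  if (inherits(sequence, "fs_reference")) sequence <- sequence$sequence
  stopifnot(inherits(event, "rearrangement_event"))
  n <- nchar(sequence)
  a <- event$src_start
  b <- event$src_end
  if (b > n) abort("source interval outside the sequence.")
  frag_len <- b - a + 1L
  new_start <- a + event$shift
  if (new_start < 1 || new_start + frag_len - 1 > n) {
    abort("destination outside the sequence after excision.")
  }
  if (event$shift > 0 && a + event$shift <= b) {
    abort("destination overlaps the source interval.")
  }
  if (event$shift < 0 && b + event$shift >= a) {
    abort("destination overlaps the source interval.")
  }
  if (event$shift == 0 && event$orientation == "forward") {
    return(structure(
      list(sequence = sequence, map = seq_len(n), inverse = seq_len(n), event = event),
      class = "fs_rearrangement"
    ))
  }
  if (event$shift == 0) { # in-place inversion
    chars <- strsplit(sequence, "")[[1]]
    idx <- seq_len(n)
    idx[a:b] <- b:a
    chars[a:b] <- strsplit(revcomp_dna(paste(chars[a:b], collapse = "")), "")[[1]]
    map <- integer(n)
    map[idx] <- seq_len(n)
    return(structure(
      list(sequence = paste(chars, collapse = ""), map = map, inverse = idx, event = event),
      class = "fs_rearrangement"
    ))
  }

  idx <- seq_len(n) # inverse[j] = original index of new position j
  frag <- a:b
  if (event$shift > 0) {
    mid <- (b + 1L):(b + event$shift) # bases that slide left by frag_len
    idx[a:(a + event$shift - 1L)] <- mid
    idx[(a + event$shift):(a + event$shift + frag_len - 1L)] <-
      if (event$orientation == "inverted") rev(frag) else frag
  } else {
    s <- -event$shift
    mid <- (a - s):(a - 1L) # bases that slide right by frag_len
    idx[(a + event$shift):(a + event$shift + frag_len - 1L)] <-
      if (event$orientation == "inverted") rev(frag) else frag
    idx[(a + event$shift + frag_len):(b)] <- mid
  }
  chars <- strsplit(sequence, "")[[1]]
  new_chars <- chars[idx]
  if (event$orientation == "inverted") {
    moved <- seq.int(a + event$shift, length.out = frag_len)
    new_chars[moved] <- strsplit(
      revcomp_dna(paste(chars[frag], collapse = "")), ""
    )[[1]]
  }
  map <- integer(n)
  map[idx] <- seq_len(n)
  structure(
    list(
      sequence = paste(new_chars, collapse = ""),
      map = map, inverse = idx, event = event
    ),
    class = "fs_rearrangement"
  )
}

#' Predict PCR amplicons by exact primer matching
#'
#' Searches the template for exact matches of the forward primer on the plus
#' strand and of the reverse complement of the reverse primer downstream,
#' and reports every pairing whose product size (from the forward primer's
#' 5' start to the reverse primer's 5' start on the minus strand, inclusive)
#' is at most `max_product`. For each forward match the nearest pairing is
#' flagged; multiple valid pairings are reported and flagged ambiguous.
#'
#' @param sequence Template string (or `fs_reference` / `fs_rearrangement`).
#' @param fwd_seq,rev_seq Primer sequences, 5'->3', at least 15 nt.
#' @param max_product Maximum product size (bp).
#' @return Tibble of class `amplicon_prediction`: `present`, `fwd_pos`,
#'   `rev_pos`, `size`, `nearest`, `ambiguous`. A single all-`NA` row with
#'   `present = FALSE` if no product is predicted.
#' @export
#' @examples
#' tmpl <- paste(rep("ACGT", 25), collapse = "")
#' insilico_pcr(tmpl, substr(tmpl, 1, 20), revcomp_dna(substr(tmpl, 81, 100)), 200)
insilico_pcr <- function(sequence, fwd_seq, rev_seq, max_product = 5000) {
  if (inherits(sequence, "fs_reference")) sequence <- sequence$sequence
  if (inherits(sequence, "fs_rearrangement")) sequence <- sequence$sequence
  fwd_seq <- normalize_dna(fwd_seq)
  rev_seq <- normalize_dna(rev_seq)
  if (nchar(fwd_seq) < 15L || nchar(rev_seq) < 15L) {
    abort("primers must be at least 15 nt.")
  }
  check_scalar_number(max_product, "max_product", min = 1)
  template <- normalize_dna(sequence)
  if (grepl("[^ACGT]", fwd_seq) || grepl("[^ACGT]", rev_seq)) {
    abort("primers must be plain A/C/G/T sequences.")
  }

  fwd_hits <- find_all(template, fwd_seq)
  rev_site <- revcomp_dna(rev_seq)
  rev_hits <- find_all(template, rev_site)

  empty <- tibble(
    present = FALSE, fwd_pos = NA_integer_, rev_pos = NA_integer_,
    size = NA_integer_, nearest = NA, ambiguous = FALSE
  )
  if (length(fwd_hits) == 0L || length(rev_hits) == 0L) {
    class(empty) <- c("amplicon_prediction", class(empty))
    return(empty)
  }
  pairs <- tidyr::expand_grid(fwd_pos = fwd_hits, rev_pos = rev_hits) |>
    mutate(
      rev_end = .data$rev_pos + nchar(rev_site) - 1L,
      size = .data$rev_end - .data$fwd_pos + 1L
    ) |>
    filter(
      .data$rev_pos > .data$fwd_pos + nchar(fwd_seq) - 1L,
      .data$size <= max_product
    )
  if (nrow(pairs) == 0L) {
    class(empty) <- c("amplicon_prediction", class(empty))
    return(empty)
  }
  out <- pairs |>
    group_by(.data$fwd_pos) |>
    mutate(nearest = .data$size == min(.data$size)) |>
    ungroup() |>
    mutate(
      present = TRUE,
      ambiguous = nrow(pairs) > 1L
    ) |>
    select("present", "fwd_pos", "rev_pos", "size", "nearest", "ambiguous") |>
    arrange(.data$fwd_pos, .data$size)
  class(out) <- c("amplicon_prediction", class(out))
  out
}

#' Evaluate a putative translocation from amplicon patterns
#'
#' Runs every junction-spanning and control primer set against the observed
#' template (by default the unrearranged reference, mirroring a bench test
#' of an assembly-predicted event). The event is `refuted` when all junction
#' sets fail to amplify while all controls amplify, `supported` when all
#' junction sets amplify (controls also amplifying), and `inconclusive`
#' otherwise - in particular whenever any control fails, the PCR-failure
#' analogue.
#'
#' @param reference Reference sequence (string or `fs_reference`).
#' @param event Optional [rearrangement_event()]; with
#'   `template = "rearranged"` it is applied to build the observed template.
#' @param junction_primers,control_primers Tibbles with `fwd_seq`,
#'   `rev_seq`, `max_product` and optional `set_id`.
#' @param template Which template is "observed": `"reference"` or
#'   `"rearranged"`.
#' @return List of class `fs_translocation_verdict`: `verdict`
#'   (`supported` / `refuted` / `inconclusive`), `detail` (per-set amplicon
#'   grid), `diagnostic`.
#' @export
evaluate_translocation <- function(reference, event = NULL,
                                   junction_primers, control_primers,
                                   template = c("reference", "rearranged")) {
  template <- match.arg(template)
  if (inherits(reference, "fs_reference")) reference <- reference$sequence
  if (nrow(control_primers) == 0L) abort("at least one control primer set is required.")
  observed <- if (template == "rearranged") {
    if (is.null(event)) abort("`event` is needed for template = \"rearranged\".")
    apply_rearrangement(reference, event)$sequence
  } else {
    reference
  }
  run_sets <- function(sets, role) {
    if (is.null(sets$set_id)) sets$set_id <- sprintf("%s_%d", role, seq_len(nrow(sets)))
    purrr::pmap(sets, function(set_id, fwd_seq, rev_seq, max_product, ...) {
      amp <- insilico_pcr(observed, fwd_seq, rev_seq, max_product)
      tibble(
        set_id = set_id, role = role, present = any(amp$present),
        size = if (any(amp$present)) min(amp$size[amp$present]) else NA_integer_
      )
    }) |> bind_rows()
  }
  detail <- bind_rows(
    run_sets(junction_primers, "junction"),
    run_sets(control_primers, "control")
  )
  controls_ok <- all(detail$present[detail$role == "control"])
  junction_present <- detail$present[detail$role == "junction"]
  verdict <- if (!controls_ok) {
    "inconclusive"
  } else if (length(junction_present) > 0L && all(junction_present)) {
    "supported"
  } else if (length(junction_present) > 0L && all(!junction_present)) {
    "refuted"
  } else {
    "inconclusive"
  }
  diagnostic <- if (!controls_ok) {
    "control amplification failed (PCR-failure analogue); junction results not interpretable"
  } else {
    NA_character_
  }
  structure(
    list(verdict = verdict, detail = detail, diagnostic = diagnostic),
    class = "fs_translocation_verdict"
  )
}

#' Default translocation event fixtures
#'
#' The two assembly-predicted events modelled by the package, scaled down
#' 100-fold for fast tests: a 537 bp fragment moved +2,581 bp and a 73 bp
#' fragment moved +3,404 bp.
#'
#' @param scale Divisor applied to the full-size events (default 100).
#' @return List of two [rearrangement_event()]s.
#' @export
default_translocation_events <- function(scale = 100) {
  list(
    large = rearrangement_event(
      src_start = 1001, src_end = 1000 + round(53749 / scale),
      shift = round(258103 / scale)
    ),
    small = rearrangement_event(
      src_start = 2001, src_end = 2000 + round(7345 / scale),
      shift = round(340463 / scale)
    )
  )
}
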