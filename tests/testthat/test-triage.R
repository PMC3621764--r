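# Variant classification, the elimination cascade, and summary statistics.

vt <- function(pos, ref, alt, zygosity = "hemi", chrom = "Z", end = NULL) {
  d <- tibble::tibble(chrom = chrom, pos = pos, ref = ref, alt = alt, zygosity = zygosity)
  if (!is.null(end)) d$end <- end
  d
}

test_that("size rules assign variant classes", {
  v <- classify_variants(tibble::tibble(
    chrom = "Z", pos = c(10, 20, 30, 40, 50),
    ref = c("A", "ATTT", "ATTTT", "A", "A"),
    alt = c("G", "A", "A", "ATT", "AGGGGGGGGGG"),
    end = NA
  ))
  expect_equal(v$vclass, c("snp", "micro_deletion", "macro_indel", "micro_insertion", "macro_indel"))
  # uncaptured interval of 52 nt is a gap
  g <- classify_variants(tibble::tibble(
    chrom = "Z", pos = 100, ref = ".", alt = "", end = 151
  ))
  expect_equal(g$vclass, "gap")
  expect_error(
    classify_variants(tibble::tibble(chrom = "Z", pos = 1, ref = "AT", alt = "GC")),
    "equal-length"
  )
  expect_error(
    classify_variants(tibble::tibble(
      chrom = "Z", pos = 1, ref = paste(rep("A", 30), collapse = ""), alt = "A"
    )),
    "27"
  )
  expect_error(
    classify_variants(tibble::tibble(chrom = "Z", pos = 1, ref = ".", alt = "", end = 3)),
    "gap"
  )
})

test_that("hemizygosity filter eliminates exactly the heterozygous calls", {
  v <- vt(seq_len(2500), "A", "G",
    zygosity = rep(c("hom", "het"), c(2156, 344))
  )
  out <- zygosity_filter(v)
  expect_equal(sum(out$status == "retained_unique"), 2156)
  expect_equal(sum(out$status == "eliminated"), 344)
  expect_true(all(out$reason[out$status == "eliminated"] ==
    "heterozygous_in_hemizygous_region"))
  # flag off: pass-through; empty input: empty output
  expect_true(all(zygosity_filter(v, FALSE)$status == "retained_unique"))
  expect_equal(nrow(zygosity_filter(v[0, ])), 0L)
})

test_that("uniqueness filter keeps the set difference against other lines", {
  focal <- vt(1:538, "A", "G")
  other <- dplyr::mutate(focal[1:293, ], line_id = "control_1")
  out <- uniqueness_filter(focal, other)
  expect_equal(sum(out$status == "retained_unique"), 245)
  expect_true(all(out$reason[out$status == "eliminated"] == "shared_with_line:control_1"))
  # nothing to match -> all retained
  expect_true(all(uniqueness_filter(focal)$status == "retained_unique"))
  # previously reported set eliminates too
  known <- focal[500:538, ]
  out2 <- uniqueness_filter(focal, known = known)
  expect_equal(sum(out2$reason %in% "previously_reported"), 39)
})

test_that("uniqueness filter equals a brute-force set-difference oracle", {
  set.seed(77)
  for (rep in 1:20) {
    focal <- vt(sample(1:400, 60), sample(c("A", "C"), 60, TRUE), "G")
    oth <- dplyr::bind_rows(
      dplyr::mutate(dplyr::slice_sample(focal, n = 25), line_id = "l1"),
      dplyr::mutate(
        vt(sample(1:400, 30), sample(c("A", "C"), 30, TRUE), "G"),
        line_id = "l2"
      )
    )
    out <- uniqueness_filter(focal, oth)
    # naive O(n*m) comparison
    shared <- logical(nrow(focal))
    for (i in seq_len(nrow(focal))) {
      for (j in seq_len(nrow(oth))) {
        if (focal$pos[i] == oth$pos[j] && focal$ref[i] == oth$ref[j] &&
          focal$alt[i] == oth$alt[j]) {
          shared[i] <- TRUE
        }
      }
    }
    expect_equal(out$status == "eliminated", shared)
  }
})

test_that("duplicate focal records are de-duplicated with a warning", {
  focal <- vt(c(1, 1, 2), "A", "G")
  expect_warning(out <- uniqueness_filter(focal), "duplicate")
  expect_equal(nrow(out), 2L)
})

test_that("gaps are never shared-eliminated, only flagged for validation", {
  focal <- classify_variants(tibble::tibble(
    chrom = "Z", pos = c(100, 300), ref = ".", alt = "", end = c(150, 360)
  ))
  other <- dplyr::mutate(focal[1, ], line_id = "lineB")
  out <- uniqueness_filter(focal, other)
  expect_true(all(out$status == "retained_unique"))
  expect_equal(out$needs_validation, c(TRUE, FALSE))
})

test_that("region filter uses the (start, end] convention", {
  v <- vt(c(21628290, 21628291, 21700000, 21804206, 21804207), "A", "G")
  out <- region_filter(v, 21628290, 21804206)
  expect_equal(out$status, c(
    "eliminated", "retained_unique", "retained_unique",
    "retained_unique", "eliminated"
  ))
  expect_true(all(out$reason[out$status == "eliminated"] == "outside_region"))
  # brute-force containment oracle on random sets
  set.seed(12)
  v2 <- vt(sample(1:1000, 200), "A", "G")
  out2 <- region_filter(v2, 250, 750)
  expect_equal(
    sum(out2$status == "retained_unique"),
    sum(v2$pos > 250 & v2$pos <= 750)
  )
})

test_that("cascade verdicts are exhaustive, exclusive, and order-invariant", {
  set.seed(99)
  n <- 200
  focal <- classify_variants(vt(
    sample(1:5000, n),
    "A", "G",
    zygosity = sample(c("hom", "het", "hemi"), n, TRUE)
  ))
  others <- dplyr::mutate(dplyr::slice_sample(focal, n = 80), line_id = "c1")
  res <- triage_cascade(focal, others, region = c(1000, 4000))
  v <- res$verdicts
  expect_equal(nrow(v), n)
  expect_true(all(v$status %in% c("retained_unique", "eliminated")))
  expect_true(all(is.na(v$reason) == (v$status == "retained_unique")))
  # retained set equals the intersection of the three independent predicates
  keep_z <- zygosity_filter(focal)$status == "retained_unique"
  keep_u <- uniqueness_filter(focal, others)$status == "retained_unique"
  keep_r <- region_filter(focal, 1000, 4000)$status == "retained_unique"
  expect_equal(v$status == "retained_unique", keep_z & keep_u & keep_r)
  # audit covers every variant and sums agree
  expect_equal(nrow(res$audit), n)
  expect_equal(
    sum(res$counts$retained_unique, na.rm = TRUE) +
      sum(res$counts$eliminated, na.rm = TRUE), n
  )
})

test_that("summary statistics reproduce the count arithmetic", {
  # 1,454 transitions + 1,046 transversions -> ratio 1.39.., printed 1.4
  ts <- vt(1:1454, "A", "G")
  tv <- vt(1455:2500, "A", "C")
  s <- summarize_variants(dplyr::bind_rows(ts, tv), region_span_bp = 990267)
  expect_equal(s$ts_count, 1454)
  expect_equal(s$tv_count, 1046)
  expect_equal(round(s$tstv_ratio, 1), 1.4)
  expect_false(s$tstv_undefined)

  # 32 micro-indels over 175,915 bp -> 0.18 per kb
  micro <- tibble::tibble(
    chrom = "Z", pos = seq(1000, by = 5000, length.out = 32),
    ref = "AT", alt = "A"
  )
  s2 <- summarize_variants(micro, 175915)
  expect_equal(round(s2$indel_density_per_kb, 2), 0.18)
  expect_equal(s2$mean_indel_size, 1)
  expect_equal(s2$mean_indel_spacing, 5000)

  # degenerate cases flag rather than throw
  one <- summarize_variants(micro[1, ], 1000)
  expect_true(one$indel_spacing_undefined)
  expect_true(is.na(one$mean_indel_spacing))
  s3 <- summarize_variants(vt(1:5, "A", "G"), 1000)
  expect_true(s3$tstv_undefined)
  expect_true(is.na(s3$tstv_ratio))

  # gap statistics
  gaps <- classify_variants(tibble::tibble(
    chrom = "Z", pos = c(100, 1000, 5000), ref = ".", alt = "",
    end = c(151, 1003, 5633)
  ))
  s4 <- summarize_variants(gaps, 10000)
  expect_equal(s4$gap_count, 3)
  expect_equal(s4$mean_gap_size, mean(c(52, 4, 634)))
  expect_equal(s4$gap_size_min, 4)
  expect_equal(s4$gap_size_max, 634)
})

test_that("triage tidiers and plot expose the cascade", {
  focal <- classify_variants(vt(1:20, "A", "G",
    zygosity = rep(c("hom", "het"), 10)
  ))
  res <- triage_cascade(focal, region = c(0, 15))
  g <- glance(res)
  expect_equal(g$n_input, 20)
  expect_equal(g$n_het_eliminated, 10)
  expect_s3_class(tidy(res), "tbl_df")
  expect_s3_class(autoplot(res), "ggplot")
})
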