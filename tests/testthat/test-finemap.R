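# Linkage assignment, interval inference, consensus, and recombination
# statistics.

panel <- study_marker_panel()

geno_row <- function(individual, class, calls) {
  tibble::tibble(
    individual = individual, class = class,
    marker = panel$marker, call = calls
  )
}

test_that("linkage rules match the genotype-table conventions", {
  # hemizygous mutant: T at the G/T locus (mutant allele) is linked,
  # the normal allele is recombined, missing is uninformative
  gt <- geno_row("m1", "mutant", c(
    "A", "T", "G", "G", "A", "A", "G", "A", "A", "A", "T", "C", NA, "A", "A"
  ))
  st <- assign_linkage(gt, panel)
  expect_equal(st$status[st$marker == "rs14754601"], "linked")
  expect_equal(st$status[st$marker == "rs16101051"], "recombined")
  expect_equal(st$status[st$marker == "rs16762348"], "uninformative")

  # carrier: het containing the mutant allele is linked, homozygous normal
  # is recombined
  gt2 <- geno_row("c1", "carrier", c(
    "GA", "GT", "AA", rep("AG", 2), "CA", "AG", "GA", "GG", "GA", "CT",
    "CC", "AA", "AA", "AA"
  ))
  st2 <- assign_linkage(gt2, panel)
  expect_equal(st2$status[st2$marker == "rs16101051"], "linked")
  expect_equal(st2$status[st2$marker == "rs14754601"], "linked")
  expect_equal(st2$status[st2$marker == "rs16761892"], "recombined")
  expect_equal(st2$status[st2$marker == "rs16102103"], "recombined")

  # normal individuals are uninformative everywhere
  gt3 <- geno_row("n1", "normal", paste0(panel$normal_allele, panel$normal_allele))
  expect_true(all(assign_linkage(gt3, panel)$status == "uninformative"))
})

test_that("alleles outside the locus alphabet raise a data error naming the locus", {
  gt <- geno_row("m1", "mutant", c(
    "C", "T", "G", "G", "A", "A", "G", "A", "A", "A", "T", "C", "A", "A", "A"
  ))
  expect_error(assign_linkage(gt, panel), "rs16101051")
})

test_that("deleted calls in hemizygotes follow the founder deletion state", {
  pan <- panel
  pan$mutant_is_deletion[5] <- TRUE
  calls <- c("A", "T", "G", "G", "-", "A", "G", "A", "A", "A", "T", "C", "A", "A", "A")
  st <- assign_linkage(geno_row("m1", "mutant", calls), pan)
  expect_equal(st$status[st$marker == "rs14755033"], "linked")
  st2 <- assign_linkage(geno_row("m1", "mutant", calls), panel)
  expect_equal(st2$status[st2$marker == "rs14755033"], "uninformative")
})

test_that("interval formulas follow the span conventions", {
  # single linked marker flanked at +-1,000 bp -> cr_min 0, cr_max 1,998
  mk <- tibble::tibble(
    marker = c("a", "b", "c"), chrom = "Z", pos = c(9000, 10000, 11000),
    normal_allele = "A", mutant_allele = "G"
  )
  gt <- tibble::tibble(
    individual = "m", class = "mutant",
    marker = mk$marker, call = c("A", "G", "A")
  )
  iv <- infer_interval(assign_linkage(gt, mk))
  expect_equal(iv$cr_min, 0)
  expect_equal(iv$cr_max, 1998)
  expect_false(iv$edge_allowance_used)

  # missing distal flank -> edge allowance
  gt2 <- tibble::tibble(
    individual = "m", class = "mutant",
    marker = mk$marker, call = c("A", "G", "G")
  )
  iv2 <- infer_interval(assign_linkage(gt2, mk), edge_allowance = 500001)
  expect_equal(iv2$cr_max, iv2$cr_min + 500001)
  expect_true(iv2$edge_allowance_used)

  # no linked marker: error by default, droppable on request
  gt3 <- tibble::tibble(
    individual = "x", class = "mutant",
    marker = mk$marker, call = c("A", "A", "A")
  )
  expect_error(infer_interval(assign_linkage(gt3, mk)), "no linked marker")
})

test_that("uninformative markers are transparent inside a linked run", {
  mk <- tibble::tibble(
    marker = letters[1:5], chrom = "Z", pos = c(1, 2, 3, 4, 5) * 1000,
    normal_allele = "A", mutant_allele = "G"
  )
  gt <- tibble::tibble(
    individual = "m", class = "mutant",
    marker = mk$marker, call = c("A", "G", NA, "G", "A")
  )
  iv <- infer_interval(assign_linkage(gt, mk))
  expect_equal(iv$inner_left, 2000)
  expect_equal(iv$inner_right, 4000)
  expect_equal(iv$n_linked_runs, 1L)
})

test_that("multiple linked runs resolve to the largest, and anchoring overrides", {
  mk <- tibble::tibble(
    marker = letters[1:7], chrom = "Z", pos = (1:7) * 1000,
    normal_allele = "A", mutant_allele = "G"
  )
  gt <- tibble::tibble(
    individual = "m", class = "mutant",
    marker = mk$marker, call = c("G", "G", "G", "A", "G", "G", "A")
  )
  st <- assign_linkage(gt, mk)
  iv <- infer_interval(st)
  expect_equal(c(iv$inner_left, iv$inner_right), c(1000, 3000))
  expect_equal(iv$n_linked_runs, 2L)
  iv_anchor <- infer_interval(st, anchor = 5500)
  expect_equal(c(iv_anchor$inner_left, iv_anchor$inner_right), c(5000, 6000))
  # anchor incompatible with any run behaves like no linked marker
  expect_error(infer_interval(st, anchor = 7500), "anchor")
})

test_that("infer_interval matches the brute-force oracle on random status vectors", {
  set.seed(404)
  pos <- sort(sample(1:1e6, 12))
  for (i in 1:300) {
    status <- sample(c("linked", "recombined", "uninformative"), 12,
      replace = TRUE, prob = c(0.5, 0.3, 0.2)
    )
    ora <- oracle_interval(pos, status)
    st <- tibble::tibble(
      individual = "x", chrom = "Z", pos = pos, status = status
    )
    if (is.null(ora)) {
      expect_error(infer_interval(st))
    } else {
      iv <- infer_interval(st)
      expect_equal(iv$cr_min, ora$cr_min)
      expect_equal(iv$cr_max, ora$cr_max)
      expect_equal(iv$inner_left, ora$inner_left)
      expect_equal(iv$outer_left, ora$outer_left)
    }
  }
})

test_that("consensus of one individual is that individual's interval", {
  gt <- study_genotype_profiles()
  iv <- infer_interval(assign_linkage(gt, panel))
  one <- iv[iv$individual == "co-276F", ]
  cons <- consensus_interval(one)
  expect_equal(cons$cr_min, one$cr_min)
  expect_equal(cons$cr_max, one$cr_max)
})

test_that("adding individuals never widens the consensus", {
  cfg <- small_config(seed = 11, recomb_rate = 40)
  f <- sim_founders(cfg)
  g <- simulate_cohort(cfg, f)
  st <- assign_linkage(dplyr::filter(g, class != "normal"), f$markers)
  iv <- infer_interval(st, anchor = cfg$causative_position, on_no_linked = "drop")
  prev <- Inf
  for (n in seq_len(nrow(iv))) {
    cons <- consensus_interval(iv[seq_len(n), ])
    expect_lte(cons$cr_max, prev)
    prev <- cons$cr_max
  }
  expect_lte(cons$cr_max, min(iv$cr_max))
})

test_that("disjoint evidence raises an inconsistency error naming individuals", {
  iv <- tibble::tibble(
    individual = c("a", "b"), chrom = "Z",
    inner_left = c(1000, 9000), inner_right = c(2000, 9500),
    outer_left = c(500, 8000), outer_right = c(3000, 9900),
    cr_min = c(1000, 500), cr_max = c(2498, 1898),
    edge_allowance_used = FALSE, n_linked_runs = 1L
  )
  expect_error(consensus_interval(iv), "disjoint.*a.*b")
  expect_error(consensus_interval(iv[0, ]), "zero")
})

test_that("bracketing recombinants yield an empty inner but valid outer interval", {
  mk <- tibble::tibble(
    marker = letters[1:4], chrom = "Z", pos = (1:4) * 1000,
    normal_allele = "A", mutant_allele = "G"
  )
  gt <- dplyr::bind_rows(
    tibble::tibble(
      individual = "left", class = "mutant",
      marker = mk$marker, call = c("G", "G", "A", "A")
    ),
    tibble::tibble(
      individual = "right", class = "mutant",
      marker = mk$marker, call = c("A", "A", "G", "G")
    )
  )
  iv <- infer_interval(assign_linkage(gt, mk))
  cons <- consensus_interval(iv)
  expect_true(cons$inner_empty)
  expect_equal(cons$cr_min, 0)
  expect_equal(cons$outer_left, 2000)
  expect_equal(cons$outer_right, 3000)
  expect_equal(cons$cr_max, 3000 - 2000 - 2)
})

test_that("region spans follow the printed end - start convention", {
  expect_equal(region_span(20813939, 21804206), 990267)
  expect_equal(region_span(21628291, 21804206), 175915)
  expect_equal(region_span(5, 5), 0)
  expect_equal(region_length(101, 200), 100)
  expect_error(region_span(10, 5), ">=")
})

test_that("recombination statistics match closed forms", {
  # no recombinants: LOD = N log10 2
  r0 <- recomb_stats(0, 100, 1)
  expect_equal(r0$theta, 0)
  expect_equal(r0$lod, 100 * log10(2), tolerance = 1e-12)

  r <- recomb_stats(10, 263, 1.004)
  expect_equal(r$theta, 10 / 263)
  expect_equal(r$cm_per_mb, 100 * (10 / 263) / 1.004)
  expect_equal(r$morgans_per_mb, r$cm_per_mb / 100)
  manual <- 10 * log10(10 / 263) + 253 * log10(1 - 10 / 263) - 263 * log10(0.5)
  expect_equal(r$lod, manual)

  # at fixed theta, LOD is linear in N
  expect_equal(recomb_stats(20, 526, 1.004)$lod, 2 * r$lod, tolerance = 1e-9)

  expect_error(recomb_stats(5, 4, 1), "exceed")
  expect_warning(recomb_stats(3, 4, 1), "0.5")
})

test_that("tidiers expose recombination and interval summaries", {
  r <- recomb_stats(10, 263, 1.004)
  td <- tidy(r)
  expect_setequal(td$term, c("theta", "cm_per_mb", "morgans_per_mb", "lod"))
  expect_equal(glance(r)$lod, r$lod)
  iv <- infer_interval(assign_linkage(study_genotype_profiles(), panel))
  expect_s3_class(autoplot(iv), "ggplot")
  expect_equal(glance(iv)$n_individuals, 2L)
})
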