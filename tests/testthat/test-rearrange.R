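# Translocation modelling and in-silico PCR.

test_that("a forward move relocates bases and conserves length and content", {
  set.seed(41)
  s <- random_seq(1000)
  ev <- rearrangement_event(101, 200, shift = 300)
  out <- apply_rearrangement(s, ev)
  expect_equal(nchar(out$sequence), 1000L)
  expect_equal(out$map[101], 401L)
  expect_equal(out$map[200], 500L)
  expect_equal(substr(out$sequence, 401, 500), substr(s, 101, 200))
  expect_equal(
    sort(strsplit(out$sequence, "")[[1]]),
    sort(strsplit(s, "")[[1]])
  )
})

test_that("zero shift is the identity", {
  s <- random_seq(200)
  out <- apply_rearrangement(s, rearrangement_event(50, 80, 0))
  expect_identical(out$sequence, s)
  expect_identical(out$map, seq_len(200L))
})

test_that("map and inverse are a bijection round-trip on random events", {
  set.seed(42)
  for (i in 1:40) {
    n <- sample(300:800, 1)
    s <- random_seq(n)
    a <- sample(1:(n - 120), 1)
    b <- a + sample(10:80, 1)
    max_right <- n - b
    max_left <- a - 1
    shift <- if (runif(1) < 0.5 && max_right > b - a + 1) {
      sample((b - a + 1):max_right, 1)
    } else if (max_left > b - a + 1) {
      -sample((b - a + 1):max_left, 1)
    } else {
      next
    }
    ori <- sample(c("forward", "inverted"), 1)
    out <- apply_rearrangement(s, rearrangement_event(a, b, shift, ori))
    expect_identical(out$map[out$inverse], seq_len(n))
    expect_identical(out$inverse[out$map], seq_len(n))
    if (ori == "forward") {
      # content conserved as a multiset (inversion complements the fragment)
      expect_equal(
        sort(strsplit(out$sequence, "")[[1]]),
        sort(strsplit(s, "")[[1]])
      )
    }
    # outside the moved/slid region the sequence is untouched
    untouched <- setdiff(seq_len(n), min(a, a + shift):max(b, b + shift))
    expect_identical(out$map[untouched], untouched)
  }
})

test_that("inversion reverse-complements the moved fragment", {
  s <- random_seq(500)
  ev <- rearrangement_event(101, 150, shift = 200, orientation = "inverted")
  out <- apply_rearrangement(s, ev)
  expect_equal(substr(out$sequence, 301, 350), revcomp_dna(substr(s, 101, 150)))
})

test_that("out-of-bounds and overlapping events error", {
  s <- random_seq(300)
  expect_error(apply_rearrangement(s, rearrangement_event(250, 320, 10)), "outside")
  expect_error(apply_rearrangement(s, rearrangement_event(100, 150, 500)), "outside")
  expect_error(apply_rearrangement(s, rearrangement_event(100, 150, 20)), "overlap")
})

test_that("the scaled default events apply cleanly", {
  s <- random_seq(10000)
  for (ev in default_translocation_events()) {
    out <- apply_rearrangement(s, ev)
    expect_equal(nchar(out$sequence), 10000L)
  }
})

test_that("an end-to-end template amplifies at its full length", {
  set.seed(43)
  s <- random_seq(100)
  amp <- insilico_pcr(s, substr(s, 1, 20), revcomp_dna(substr(s, 81, 100)), 200)
  expect_true(amp$present[1])
  expect_equal(amp$size[1], 100L)
  expect_equal(amp$fwd_pos[1], 1L)
})

test_that("junction primers amplify only on the rearranged template", {
  set.seed(44)
  s <- random_seq(2000)
  ev <- rearrangement_event(301, 400, shift = 600)
  re <- apply_rearrangement(s, ev)
  junction <- 301 + 600 # new start of the moved fragment
  fwd <- substr(re$sequence, junction - 60, junction - 41)
  rev <- revcomp_dna(substr(re$sequence, junction + 41, junction + 60))
  expect_false(insilico_pcr(s, fwd, rev, 500)$present[1])
  expect_true(insilico_pcr(re$sequence, fwd, rev, 500)$present[1])
})

test_that("amplicon predictions match a naive search oracle", {
  set.seed(45)
  for (i in 1:25) {
    s <- random_seq(400)
    f_at <- sample(1:300, 1)
    r_at <- sample(1:350, 1)
    fwd <- substr(s, f_at, f_at + 17)
    rev <- revcomp_dna(substr(s, r_at, r_at + 17))
    maxp <- sample(c(50, 150, 400), 1)
    got <- insilico_pcr(s, fwd, rev, maxp)
    ora <- oracle_pcr(s, fwd, rev, maxp)
    if (is.null(ora)) {
      expect_false(any(got$present))
    } else {
      expect_true(any(got$present))
      best <- got[got$nearest %in% TRUE, ][1, ]
      expect_equal(best$size, ora$size)
      expect_equal(best$fwd_pos, ora$fwd)
    }
  }
})

test_that("primer validation rejects short or non-DNA primers", {
  s <- random_seq(100)
  expect_error(insilico_pcr(s, "ACGTACGT", substr(s, 50, 70)), "15")
  expect_error(insilico_pcr(s, paste(rep("N", 20), collapse = ""), substr(s, 50, 70)), "A/C/G/T")
})

test_that("translocation verdicts follow the control-gated logic", {
  set.seed(46)
  s <- random_seq(3000)
  ev <- rearrangement_event(501, 700, shift = 900)
  re <- apply_rearrangement(s, ev)
  junction <- 501 + 900
  junction_primers <- tibble::tibble(
    set_id = "j1",
    fwd_seq = substr(re$sequence, junction - 50, junction - 31),
    rev_seq = revcomp_dna(substr(re$sequence, junction + 31, junction + 50)),
    max_product = 300
  )
  control_primers <- tibble::tibble(
    set_id = "c1",
    fwd_seq = substr(s, 2500, 2519),
    rev_seq = revcomp_dna(substr(s, 2600, 2619)),
    max_product = 300
  )
  # observed template is the reference: junctions absent, controls present
  ref_verdict <- evaluate_translocation(s, ev, junction_primers, control_primers)
  expect_equal(ref_verdict$verdict, "refuted")
  # observed template actually rearranged: everything amplifies
  alt_verdict <- evaluate_translocation(
    s, ev, junction_primers, control_primers,
    template = "rearranged"
  )
  expect_equal(alt_verdict$verdict, "supported")
  # failing control makes the test inconclusive regardless of junctions
  bad_control <- tibble::tibble(
    set_id = "c_bad",
    fwd_seq = paste(rep("A", 20), collapse = ""),
    rev_seq = paste(rep("C", 20), collapse = ""),
    max_product = 300
  )
  inc <- evaluate_translocation(s, ev, junction_primers, bad_control)
  expect_equal(inc$verdict, "inconclusive")
  expect_match(inc$diagnostic, "control")
  expect_error(
    evaluate_translocation(s, ev, junction_primers, control_primers[0, ]),
    "control"
  )
})
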