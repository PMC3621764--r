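# Synthetic-data generator: determinism, structural invariants, and
# conservation of requested variant loads.

test_that("identical configs give byte-identical outputs", {
  cfg <- small_config(seed = 42)
  r1 <- sim_reference(cfg)
  r2 <- sim_reference(cfg)
  expect_identical(r1$sequence, r2$sequence)
  expect_identical(r1$features, r2$features)
  f1 <- sim_founders(cfg)
  expect_identical(f1, sim_founders(cfg))
  g1 <- simulate_cohort(cfg, f1)
  g2 <- simulate_cohort(cfg, f1)
  expect_identical(as.data.frame(g1), as.data.frame(g2))
  p1 <- plant_variants(cfg, f1, r1)
  p2 <- plant_variants(cfg, f1, r1)
  expect_identical(p1$truth, p2$truth)
})

test_that("degenerate GC fractions drive base composition", {
  cfg <- small_config(seed = 5, gc_fraction = 1)
  ref <- sim_reference(cfg)
  expect_match(ref$sequence, "^[GC]+$")
  cfg0 <- small_config(seed = 5, gc_fraction = 0)
  expect_match(sim_reference(cfg0)$sequence, "^[AT]+$")
})

test_that("default gene models reproduce the published footprint and pass invariants", {
  ref <- sim_reference(sim_config(seed = 2))
  expect_equal(nrow(ref$genes), 4L)
  spans <- ref$genes$tx_end - ref$genes$tx_start + 1
  # relative spans of the first two genes: 20,461 vs 6,173 bp
  expect_equal(spans[1], 20461)
  expect_equal(spans[2], 6173)
  for (gid in ref$genes$gene_id) {
    f <- dplyr::filter(ref$features, gene_id == gid)
    ex <- dplyr::filter(f, feature == "exon") |> dplyr::arrange(start)
    expect_gte(nrow(ex), 2L)
    if (nrow(ex) > 1) expect_true(all(ex$start[-1] > ex$end[-nrow(ex)]))
    cds_len <- sum(dplyr::filter(f, feature == "CDS")$end -
      dplyr::filter(f, feature == "CDS")$start + 1)
    expect_identical(cds_len %% 3, 0)
    expect_equal(nrow(dplyr::filter(f, feature == "five_prime_UTR")), 1L)
    expect_equal(nrow(dplyr::filter(f, feature == "three_prime_UTR")), 1L)
  }
  # genes do not overlap
  g <- dplyr::arrange(ref$genes, tx_start)
  expect_true(all(g$tx_start[-1] > g$tx_end[-nrow(g)]))
})

test_that("a segment too short for the requested genes errors", {
  cfg <- sim_config(
    seed = 1, segment_start = 1, segment_length = 2000,
    causative_position = 1000
  )
  expect_error(sim_reference(cfg), "too short")
})

test_that("default founder panel is the published 15-marker panel", {
  f <- sim_founders(sim_config(seed = 9))
  expect_equal(nrow(f$markers), 15L)
  expect_equal(f$markers$pos[1], 20800461)
  expect_equal(f$markers$pos[15], 21995335)
  expect_true(all(f$markers$normal_allele != f$markers$mutant_allele))
  expect_true(f$causative$is_causative)
})

test_that("zero recombination rate gives zero recombinant chromosomes", {
  cfg <- small_config(seed = 3, recomb_rate = 0)
  g <- simulate_cohort(cfg, sim_founders(cfg))
  expect_equal(sum(cohort_meiosis(g)$recombinant), 0L)
  # and every mutant is fully linked
  st <- assign_linkage(dplyr::filter(g, class == "mutant"), sim_founders(cfg)$markers)
  expect_true(all(st$status == "linked"))
})

test_that("cohort classes have the expected call shapes", {
  cfg <- small_config(seed = 4)
  f <- sim_founders(cfg)
  g <- simulate_cohort(cfg, f)
  expect_true(all(nchar(g$call[g$class == "mutant"]) == 1))
  expect_true(all(nchar(g$call[g$class == "carrier"]) == 2))
  normals <- dplyr::filter(g, class == "normal") |>
    dplyr::left_join(f$markers, by = c("marker", "chrom", "pos"))
  expect_true(all(normals$call == paste0(normals$normal_allele, normals$normal_allele)))
})

test_that("planted variant truth conserves the requested counts", {
  cfg <- small_config(seed = 6)
  pv <- plant_variants(cfg, sim_founders(cfg))
  got <- pv$truth |>
    dplyr::mutate(vclass = sub("micro_(insertion|deletion)", "micro_indel", vclass)) |>
    dplyr::count(vclass, status) |>
    tidyr::pivot_wider(names_from = status, values_from = n, values_fill = 0L)
  want <- cfg$variant_counts
  for (cl in want$vclass) {
    expect_equal(got$shared[got$vclass == cl],
      want$shared[want$vclass == cl],
      ignore_attr = TRUE
    )
    expect_equal(got$unique[got$vclass == cl],
      want$unique[want$vclass == cl],
      ignore_attr = TRUE
    )
  }
  expect_equal(sum(pv$truth$is_causative), 1L)
  expect_equal(pv$truth$pos[pv$truth$is_causative], cfg$causative_position)
  # class size bounds
  sz <- abs(nchar(pv$truth$alt) - nchar(pv$truth$ref))
  expect_true(all(sz[pv$truth$vclass %in% c("micro_insertion", "micro_deletion")] %in% 1:3))
  expect_true(all(sz[pv$truth$vclass == "macro_indel"] %in% 4:27))
  glen <- pv$truth$end - pv$truth$pos + 1
  expect_true(all(glen[pv$truth$vclass == "gap"] >= 4))
  # shared variants appear identically in at least one control line
  shared <- dplyr::filter(pv$truth, status == "shared")
  expect_true(all(grepl("control_", shared$lines)))
})

test_that("triage on emitted tables recovers exactly the planted uniques", {
  cfg <- small_config(seed = 8)
  pv <- plant_variants(cfg, sim_founders(cfg))
  focal <- dplyr::filter(pv$variants, line_id == "focal", vclass != "gap")
  controls <- dplyr::filter(pv$variants, line_id != "focal")
  verdict <- uniqueness_filter(focal, controls)
  truth_unique <- dplyr::filter(pv$truth, status == "unique", vclass != "gap")
  expect_equal(
    sum(verdict$status == "retained_unique"),
    nrow(truth_unique)
  )
  expect_setequal(
    verdict$pos[verdict$status == "retained_unique"],
    truth_unique$pos
  )
})

test_that("planted micro-insertions classify as micro_insertion downstream", {
  cfg <- small_config(seed = 10)
  pv <- plant_variants(cfg, sim_founders(cfg))
  ins <- dplyr::filter(pv$truth, vclass == "micro_insertion")
  reclass <- classify_variants(dplyr::select(ins, chrom, pos, end, ref, alt))
  expect_true(all(reclass$vclass == "micro_insertion"))
})

test_that("overcrowded segments fail placement with a clear error", {
  cfg <- sim_config(
    seed = 1, segment_start = 1, segment_length = 400,
    n_markers = 2, causative_position = 200,
    variant_counts = tibble::tibble(
      vclass = "snp", shared = 0L, unique = 300L
    ),
    genes = tibble::tibble(
      gene_id = "g1", start = 10, end = 390, strand = "+"
    )
  )
  expect_error(plant_variants(cfg, sim_founders(cfg)), "fit|overlap|crowded")
})
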