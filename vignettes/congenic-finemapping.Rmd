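---
title: "Fine-mapping a congenic introgression and triaging its variants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fine-mapping a congenic introgression and triaging its variants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(finescan)
library(dplyr)
```

## The problem

A congenic line carries a small donor-derived chromosomal block — an
introgression — on an otherwise inbred background. When that block harbours a
recessive mutation, every affected individual must have inherited the mutant
haplotype at the causative locus, and every crossover observed within the
block trims the interval that can still contain it. `finescan` implements
this fine-mapping logic for a Z-linked design (female birds are hemizygous
ZW, so affected females carry a single Z allele at every locus), together
with the downstream triage of the sequence variants found inside the mapped
interval: a hemizygosity filter, a multi-line uniqueness filter, a region
filter, gene-feature annotation with six-reading-frame consequence calls,
microRNA seed-site scanning of 3' UTRs, and in-silico PCR evaluation of
assembly-predicted rearrangements.

## Interval inference

`assign_linkage()` classifies each (individual, marker) genotype call against
the founder alleles. A hemizygous mutant is *linked* at a marker where its
single allele is the mutant-haplotype allele and *recombined* where it shows
the normal-background allele; a heterozygous carrier is linked where it is
heterozygous containing the mutant allele and recombined where it is
homozygous normal. Missing calls, loci with identical founder alleles, and
non-carrier individuals are *uninformative*; uninformative markers never
break a linked run. A deletion call (`"-"`) in a hemizygote is linked only
when the founder mutant haplotype is recorded as deleting that locus.

`infer_interval()` reduces each individual's status vector to two nested
intervals:

* the **minimum causative region** spans the outermost markers of the maximal
  linked run, `cr_min = inner_right − inner_left`;
* the **maximum causative region** is bounded by the nearest flanking
  recombined markers, `cr_max = outer_right − outer_left − 2`.

Spans deliberately follow the `end − start` convention used for printed
coordinate pairs (`region_span()`); `region_length()` gives the inclusive
count, which is one larger. The `− 2` in `cr_max` expresses that both
flanking marker positions themselves are excluded; this convention exactly
reproduces the published per-sample and consensus values
(`984,486` / `1,003,744` bp for the key recombinant sample, `30,757` /
`175,915` bp overall), so it is adopted throughout even though a closed
formula was never stated alongside those tables. Where a flank is missing at
the edge of the panel, `cr_max = cr_min + edge_allowance`; the default
allowance of 500,001 bp reproduces the edge columns of the same table and is
exposed as a parameter.

Two situations need a policy rather than a formula:

* **Double recombinants.** An individual can show two separated linked runs.
  Without further information the run containing the most markers is chosen
  (ties resolved toward the most distal run) and the individual is flagged
  via `n_linked_runs`. When prior mapping already localises the mutation,
  `anchor =` selects the run whose flank-bounded open interval contains the
  anchor instead; individuals with no anchor-compatible run carry no
  information about the anchored region and are treated like individuals
  with no linked marker.
* **Empty inner consensus.** With enough recombinants, two individuals can
  bracket the causative site between adjacent markers from opposite sides,
  leaving no marker linked in *all* individuals. `consensus_interval()`
  then reports `inner_empty = TRUE` with `cr_min = 0` while the outer
  interval remains valid. A hard inconsistency error — naming the offending
  individuals — is reserved for cohorts whose flank-bounded open intervals
  have an empty intersection, which cannot happen without genotyping error
  in a single-locus model.

`recomb_stats()` reports the recombination fraction `theta = R/N`, the rate
in both cM/Mb and Morgans/Mb (both scalings are emitted because the
published rate range appears to mix them), and the two-point LOD score
`Z = R·log10(theta) + (N−R)·log10(1−theta) − N·log10(0.5)`, with
`Z = N·log10(2)` when no recombinant is observed. For the published counts
(10 recombinants among 263 informative meioses over 1.004 Mb) this gives
LOD ≈ 60.7 and 3.79 cM/Mb; the published LOD of 61.4 and the printed
0.025–0.030 cM/Mb range are not reproducible from any integer `(R, N)` at
the printed precision and are therefore not asserted anywhere.

```{r}
panel <- study_marker_panel()
profiles <- study_genotype_profiles()
intervals <- infer_interval(assign_linkage(profiles, panel))
select(intervals, individual, cr_min, cr_max)
```

## The variant triage cascade

Variants are classified by size (`classify_variants()`): single-base
substitutions are SNPs, 1–3 nt indels micro-indels, 4–27 nt indels
macro-indels, and uncaptured intervals of ≥ 4 nt are gaps. Three independent
predicates then act on the focal line's variant table:

1. `zygosity_filter()` — in a hemizygous region no true variant can be
   heterozygous, so heterozygous calls are eliminated;
2. `uniqueness_filter()` — a variant is eliminated as shared when an
   identical `(chrom, pos, ref, alt)` record exists in any control line or
   in a previously reported set. Variant identity is exact record equality;
   the pairwise-line comparison procedure is not specified beyond that.
   Gaps are never shared-eliminated — a shared uncaptured interval could
   still hide line-specific sequence — and are flagged `needs_validation`
   instead;
3. `region_filter()` — positions outside the causative interval are
   eliminated under a `(start, end]` convention, so a variant exactly at the
   proximal flanking marker is out and one at the distal end position is in.

Because each stage is a pure predicate of the variant record, the retained
set is the intersection of the three and is invariant to the order of
application; `triage_cascade()` composes them, assigns exactly one verdict
and reason per variant (reasons follow the cascade order), and emits an
audit log so every count in a report is traceable. `summarize_variants()`
computes transition/transversion counts (transitions are A↔G and C↔T),
per-kb densities over a caller-supplied span (the published density
denominators are ambiguous, so the span is always explicit), size and
spacing means, and gap statistics; ratios are kept at full precision and
rounded only in report output.

## Feature annotation and six-frame consequences

`annotate_variants()` places each variant against gene models with
precedence splice site > exon/UTR > intron > non-genic. A splice site is the
`splice_window` intronic bases adjacent to each exon boundary; the default
of 2 nt is the canonical donor/acceptor dinucleotide, and the window is a
parameter because the source analyses never define "splice site". Gaps are
intervals and report every category they span. Variants upstream of a
transcription start (strand-aware, default window 1,000 bp) are flagged
promoter-proximal rather than given a separate category.

`call_consequence()` evaluates SNPs in any of the six reading frames of the
*genomic* sequence — frame `+k` tiles codons from offset `k` on the forward
strand, `−k` does the same on the reverse complement — because that is how
the original screen was run, independent of annotated CDS phases. Effects
follow the standard (NCBI table 1) genetic code: synonymous, missense,
nonsense (alt is a stop), stop-loss. Codons truncated by a sequence end are
flagged and not called. `frameshift_scan()` labels indels frameshift when
the length difference is not a multiple of three, in-frame otherwise, and
re-translates the mutated sequence to the segment end: the first downstream
stop is *novel* unless the frame is preserved and its nucleotide offset
equals the reference stop shifted by the indel length — so an in-frame
deletion that merely pulls the natural stop closer is not a novel stop, but
any stop reached through a shifted frame is.

## Seed-site scanning

`scan_utr()` reports perfect seed matches in the canonical site classes:
`seed6` (UTR reverse complement of miRNA nt 2–7, the span being
configurable via `helix_from`/`helix_to`), `7mer_m8` (nt 2–8), `7mer_A1`
(seed6 plus an `A` opposite miRNA nt 1) and `8mer` (both). The energy term
is a documented stand-in, not a hybridisation model: G:C pairs score −3.0,
A:U −2.0 and G:U −1.0 kcal/mol, summed over the seed pairs plus a greedy
3'-ward extension of the duplex while bases keep pairing. It exists so the
−20 kcal/mol screening workflow (`rnahybrid_config()`) is expressible and
monotone in its cutoff, and it sits behind a pluggable `energy_fun`; site
*counts* from any particular external catalogue are explicitly not
reproduced, and miRNA catalogues are always user-supplied FASTA.
`diff_sites()` scans reference and mutant UTRs and matches sites through a
global alignment of the two sequences, so an upstream indel does not
spuriously "move" every downstream site: a site is gained or lost only if
its (miRNA, class, reference-projected start) key changes.

## Rearrangement evaluation

`apply_rearrangement()` moves a fragment by a signed shift (optionally
inverted) with an exact coordinate bijection, conserving sequence length.
`insilico_pcr()` is exact-match PCR: the forward primer on the plus strand,
the reverse complement of the reverse primer downstream, nearest pairing
within the product-size cap; mismatch tolerance is deliberately out of
scope because the modelled decision is about amplicon presence, not
hybridisation thermodynamics. `evaluate_translocation()` encodes the
validation logic: an event is *refuted* when every junction-spanning primer
set fails on the observed template while every control set amplifies,
*supported* when the junction sets amplify, and *inconclusive* whenever a
control fails (the PCR-failure analogue). Fragment orientation of the
modelled events is not recorded in the source material; both orientations
are supported and forward is the default.

## The synthetic cohort generator

`sim_config()` fixes the study conditions the package is tested under: a
1.2 Mb Z segment carrying the published 15-marker panel at its printed
positions and allele pairs; a cohort of 197 hemizygous mutant females, 66
carrier males and 41 normals, each contributing one informative meiosis (the
pedigree depth of the source cross is unrecorded, and one meiosis per
individual matches how recombinants were counted); crossovers Poisson with
mean `rate × Mb / 100` (Haldane, no interference — the simplest model
consistent with a single per-Mb rate) anchored so that every affected
individual carries the mutant haplotype at the causative position; and a
variant load matching the published per-class counts for the originally
linked region, including a 344/2,500 heterozygous-call fraction that gives
the zygosity filter something to remove. The default recombination rate of
3.8 cM/Mb is the empirical rate implied by the observed 10 recombinants in
263 meioses over ~1 Mb; the printed 0.025–0.030 cM/Mb is internally
inconsistent with those counts and would produce essentially no
recombinants at this cohort size. Genotyping is error-free by default (an
error rate is exposed but defaults to 0), gap lengths are drawn with mean
≈ 52 bp truncated at 634 bp to match the published gap-size summary, and
gene models default to the four published gene footprints with simulated
exon/UTR structure (at least two exons, CDS length divisible by three).

What the generator does *not* emulate: sequencing reads, base qualities,
capture-probe efficiency, population allele frequencies, or linkage
disequilibrium structure beyond the single introgressed block. Passing the
end-to-end tests therefore demonstrates the correctness of the interval
logic and the cascade arithmetic under the stated model, not robustness to
genotyping error or to multi-block introgressions.

## Numerical and design choices

* Coordinates are 1-based inclusive everywhere in memory; BED conversion
  helpers are exact inverses, and GFF3/VCF writers emit 1-based records.
* Marker positions must be strictly increasing; ties are rejected.
* Placement of planted variants retries bounded rounds before raising a
  sizing error; a 1 bp buffer keeps planted records from abutting.
* Deterministic sub-seeds (small fixed offsets from the config seed) give
  byte-identical outputs per stage while keeping stages independent.
* Problem sizes used by the checks were chosen at desk scale: exhaustive
  enumeration of all 2^15 linkage vectors of the 15-marker panel, all
  substitutions of a 300-nt sequence in six frames, 1,000 random UTR/miRNA
  pairs, 100 simulated cohorts at the study cohort size, and 10,000 gametes
  for the crossover-fraction check.

## Known limitations

* Multipoint likelihood mapping, pedigree reconstruction and map functions
  beyond Haldane are out of scope.
* The uniqueness filter's identity is exact record match; left-alignment or
  normalisation of equivalent indel representations is not attempted.
* The published interval table contains cells that are mutually inconsistent
  at the ±1 bp level; the implemented conventions reproduce the values that
  are arithmetically consistent and no attempt is made to match the others.
* The seed-scan energy is a screen, not a free-energy prediction; absolute
  site counts depend on the miRNA catalogue supplied.
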