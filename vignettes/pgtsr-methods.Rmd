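---
title: "Breakpoint mapping and carrier phasing for reciprocal translocations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Breakpoint mapping and carrier phasing for reciprocal translocations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pgtsr)
```

## The problem

A balanced reciprocal translocation (BRT) exchanges the terminal segments of
two non-homologous chromosomes, t(A;B), with no net gain or loss of
material. Carriers are phenotypically normal but produce a high proportion
of chromosomally unbalanced gametes, because at meiosis I the translocation
quadrivalent — the normal homologs A and B plus the two derivatives der(A)
and der(B) — can partition in several ways. Only *alternate* segregation
(both normals, or both derivatives, to the same pole) yields balanced
gametes; *adjacent-1*, *adjacent-2* and *3:1* segregation yield gametes with
partial monosomies and trisomies.

Preimplantation genetic testing for structural rearrangements (PGT-SR)
screens embryo biopsies by low-pass copy-number profiling and selects
balanced embryos for transfer. Copy number alone, however, cannot separate
the two balanced classes: a fully normal embryo and a balanced carrier
embryo have identical dosage everywhere. Distinguishing them requires
(1) the breakpoint positions and (2) knowledge of which parental haplotype
rides each derivative chromosome, so that flanking SNPs reveal whether the
embryo inherited the derivative or the normal homolog. This package
implements that analysis chain, in two complementary forms:

* **CNV route** — *reference embryos* (embryos unbalanced on both
  translocation chromosomes) betray the breakpoints as shared segment
  boundaries, and betray the derivative haplotypes because their unbalanced
  dosage exposes single carrier haplotypes around the breakpoints.
* **Long-read route** — reads spanning a derivative junction split into two
  alignment blocks on different chromosomes; clustering the split
  coordinates localizes the breakpoint to a single base, and the SNP
  alleles carried by junction-spanning reads directly phase the derivative
  haplotype.

A synthetic pedigree simulator with complete ground truth stands in for
patient data, so every stage is testable end to end.

## The simulator

`toy_genome()` builds a two-chromosome diploid genome (default 2 × 5 Mb,
one SNP per 2 kb) with phased carrier haplotypes H1/H2 and a partner
genotype; about a quarter of sites come out *fully informative* (carrier
heterozygous, partner homozygous), matching the kind of site a clinical
haplotyping assay relies on. `build_derivatives()` forms der(A)/der(B) as
an exact base partition of A ∪ B: der(A) is the centromere-bearing part of
A joined to the exchanged distal fragment of B, with the incoming fragment
inverted whenever a q-arm piece is joined to a p-arm piece so that
telomeres face outward. The junction convention — der(A) joins
(A, bp\_a) to (B, bp\_b), der(B) joins (A, bp\_a + 1) to (B, bp\_b + 1) —
guarantees the partition invariant, which the test suite verifies by
exhaustive per-base scans.

`segregate()` draws gametes per segregation mode, with the balanced flag
always *computed* from base coverage rather than asserted. An embryo is a
carrier gamete plus a normal partner gamete; its true copy number per
region follows by enumeration. Three observation layers are then simulated:

* **Bin counts** (`simulate_bin_counts()`): negative-binomial counts with
  mean `m·CN/2` and variance `(1 + dispersion)·mean`. `dispersion` is the
  excess variance relative to Poisson (default 0.1); `dispersion = 0` is
  the fully deterministic degenerate case used by exact tests. The default
  `m = 500` counts per disomic bin corresponds to low-pass sequencing of an
  amplified biopsy at the package's default 200 kb bins.
* **SNP observations** (`simulate_snp_observations()`): the alleles of the
  haplotypes actually present in the embryo, with per-allele dropout at
  rate `ado` (one copy-weighted allele always survives — locus-level
  dropout is not modeled) and genotyping errors at `error_rate`. This is
  the whole-genome-amplification artifact model that the ADO-tolerant
  majority voting downstream must survive.
* **Long reads** (`simulate_long_reads()`): reads sampled uniformly from
  the carrier's four molecules, log-normal lengths (default mean ≈ 19 kb),
  per-read mean quality from a normal distribution so that a realistic
  fraction fails the QC threshold. Junction-spanning reads receive two
  blocks with the correct breakend orientation and carry the SNP alleles of
  the haplotype physically on that derivative. FASTQ/BED writers convert
  from the internal 1-based inclusive coordinates at the boundary.

What the simulator deliberately does **not** model: sequence-level base
errors and homopolymer noise, amplification bias along the genome,
crossovers within arms (recombination appears only as the option to inject
a flank-haplotype switch), and Robertsonian translocations. Passing tests
therefore demonstrate the correctness of the analysis logic under the
stated noise models, not performance on raw clinical data.

## Copy-number stage

`normalize_counts()` scales each bin by the autosomal median
(CN = 2·count/median). `segment_profile()` performs recursive binary
segmentation: the candidate cut maximizing the normalized mean difference
is accepted when the raw mean change is at least `threshold` (default 0.3
copies) and both sides keep `min_seg_bins` bins (default 3); boundaries are
reported at the first bin of the right-hand segment. Raising the threshold
can only remove cuts, so segment counts are monotone in it — a property the
suite checks.

`call_segment_cn()` interprets a segment mean by its deviation `d` from 2:
|d| < 0.2 is normal; 0.2 ≤ |d| ≤ 0.7 is called mosaic (CN 3 gain or CN 1
loss with fraction |d|, e.g. a mean of 2.31 is a ~31% trisomic mosaic);
beyond 0.7 the rounded integer CN (0–4) is called. The clinical tables this
package mirrors report mosaics around 31–51% and full calls otherwise; the
0.2/0.7 cutoffs are this package's own choice since no published cutoff
exists.

Karyotype strings use the clinical segment dialect
(`"46, XN, +2q(q14.3→q37.3,~118Mb,×3), -5p(pter→p13.2,~35Mb,×1)"`), with
whole-arm calls (`"+17p(×3)"`) supported, size labels floored to whole Mb,
and cytoband tokens resolved through a UCSC-dialect band map
(`load_cytobands()`; a synthetic toy map ships in `inst/extdata/`).
Serialization and parsing are exact inverses, property-tested on generated
calls.

An embryo is classified `reference_unbalanced` when it has at least one
non-mosaic unbalanced segment on *each* translocation chromosome;
mosaic-only events never qualify. "Unbalanced on both chromosomes" is the
operational reading of a reference embryo and matches every reference row
of the fixture pedigrees, including one whose second chromosome carries an
extra, unrelated event.

## Breakpoint localization

`localize_from_cnv()` collects, per translocation chromosome, each
reference embryo's copy-state change edge nearest the centromere on the
exchanged arm (adjacent same-direction segments merged, chromosome termini
ignored). This generalized edge rule is needed because a reference embryo
can expose the breakpoint through a *proximal* imbalance (e.g. a
pter→breakpoint gain) as well as through the usual distal segment.
Boundaries snap to the bin grid; the representative is the modal position
with deterministic tie-breaks (median, then the smaller coordinate); the
half-window is the larger of the bin width and half the boundary spread.

`detect_junctions()` turns consecutive alignment blocks on different
chromosomes into breakend-pair candidates, clusters them greedily within a
10 bp tolerance, takes modal representatives per side, discards clusters
below 3 supporting reads, and merges reciprocal partner clusters (opposite
orientation, ≤ 1 bp offset) into one translocation. On error-free
simulated reads the representatives equal the planted breakpoints exactly —
the desk-scale analogue of single-base breakpoint mapping. Read QC keeps
reads with mean quality ≥ 7 (a read at exactly 7 passes), and
`read_stats()` reports N50 (largest-first cumulative scan) and depth.

`check_concordance()` quantifies agreement between the two routes as the
distance between the CNV window center and the split-read coordinate, and
whether it falls inside the window. On the two fixture pedigrees the four
distances are 42,487 / 34,118 / 8,295 / 57,719 bp, all inside ±200 kb. The
fixture localization runs on a 100 kb grid because the published window
centers sit on 100 kb multiples; the simulator pipeline uses its native
bin width.

## Haplotype phasing and carrier calls

`select_informative_snps()` keeps fully informative sites within ±2 Mb of
a breakpoint and annotates each with its flank (proximal = centromere
side). Semi-informative sites (partner heterozygous) are excluded by
default because dosage logic would be required to use them.

Reference-embryo phasing (`phase_derivative_from_references()`) uses two
vote types, both on proximal-flank SNPs where the embryo carries exactly
one carrier haplotype:

* an embryo **monosomic for the distal segment** of chromosome X received
  der(X), so its visible carrier allele *is* the derivative haplotype —
  a direct vote;
* an embryo **trisomic for the distal segment** received the normal X
  homolog, so its proximal carrier allele identifies the *normal-linked*
  haplotype — an inverse vote.

Trisomic-region dosage is never used (both carrier haplotypes are present
there, so alleles alone carry no linkage information), and SNPs inside
monosomic regions serve as a cross-check: the carrier allele must be absent
there, and confident violations are counted separately. Votes pool over
embryos and SNPs; linkage is emitted per chromosome only at ≥ 90%
consistency, otherwise the stage stops and names the discordant embryos.

Junction-read phasing (`phase_from_junction_reads()`) is independent of
reference embryos: alleles observed on junction-spanning reads belong to
the derivative molecule by construction, on *both* sides of the junction.
Per-SNP majorities over supporting reads pool into the same linkage
structure. On noiseless pedigrees the two routes agree exactly — one of the
acceptance properties.

`call_carrier_status()` applies to euploid embryos only (unbalanced embryos
are refused by precondition). Per chromosome, proximal-flank SNPs vote for
the transmitted carrier haplotype; a call requires ≥ 5 voting SNPs and an
80% majority, which tolerates allele dropout because dropout corrupts
individual votes, not the majority. Transmitted = derivative-linked on both
chromosomes gives `carrier`; normal-linked on both gives `non_carrier`;
anything else — disagreement, unresolved linkage, or thin evidence — is
`inconclusive`, never a guess. Preferring SNPs nearest the breakpoint and
reporting the flanks separately bounds the damage a recombination event
between SNP and breakpoint could do.

The 2 Mb window, 5-SNP minimum, 80% majority and 90% consistency defaults
are this package's choices (no published values exist); they are set so
that carrier calling is error-free at `ado = 0` and ≥ 95% accurate at
`ado = 0.1` with ≥ 20 informative SNPs per flank on the toy genome — both
verified over 200 simulated euploid embryos under fixed seeds.

## Numerical and design choices

* Coordinates are 1-based inclusive everywhere internally; BED/BEDPE and
  cytoband readers/writers convert at the file boundary.
* Every tie-break is deterministic (mode → median → smaller coordinate), so
  a config plus seed fully determines every output byte; `write_report()`
  output is byte-stable and the suite hashes it.
* All stage seeds derive from one master seed in `pipeline_config()`.
* Degenerate inputs have defined behavior: empty read sets give zero stats
  with a warning; a flat profile gives one segment; zero informative SNPs
  or zero reference embryos give inconclusive calls or an instructive
  error, mirroring the clinical requirement that carrier status cannot be
  resolved without a reference embryo (unless junction reads are
  available).
* 3:1 segregation and mosaic overlays are config options, off by default.
* Problem sizes in tests are chosen for seconds-scale runs: 2 × 5 Mb toy
  genome, 12-embryo pedigrees, 5,000 long reads, 100 localization
  replicates, 200 embryos for accuracy estimates.

## Known limitations

The simulator's clean alignment blocks sidestep real long-read alignment
ambiguity (soft-clip jitter around junctions would spread candidates by a
few bases; the 10 bp cluster tolerance anticipates this but is untested
against a real aligner). Breakpoints inside assembly gaps or segmental
duplications, Robertsonian translocations, and GC-driven coverage waves are
out of scope. The fixture pedigrees' base-pair segment coordinates are
synthetic encodings consistent with the published band-level tables and
windows, not measured values.
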