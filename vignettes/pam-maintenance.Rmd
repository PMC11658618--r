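---
title: "Tracking tumor-specific CRISPR PAM targets across metastases"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracking tumor-specific CRISPR PAM targets across metastases}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pamtrack)
```

## The problem

A somatic single-base substitution (SBS) can create a protospacer-adjacent
motif (PAM) — the NGG trinucleotide SpCas9 requires next to its target —
that exists in the tumor genome but not in the patient's germline. Such
*novel PAMs* are tumor-specific cut sites: a guide RNA against the adjacent
20-base protospacer directs double-strand breaks to cancer cells only. For
this to work against metastatic disease, the targets selected from a primary
tumor must still be present in every metastasis. Two forces govern that:
mutations carried by the cancer-initiating clone (*truncal* mutations)
propagate to all descendants, while ongoing chromosomal instability — above
all loss of heterozygosity (LOH) — can delete them again.

`pamtrack` implements the complete desk-side analysis: discovery of novel
PAMs from matched tumor−normal variant calls, sgRNA design and annotation,
zygosity/copy-number classification of each target, maintenance statistics
across the metastases of a case, and UPGMA sample trees. Because matched
rapid-autopsy sequencing data are rarely shareable, the package also ships a
haplotype-resolved clonal-evolution simulator that generates complete cases
with ground truth for every pipeline stage.

## The VAF–copy-number model

The observable that links zygosity, copy number and purity is the variant
allele fraction (VAF). For a variant on `m` of `cn` tumor copies in a sample
of tumor-cell fraction `p` (contaminating normal cells contribute two
reference copies):

$$\mathrm{VAF} = \frac{m\,p}{cn\,p + 2(1-p)}$$

At purity 1 this reduces to `m/cn`: 1 in haploid LOH regions, 0.5 for a
diploid heterozygote, 1/3 and 2/3 on a triploid background. `expected_vaf()`
implements this; the simulator emits every call with exactly this value
(optionally binomially resampled at a configured depth). Germline
heterozygous variants in tumor samples use the variant
$(m p + (1-p))/(cn\,p + 2(1-p))$, since contaminating normal cells also
carry the allele.

Two consequences drive the whole analysis:

* a truncal heterozygous SBS in a region that later suffers *haploid* LOH in
  one metastasis survives there with probability 1/2 (its copy is either the
  kept or the lost one), and with probability 2/3 when a triploid region
  loses one of three copies — loss at a rate of about 50% *per copy*;
* in regions of *truncal* LOH (one haplotype lost in the founder clone,
  before dissemination) every surviving PAM sits on the sole remaining copy
  at VAF 1, cannot be heterozygously lost again, and is maintained in 100%
  of metastases.

## Pipeline stages and their parameters

| Stage | Function | Threshold (default) |
|---|---|---|
| somatic subtraction | `somatic_subtract()` | MQ ≥ 20, depth ≥ 10, AF ≥ 0.05 |
| novel-PAM scan | `scan_novel_pams()` | NGG/CCN register creation, ≤ 2 per SBS |
| sgRNA design | `design_sgrna()` | 20-base protospacer; GC optimal in [0.40, 0.80], inclusive |
| context | `annotate_context()` | near-coding window 2000 bp |
| presence call | `call_presence()` | VAF ≥ 0.05 and depth ≥ 20, else absent / no-coverage |
| LOH call | `classify_pam_zygosity()` | VAF ≥ 0.95 |
| region label | `classify_regions()` | CN = 1 *or* mean truncal-PAM VAF ≥ 0.95 |
| sample QC | `depth_qc()` | mean depth ≥ 20× |

Notes on the less obvious choices:

* **Novelty is register-based.** A PAM is novel iff a specific 3-base
  register matches NGG (plus strand) or CCN (minus strand, read on the plus
  strand) in the mutant but not the germline sequence. Since N matches any
  base, this is equivalent to creating a GG (or CC) dinucleotide; an alt of
  A or T can never qualify, alt G forces the plus strand, alt C the minus
  strand, and `GGG → GGGG` correctly yields exactly one new register.
  Registers running past a contig end are skipped silently. Only canonical
  SpCas9 NGG is considered; NAG off-target PAMs are not.
* **GC window boundaries are inclusive** (a protospacer at exactly 40% GC is
  optimal), and an event without room for a 20-base protospacer is flagged
  undesignable rather than dropped.
* **The presence cutoff (5% VAF) is asymmetric with depth**: below 20× a
  site is `no_coverage`, never `absent`, and no-coverage cells are excluded
  from both numerator and denominator of every maintenance statistic (counts
  of affected cells are reported). A site with no call record is scored at
  VAF 0 assuming coverage at the sample's median call depth; supply
  `site_depths` to `presence_matrix()` when real per-site depths exist.
* **Region zygosity uses truncal PAMs only** in `run_case()`: metastasis-
  private SBS sit at VAF ≈ 0.5 on a single copy and would dilute the VAF = 1
  signature by which copy-neutral LOH (CN 2, but one parental allele) is
  recognized. A PAM with no covering copy-number segment inherits the
  diploid default CN 2 with a warning.
* **Truncal definition** follows the operational rule: present in *any*
  primary sample and absent in the matched normal; for a case without a
  primary sample, present in more than one metastasis. Region granularity is
  whole contigs for simulated data and whatever interval map (chromosome
  arms) the caller supplies for real data; mixed intervals are labeled at
  the granularity given, not subdivided.
* **Trees.** Distances are raw Hamming counts over the binary presence
  matrix with pairwise deletion of no-coverage sites. UPGMA is implemented
  in-package so that merge ties break deterministically (lexicographically
  by concatenated member names — standard library implementations leave
  this unspecified); trees are `ape::phylo` objects, serialized as Newick,
  and re-rooted at the primary with the fewest sample-unique PAMs (ties:
  lexicographic, logged). Statistical comparisons (`compare_groups()`)
  dispatch to the standard Mann–Whitney / Kruskal–Wallis / one-way ANOVA
  routines from `stats`.

## What the simulator emulates

`simulation_config()` + `simulate_case()` generate one rapid-autopsy case:

1. **Genome.** `n_contigs` contigs of `contig_length` i.i.d. bases at the
   configured GC content (default 10 × 100 kb at 0.41, a scaled-down
   mammalian composition), with `n_germline_het` heterozygous germline SNVs
   on uniformly chosen haplotypes.
2. **Founder clone.** `n_truncal_sbs` truncal SBS, each on one uniformly
   chosen copy; then truncal LOH (loss of one whole haplotype) on
   `truncal_loh_contigs`, applied *before* any branching — truncal SBS on
   the lost haplotype vanish from every descendant, those on the retained
   one are fixed at VAF 1. Contigs may instead be configured triploid (one
   haplotype replicated; truncal SBS there occupy one of the three copies)
   or with copy-neutral truncal LOH (retained haplotype reduplicated, CN 2
   at VAF 1). Truncal LOH on a polyploid contig is rejected at validation
   so the VAF classes stay unambiguous.
3. **Lineage.** Metastases descend from the founder along a random
   ultrametric coalescent (sequential random merges at unit-height steps).
   Every branch — terminal and internal — accrues
   `round(n_private_sbs_per_met × span)` new SBS, so each metastasis carries
   at least `n_private_sbs_per_met` leaf-private SBS and clades share the
   SBS of their common internal branches. This clock-like construction is
   what makes the lineage recoverable by UPGMA; a star phylogeny with
   exchangeable leaf-private counts would leave nothing to recover.
   Primary samples are drawn from the founder itself (no private events):
   they represent the ancestral state, which keeps the operational truncal
   definition aligned with the founder genotype. A corollary is that
   primaries carry no derived mutations and therefore do not participate in
   metastasis clustering; they belong at the root, which is exactly where
   `reroot_at_primary()` puts them.
4. **Private LOH.** Each metastasis independently draws
   `private_loh_events_per_met` contigs (excluding truncal-LOH contigs) and
   deletes one uniformly chosen copy there — the mechanism behind the 1/2
   and 1/3 loss rates above.
5. **Emission.** Every variant in every sample is emitted at the model VAF
   (`m`/CN at the default purity 1; real FFPE purities are unreported for
   this kind of material, and purity 1 matches the cell-line setting the
   LOH analysis comes from — lower the parameter to emulate cellularity).
   `mean_depth = 0` means noise-free VAFs (depth reported as 100×);
   positive values binomially resample alt reads at that depth. The normal
   sample carries only germline variants at CN 2. One master seed drives
   per-stage substreams (derived by a stable hash of the stage label), so
   outputs are byte-identical given a config and adding a sample does not
   reshuffle unrelated draws.

Ground truth accompanies every case: per-variant origin, haplotype/copy,
truncality; per-variant-per-sample mutant copies and CN; per-region cohort
labels; the lineage tree as `ape::phylo`.

**What it does not emulate** — and therefore what green tests do *not*
establish about real data: read-level artifacts (FFPE deamination, mapping
error, probe specificity), subclonal structure within a sample beyond a
single purity mixture, indels/SVs, mutation signatures, and real
chromosome-arm geometry. The simulator validates the *logic* of the
pipeline (filters, classifications, arithmetic, tree building), not the
upstream variant calling it deliberately consumes as input.

## Problem sizes used for validation

The test-suite and the acceptance script rerun the pipeline end-to-end on
cases chosen to give the binomial loss fractions ~1,500 informative PAMs
(10 contigs × 100 kb, 10,000 truncal SBS where a ±3-SD check needs ≥1,000
PAMs on affected contigs, 1,000 otherwise; 4–6 metastases). At the observed
PAM-creation rate of roughly 0.15–0.18 per SBS this keeps every check well
powered while a full run stays under half a minute on one core. The
exhaustive scanner check enumerates all 1024 germline 5-mers × 9 center
substitutions against an independent string-matching oracle.

## Known limitations

* Copy-number input is integer total CN per segment; B-allele frequencies
  are not used, so copy-neutral LOH is detectable only through the VAF of
  overlapping PAMs.
* The depth-QC rule is a simple mean-depth floor plus a flag for depressed
  percent-truncal at adequate depth; the visual "linear portion" criterion
  used with capture data has no algorithmic definition.
* `percent maintained` and `percent truncal` treat metastases as exchangeable
  samples; no weighting by lesion size or site is attempted.
* The UPGMA distance is an unnormalized Hamming count; with very uneven
  no-coverage patterns a normalized coefficient could rank pairs differently.
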