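---
title: "editscan: models, thresholds and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{editscan: models, thresholds and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(editscan)
```

# Scope

editscan analyses adenosine-to-inosine (A-to-I) RNA editing starting from
the point where an RNA-Seq variant caller has produced candidate
substitutions.  Inosine base-pairs like guanosine, so edits surface as A>G
mismatches (T>C on the antisense strand) between RNA reads and the genome.
Four analysis stages are implemented, plus seeded generators that emulate
every input shape so the whole stack is testable offline.  This vignette
records the models, the tunable parameters and the design decisions that
were genuinely open.

# Realignment-based artifact removal (RAAR)

## The problem

Variant calls from RNA-Seq are contaminated by three well-known alignment
artifact classes:

* **multi-alignment artifacts** — reads from one copy of a homologous or
  repetitive region aligned to the other copy, so the copies' divergent
  bases masquerade as variants;
* **splice-junction artifacts** — junction-spanning reads aligned
  ungapped so that the part belonging to the downstream exon overhangs
  into the intron, producing a run of false mismatches;
* **indel artifacts** — reads from an indel-bearing haplotype aligned
  without the gap, producing false mismatches downstream of the indel.

## The filter

For each candidate variant, the reads whose aligned base at the variant
position equals the alternate allele ("supporting reads") are realigned
from scratch:

1. **Candidate loci.** Every 11-mer of the read (both orientations) is
   looked up in an exact k-mer index of the reference; hits are clustered
   by alignment diagonal and each cluster padded by one read length.  The
   read's original locus is always a candidate.  Clusters on the same
   chromosome and strand closer than `join_gap` (default 5,000 bases,
   capped at `max_intron`) are joined into one window so a spliced
   alignment can bridge the two seed clusters of a junction-spanning
   read.  Joining windows is an extension of plain per-cluster windows;
   without it, the two exon-side clusters of a junction read would be
   realigned separately and no placement could expose the intron.
2. **Three alignment modes per window** (compiled, Gotoh-style local DP):
   ungapped; gapped with affine penalties; and spliced, allowing exactly
   one reference-only gap of length `min_intron`..`max_intron` at a flat
   penalty.  Per window the single best-scoring mode is kept; ties prefer
   the simpler mode.  One intron per read is enough at read lengths of
   50–100 bases, where two junctions in one read are vanishingly rare.
3. **Read verdict.**  A read CONFIRMs its variant only if the top-scoring
   placement still covers the variant position with the alternate base
   intact, and no placement *not* covering the position scores within
   `near_tie_ratio` of the best.  Otherwise the read REFUTEs with a
   reason: a better or near-tying placement elsewhere
   (`best_elsewhere`/`near_tie`), a spliced or gapped placement that
   erases the mismatch (`spliced_better`/`gapped_better`), or loss of the
   alternate base (`alt_lost`).
4. **Variant verdict.**  A variant passes iff the confirmed fraction is
   at least `min_confirm_frac` *and* the confirmed count is at least
   `min_alt_reads`; otherwise the modal refute reason names the artifact
   class, with ties broken in the fixed order multi-alignment >
   splice-junction > indel.

## Parameters

| parameter | default | units | why |
|---|---|---|---|
| match / mismatch | +1 / −1 | score | standard Blat-like weighting |
| gap open / extend | −2 / −1 | score | small indels cheaper than 2 mismatches per base |
| intron penalty | −3 | score | flat: intron length carries no cost beyond a fixed charge |
| `min_intron` | 20 | bases | reference gaps shorter than real introns are deletions; keeps the indel and splice artifact classes separable |
| `max_intron` | 50,000 | bases | generous upper bound for human introns at desk scale |
| `near_tie_ratio` | 0.95 | — | a placement elsewhere within 5% of the best is ambiguity, not confirmation (inclusive comparison) |
| `min_confirm_frac` | 0.90 | fraction | a variant whose support is >10% refuted is suspect |
| `min_alt_reads` | 5 | reads | matches the stringent site-calling floor |
| `junction_window` | 4 | bases | variants this close to an annotated exon boundary are force-routed through spliced realignment |

These per-step values are design choices of this package (the upstream
description of the procedure does not pin them); every one is exposed in
`scoring_scheme()` / `raar_config()`.

`min_intron` is an addition to the minimal parameter set: without a floor,
a 3-base deletion would score as a −3 "intron" instead of a −4 deletion
and indel artifacts would be reported as splice artifacts.  20 bases is
well below the shortest credible human intron yet above any plausible
polymerase slip.

External Blat realignments can be supplied as PSL; for reads present in
the PSL, those hits replace internal realignment (reference gaps of 20+
bases in a PSL block structure are flagged as introns).

# Editing quantification

**Definitions.** A *site* is a recurrent genomic substitution; an *event*
is one sample's observation of editing at a site; the *level* is the
fraction of reads carrying the edited base.

**Two-step detection.**  Stringent calling requires, in at least one
sample, ≥ 5 supporting reads *and* ≥ 5% allele frequency (both
inclusive).  Relaxed retrieval then revisits the confident sites in every
sample and keeps any event with total depth ≥ 10 reads — including
zero-level events, with no frequency floor — because the stringent cutoff
systematically suppresses the prevalent lowly-edited fraction.  Cells
below the depth floor are explicitly missing, not zero.

**DNA support filter.**  A variant whose allele frequency in paired
DNA-Seq is ≥ 5% (inclusive) is a genomic variant, not editing, and is
removed.  Positions with no DNA coverage keep the RNA variant but are
flagged `dna_uncovered`: absence of DNA evidence is not evidence of a DNA
variant.  (The uncovered case was an open choice; dropping such variants
would silently bias against low-input DNA libraries.)

**Spectra and histograms.**  Substitution spectra are tabulated over the
12 types as stored on the + reference strand.  Level histograms use
5-percentage-point bins of editing level — `[0,5), …, [95,100]` — with a
centred 3-bin moving average whose edge bins use 2-term means.  The "bin
size" is a level bin, not a genomic length; the histogram x-axis is a
percentage.

# Cohort statistics

**Recurrence.**  Only sites with ≥ 20× depth in *every* sample are
scored; the statistic is the number of samples with non-zero level.
Requiring the floor in all samples removes the confound between "not
edited" and "not covered".

**Validation against an external cohort.**  A sample supports a site
when depth ≥ 10, edited reads ≥ 1 and allele frequency ≥ 1% (all
inclusive).  Categories: `real` (≥ 2 supporting samples), `likely`
(exactly 1), `unsupported` (0 supporting but ≥ 1 sample covered),
`insufficient` (no sample covered).  The narrative description of the
rule is ambiguous between "more than two" and "two or more"; the
inclusive ≥ 2 reading is used.

**Differential editing.**  Per site, tumour and normal levels are
compared across pairs with a classic paired t-test (n − 1 degrees of
freedom); pairs with a missing cell in either member are dropped
(complete-pairs analysis), and sites with fewer than `min_pairs = 10`
usable pairs are not tested — the same ≥ 10 floor that cohort selection
uses, reapplied per site, which is this package's choice.
Benjamini–Hochberg q-values are computed across all tested sites of the
tumour type (coding and 3'UTR pooled; a `by_region` flag switches to
per-region families, since the original family structure is not fully
pinned).  Zero-variance differences are degenerate for the t statistic;
the conventions are: identical vectors → t = 0, p = 1; constant non-zero
difference → p = 0, flagged.

**Direction calls.**  A site is called up iff ≥ 2 tumour types show a
significant increase while ≤ 1 shows a significant decrease (and
symmetrically for down).  Per gene, the up/down site counts are reported
and a gene is *consistent* when all called sites agree.

# 3'UTR microRNA regulation

A 7-mer seed (positions 2–8 of the mature miRNA) pairs antiparallel with
the target: seed position *i* against target position 8 − *i*.  Canonical
pairs are A:U and G:C; G:U wobble counts only when `wobble_counts =
TRUE`, since wobbles are a weaker, distinct pairing class.  An A-to-I
edit replaces a target A by G: `destroys` means the unedited 7-mer paired
perfectly and the edited one does not; `creates` is the reverse;
everything else is `none`.  Full 7-mer perfection is required (offset
6-mers are not counted) — the conservative reading where the geometry was
not fully specified.

Intersection of single-base sites with seed-match intervals is half-open
(`start0 <= pos0 < end0`) and strand-blind by default, matching the
common intersectBed default; the biologically correct strand-aware mode
is one flag away and recommended when target strands are trusted.

Editing–expression coupling is measured as the Pearson correlation
between per-sample editing-level deltas and log2 expression deltas,
after excluding samples with copy-number alterations at the locus
(CNV-driven expression change would confound the correlation).  Fewer
than 3 remaining samples or zero variance yields a flagged NA.  Group
comparisons of correlation values use Welch's t-test by default (the
pooled variant is an option); equality of variances between a 3-site
focal group and a large background group should not be assumed.

The four-subtype regulatory model combines gene role, editing direction
in tumours and seed effect:

| subtype | role | editing | seed effect | consequence |
|---|---|---|---|---|
| I | oncogene | up | destroys | repression lost, oncogene up |
| II | tumour suppressor | up | creates | repression gained, suppressor down |
| III | tumour suppressor | down | destroys | site regained, suppressor down |
| IV | oncogene | down | creates | created site lost, oncogene up |

The other four triples are inconsistent with the model; the mapping is a
bijection onto {I, II, III, IV} and is tested exhaustively.

# The synthetic world

The generators state a test world once; their defaults are not tuned to
test outcomes.

* **Genome** (`simulate_genome_with_paralogs`): two 20 kb chromosomes;
  twelve two-exon genes (300-base exons, 150-base introns) on chromosome
  1; paralog source segments (300 bases) on chromosome 1 with copies on
  chromosome 2, identical except one forced divergent base at the centre
  plus optional random divergence.  The first intron base of every gene
  is forced to differ from the first base of the downstream exon so
  ungapped read-through always mismatches.  150-base introns are short
  for a mammalian gene but keep windows small; nothing in the filter
  depends on intron length beyond `min_intron`.
* **Reads** (`simulate_reads_with_artifacts`): 75-base error-free reads,
  50× at planted sites, editing levels uniform in 0.2–0.6.  Artifact
  reads are emitted *pre-misaligned* — the generator writes the wrong
  alignment deliberately, because the test target is the adjudication,
  not an aligner.  Planted alt-read counts are binomial conditioned on
  the 5-read caller floor, since a candidate VCF by construction contains
  only calls the caller could make; without the conditioning, "zero true
  variants removed" would be ill-posed for sites that happened to draw
  < 5 edited reads.
* **Cohort** (`simulate_editing_cohort`): 40 tumour–normal pairs, 1,000
  sites with base levels uniform in 0.1–0.4, Poisson(50) depth, and
  beta-binomial edited counts with overdispersion ρ = 0.01 — plain
  binomial sampling would understate between-sample variance and make the
  paired t-test look better than it is.  50 planted differential sites
  shift the tumour mean by Δ = 0.15.
* **Coupling** (`simulate_coupled_expression`): Δexpression = β·Δediting
  + Gaussian noise with the noise SD solved from the target population
  correlation (r = β·σ_edit / sqrt(β²σ_edit² + σ_noise²)); target r = 0.1
  for coupled sites emulates the weak but real coupling expected when one
  miRNA contributes a small share of a gene's regulation.

For the correlation-separation check, 14 cohorts of 60 pairs are
simulated with 3 coupled and 20 background sites; 60 pairs is
representative of the larger real cohorts (the printed pan-cancer pair
counts range from 13 to 99) and was fixed by a power calculation *before*
the test was first run: with n pairs, the sampling SD of r is
≈ 1/√(n−3) ≈ 0.13, giving a Welch-t noncentrality of ≈ 4.6 for a 0.1
group shift at group sizes 42 vs 280.

What a green test does **not** establish: the generators use error-free
reads (no base-quality model), uniform coverage, deterministic exon
structures, single-end reads and artifact reads placed by construction —
so passing says the adjudication logic is right, not that a real aligner's
error modes are covered.  Overdispersion is constant across sites,
whereas real editing QTLs vary; the type-I calibration therefore checks
the t-test under stated noise, not under every real-data pathology.

# Numerical conventions

* All internal coordinates are 0-based half-open; VCF POS and catalog
  positions are 1-based only at the I/O boundary.
* Every threshold comparison that implements a published "≥" is
  inclusive, and the boundary cases (alt = 5 with af = 0.05; DNA af =
  0.05; depth = 10 with level 0; depth 19 vs 20; depth 10/alt 1/af 0.01)
  are asserted exactly in the acceptance tests.
* Realignment tie-breaks are total orders (score desc, then chromosome,
  then start), so identical inputs give identical verdicts.
* Degenerate statistics (zero-variance differences, < 3 correlation
  samples) are flagged rather than silently propagated.

# Known limitations

* The internal pileup is fixture-scale; production pileups should come
  from samtools-style tooling upstream.
* Spliced realignment allows one intron per read.
* The k-mer candidate search is exact-match; at high divergence (> ~10%)
  a paralog copy can escape seeding, which is conservative for artifact
  detection (the read keeps its original locus) but can miss a
  multi-alignment refutation.
* BH is applied within tumour type; cross-type families are the caller's
  responsibility.
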