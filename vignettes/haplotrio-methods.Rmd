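---
title: "Methods: diploid trio comparison, de novo rates and sex-chromosome analysis"
author: "haplotrio"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: diploid trio comparison, de novo rates and sex-chromosome analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(haplotrio)
```

# Scope

`haplotrio` implements the downstream computations that become possible
once both haplotypes of a diploid individual are assembled independently
from a parent-offspring trio: the full spectrum of heterozygous
differences between the two haplotype assemblies, pileup-based site
quality control with an error partition, dual-reference de novo mutation
(DNM) rate estimation with callability correction, sex-linked scaffold
classification from female/male coverage with Hi-C rescue and
longest-rule de-collapse, and divergence dating of X-Y gametologue
strata.  Assembly itself, read mapping and external variant callers are
out of scope; the package consumes their standard outputs (FASTA,
show-coords/PAF alignment blocks, per-site genotype tables, coverage
tracks, interaction tables, CDS pairs) and, for testing, generates all
of them synthetically with known truth.

# The synthetic diploid trio

`simulate_trio_genomes()` draws a maternal haplotype at random, derives
the paternal haplotype by planting heterozygous variants (SNVs, indels
up to 50 bp, and the five structural classes: large indels, inversions,
translocations, tandem CNVs, inverted translocations), and derives the
child's two transmitted haplotypes by adding de novo mutations.  Key
modelling decisions:

* **Parents are homozygous for their transmitted allele at every
  site.**  This is the limit of a fully inbred parent and is what makes
  the dual-reference genotype patterns exact.  Each haplotype assembly
  is built from the *child's* reads, so a maternal DNM is the reference
  base of the maternal assembly: against the paternal reference the
  trio reads (0/0, 0/0, 0/1), against the maternal reference
  (1/1, 1/1, 0/1).  Real parents are heterozygous at their own
  polymorphic sites; those sites never satisfy the candidate pattern,
  so the simplification does not change what the DNM pipeline sees at
  candidate sites.
* **Total DNM count is Poisson with mean `dnm_rate` times the summed
  length of the two transmitted haploid genomes**, and the paternal
  share is Binomial with the configured paternal fraction (default
  2/3, i.e. a 2:1 paternal:maternal ratio).  The summed-length
  convention matches the rate estimator, whose denominator sums
  callable sites over both parental references.
* **Placement is collision-free by bounded resampling** (100 attempts,
  then an error), with reserve margins around each event and a 60-bp
  margin at sequence ends so that every planted variant is within reach
  of exact-anchor alignment.  Truth tables are therefore unambiguous.
* **Runs of homozygosity are planted as variant-free intervals**; DNMs
  may still fall inside them, as in real data.
* All randomness flows from one integer seed through named substreams
  (`"trio"`, `"site_calls"`, `"coverage"`, `"hic"`, `"gametologues"`,
  `"chains"`, `"alpha"`), so a given (config, seed) pair reproduces
  every output byte-for-byte regardless of call order.

`simulate_site_calls()` renders per-site trio genotype tables against
both references, with Poisson depth, binomial allele sampling, a
symmetric per-read miscall probability toward the site's alternative
allele, and a maximum-likelihood genotype caller over alt dosage
{0, 1, 2} whose genotype quality (GQ) is the scaled log-likelihood gap
between the best and second-best dosage, capped at 99 (external callers
report a phred-scaled quantity of the same form).  Site-level rendering
assumes a colinear trio (no planted indels/SVs), so a position means
the same site on both references; the structural classes are exercised
through the alignment route instead.  The child's reads are drawn
independently on the two references, whereas real pipelines map one
read set twice; this makes cross-reference filtering slightly harsher
than in real data and biases the rate estimate a few percent downward,
well inside the Poisson uncertainty at realistic DNM counts.

What the generator does *not* emulate: mapping artefacts, mosaicism and
chimerism, GC-dependent coverage, indel sequencing errors, linked-read
barcode structure.  Passing recovery tests therefore demonstrate the
correctness of the downstream logic under the stated error model, not
robustness to every real-data failure mode.

# Heterozygosity spectrum

`align_haplotypes()` is a deliberately simple exact-anchor aligner for
toy genomes (guardrail: 50 Mb total): unique reference k-mers (default
31) are located in the query on both strands and chained along shared
diagonals into gapless blocks.  Because any length change shifts the
diagonal, mismatch columns inside a block are SNVs and every indel or
SV surfaces as a block junction or as a relocated, reverse, or
multi-covering block.  The `join_gap` parameter (default 200 bp)
bridges anchor deserts caused by SNV clusters but splits blocks at
longer same-diagonal gaps so that length-neutral events (inversions,
substituted segments) are not absorbed; inversions shorter than
`join_gap` are a known blind spot.  Genomes beyond the guardrail are
aligned externally (`nucmer`/`minimap2`) and ingested with
`read_alignment_blocks()`.

`extract_small_variants()` re-aligns junction segments whose implied
length change is at most 50 bp with Needleman-Wunsch and left-aligns
indels (VCF normalization), so calls compare exactly against truth even
inside short repeats.  `classify_svs()` applies one deterministic
precedence per junction — CNV > inverted translocation > inversion >
translocation > large indel — using a coverage sweep for multi-covered
intervals (copy counts from coverage depth), a length-weighted longest
increasing subsequence over query positions as the syntenic backbone,
and junction gap arithmetic for large indels, suppressing junctions
already explained by a relocated or copied block.

The 50-bp boundary between small and large indels, the 500-kb SNV and
1-Mb SV density windows, and the >1-Mb ROH floor follow the
conventions of chromosome-scale diploid comparisons.  `detect_roh()`
needs a density cutoff; the default is 5% of the genome-wide mean SNV
density over 100-kb scan windows, with zero-variant windows always
qualifying (so a variant-free chromosome is wall-to-wall ROH).  The
overall heterozygosity rate counts one base per SNV plus the full
length of each indel and SV, once, over the maternal-side aligned
length; both conventions are explicit arguments.

# Site QC and the error partition

The per-site pileup diversity is
$\pi = 2\,(AT+AC+AG+TC+TG+CG)/(D(D-1))$ with the pairwise terms read
as products of base depths — the probability that two reads drawn
without replacement disagree.  A site is *complex* when $\pi > 0.4$
**and** the third-highest base depth exceeds 5 (both conditions, so an
even biallelic site with $\pi \approx 0.5$ is kept); sites under depth
10 are unusable.  The confident SNP set is built as
Set1 = B∩C, Set2 = A∪Set1, Set3 = Set2 minus complex/low-depth/unaligned
sites.

The evidence chain records the consensus base at five stages (raw
reads, corrected reads, pre-polish assembly, post-polish assembly,
short reads).  The published description names the chain but not its
decision rules; this package fixes one defensible table, applied in
order so classes are mutually exclusive: any N is unresolved; a final
base that matches the raw consensus but conflicts with both corrected
and short-read consensus is a *sequencing error*; a pre-polish base
that matched the short reads while the post-polish base departed is a
*polishing error*; agreement of final, corrected and short reads is a
*true variant*; anything else is unresolved.  Error rates divide class
counts by assayed bases (default: sites with complete chains).

# De novo mutation rate

Candidates require parents 0/0 and child 0/1 on one reference;
validation requires parents 1/1 and child 0/1 at the same site on the
other reference.  Filters (defaults: GQ ≥ 20, child allelic balance in
[0.3, 0.7], no parental alternative reads, per-individual depth within
half-to-twice its mean) must pass on both references.  Callability
counts double-homozygous-reference sites passing the depth/GQ/parental
filters; the allelic-balance loss belongs to the negative rate factor
$\alpha$, estimated by Monte Carlo as the rejection rate of simulated
true heterozygous offspring sites.  The rate is

$$\mu = \frac{M_{\mathrm{mat}} + M_{\mathrm{pat}}}
{C_{\mathrm{mat}}(1-\alpha_{\mathrm{mat}}) +
 C_{\mathrm{pat}}(1-\alpha_{\mathrm{pat}})}$$

with an exact (Garwood) Poisson 95% interval on the summed count.  The
default thresholds are stated here as this package's defaults, not as
the published study's (whose exact cut-offs live in supplementary
material).  X/Y sites can be excluded by restricting the input tables;
the recovery tests use autosomal layouts.  The parameter-recovery
condition exercised by the test suite is a 10-Mb haploid genome,
planted rate 5×10⁻⁷ per site per generation, paternal fraction 2/3,
depth 30, base error 10⁻³, 20 seeded replicates.

Why two references matter: a read-level false het call in the child
shows parents 0/0 on *both* references, never the 1/1 validation
pattern, because nothing entered either assembly.  The test suite
demonstrates this by planting no DNMs at an elevated base error:
single-reference discovery returns false candidates, the
cross-validated set is empty.

# Sex-linked sequences

Coverage tracks are peak-normalized: each sample is divided by the
midpoint of the modal histogram bin (bin width 5% of the median), which
anchors the two-copy state at 1 and makes the female/male (F/M) ratio
depth-independent.  Windows with F/M in [1.5, 2.5] are X-linked
(5-kb pass), in [0.0, 0.3] Y-linked (2-kb pass).  Zero-male windows use
a one-read-equivalent pseudocount and a ratio cap of 10, a convention
this package fixes because F/M is undefined at M = 0.  A scaffold is
called when 80% of its windows agree; a terminal run of ≥ 25 near-1
windows (ratio within [0.75, 1.25]) is annotated as a pseudoautosomal
region when — and only when — trimming it turns the remainder into a Y
call, so an autosome half-covered by X-like windows is not rescued into
a sex call.

Hi-C rescue compares each unplaced scaffold's interaction strengths
toward the Y against those toward autosomes/X with a two-sided Wilcoxon
rank-sum test, Benjamini–Hochberg corrected across scaffolds
(the published FDR method is unstated; BH is the default reading);
rescue additionally requires the median Y strength to exceed the
median autosome/X strength.  Scaffolds need strictly more than five
values on each side.  The synthetic interaction strengths are lognormal
(meanlog 0, sdlog 0.5), the rough shape of normalized contact counts.

`longest_rule_decollapse()` reconstructs a collapsed region: repeatedly
select the candidate contig with the longest backbone match that does
not overlap a previous selection (ties: earlier backbone start), order
selections by backbone position, fill uncovered stretches from the
backbone, and place exactly 1,000 N between consecutive placed contigs.
An independent step-by-step verifier in the test suite replays the rule
on random instances.

# Gametologue strata and dating

`compute_dn_ds()` implements Nei–Gojobori (1986) with Jukes–Cantor
correction: synonymous site fractions per codon averaged over both
sequences, differences averaged over mutational pathways that avoid
stop codons (falling back to all pathways if none avoids a stop),
$d = -\tfrac34\ln(1-\tfrac43 p)$, `NA` at saturation ($p \ge 3/4$).
Changes to stop codons count as non-synonymous.  A shared terminal
stop codon is dropped; an internal stop is an input error.  The
estimator is fixed to NG86+JC because the source analyses report
pairwise dS without naming a model; a different estimator can be
swapped in upstream of the segmentation since strata assignment only
consumes a `ds` column.

Strata are contiguous groups along the X: pairs ordered by position
are segmented by exact least-squares dynamic programming, with k
supplied or chosen by a BIC-style penalty ($n\log(RSS/n) + 4k\log n$).
With a dozen gametologues and appreciable estimator noise, automatic
selection of k is intrinsically unstable — isolating one noisy pair can
reduce the residual sum of squares as much as a true boundary — so k
should be supplied when external evidence (phylogeny, synteny) fixes
the stratum count; the penalty default is tuned to be conservative.
Pairs flagged as recent intra-species duplications with dS below a
floor (default 0.02) are excluded from all strata, mirroring how a
recently duplicated gametologue pair is not assignable to any stratum.
Labels S1..Sk are ordered by decreasing mean dS (S1 oldest), which
makes the label means monotone by construction.

Dating uses the molecular clock $T = d/(2r)$ — both copies accumulate
substitutions after recombination stops — with yearly rates given
directly or as per-generation rates divided by a generation time;
generation time has no default and must be supplied.  The range across
supplied rates is reported.  Dating methods beyond this generic clock
(e.g. multi-calibration schemes) are out of scope.

# Numerical choices and problem sizes

* Genotype calling uses a (depth, alt-count) lookup table per
  configuration; depths are clamped at the 1−10⁻¹² Poisson quantile.
* The built-in aligner computes identity by direct column comparison;
  junction refinement uses match 1 / mismatch −2 / gap open 6 /
  extend 1, a setting that places a single clean gap for an isolated
  indel in random sequence.
* The test suite runs its recovery studies at reduced but honest
  scales chosen to exercise the asymptotics: 10-Mb genomes and 20
  replicates for the DNM study, 18-Mb layouts and 20 seeds for the
  sex-linkage study, 150-250-kb toy diploids for alignment round
  trips, 1,000 null scaffolds for FDR control, 100 random instances
  for the longest rule.
* `sim_config()` defaults (SNV heterozygosity 1.3×10⁻³ per bp, depth
  30, base error 10⁻³, paternal fraction 2/3) are the study conditions
  of a highly heterozygous diploid trio sequenced at typical short-read
  depth.

# Known limitations

* The site-call renderer requires colinear references (no planted
  indels/SVs); structural classes are tested through the alignment
  route.
* Inversions shorter than `join_gap` merge into their flanks; SV
  breakpoints are resolved to within the anchor length.
* The evidence-chain decision table is one defensible formalization of
  a published description that omits its rules; absolute error-rate
  comparisons against the original pipeline are not meaningful beyond
  order of magnitude.
* The α correction covers discovery-side filtering only; validation-side
  filtering on the second reference removes a few percent of true DNMs
  and is left uncorrected, as in the published estimator.
* Automatic stratum-count selection is unreliable for small numbers of
  gametologue pairs (see above).
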