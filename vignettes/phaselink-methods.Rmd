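---
title: "Methods: proband-independent haplotyping and integrated PGT"
author: "phaselink"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: proband-independent haplotyping and integrated PGT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phaselink)
```

# The problem

Preimplantation genetic testing for monogenic disease (PGT-M) decides, per
embryo, whether a parental pathogenic variant was transmitted. Direct
genotyping of the variant in a few-cell trophectoderm biopsy is unreliable
on its own: multiple displacement amplification (MDA) drops one allele of a
heterozygote ("allele dropout", ADO) often enough that a single assay can
turn a carrier embryo into an apparent wild type. The standard remedy is
linkage: phase the carrier parent's chromosome into a *risk* haplotype (the
one bearing the variant) and a *non-risk* haplotype, then read out which
haplotype the embryo inherited from many surrounding markers, so that no
single genotyping error can flip the diagnosis. Classically that phase is
anchored on a proband or other affected relative; this package implements
the proband-independent alternative: the carrier's own DNA is sequenced as
barcoded linked reads, long molecules carry the variant together with
nearby heterozygous SNPs, and the phase is assembled directly from that
molecule-level co-observation evidence.

The same embryo libraries support aneuploidy screening (PGT-A). The package
implements the three analysis channels that complement each other:
read-depth copy number (Log2RR + circular binary segmentation), which is
blind to genome-wide ploidy changes; a chromosome-level Z score on
heterozygosity and B-allele frequency (BAF), which catches haploidy and
triploidy; and runs-of-homozygosity (ROH) detection, which flags
heterozygosity deserts that copy number cannot explain.

Everything runs on a bundled, seeded simulator, so the full pipeline is
testable end to end without sequencing data; real inputs in the same
formats (VCF, fragment TSV, window-count TSV) drop into the same functions.

# Parental phasing from barcoded fragments

## Evidence model

Each barcoded molecule is assumed to originate from one parental haplotype
and reports an allele (0 = ref, 1 = alt) at every heterozygous marker it
covers, with a per-observation error probability. Two sites co-observed on
one molecule therefore vote for their relative phase: equal alleles vote
"same orientation", unequal alleles vote "opposite". For sites $i,j$ the
edge weight is

$$w_{ij} = (\#\text{same}) - (\#\text{opposite}),$$

and its sign estimates the parity $h_i \oplus h_j$ of the haplotype vector
$h$ regardless of which haplotype each molecule came from.

## Assembly

`phaseSites()` 2-colors the co-observation graph greedily: edges are
processed by descending $|w|$ (ties broken by site order, so the result is
deterministic), merged with a parity-tracking union-find, and zero-weight
edges — exact ties, which carry no information — are skipped. Each
connected component becomes one haplotype block; orientation within a block
is arbitrary until signing.

The coloring is then refined against the minimum error correction (MEC)
objective, the number of allele flips needed to make every fragment
consistent with one of the two haplotypes
(`mecScore()` = $\sum_f \min(d(f, h), d(f, \bar h))$). Two move types are
used until neither improves: single-site flips, and *suffix flips* within a
block. The second is essential: when a weak junction (a single bridging
molecule with an error) mis-orients everything past it, every single-site
move increases MEC, but flipping the whole tail repairs it in one step. On
random 8–12-site instances with 10% allele noise the refined greedy result
attains the exhaustive-search minimum MEC in ≈99% of cases (the test suite
verifies ≥95% over 200 instances).

## Signing and informative SNPs

`signHaplotypes()` labels the haplotypes using only the carrier's own data:
molecules that span the pathogenic site vote with the allele they carry
there; the haplotype whose molecules carry the alt allele is signed *risk*.
Signing refuses (an explicit no-call, never a guess) when fewer than 5
molecules span the target or when fewer than 80% of the spanning molecules
agree with the assigned phase. Both thresholds are package choices — a tie
or a thinly covered target must not silently pick a side, because every
downstream embryo call inherits the signing.

`selectInformativeSnps()` keeps, within ±2 Mb of the target, the phased
sites where the *other* parent is homozygous: there the embryo genotype
plus the other parent's obligate allele deterministically reveal which of
the carrier's haplotypes was transmitted. Sites where both parents are
heterozygous cannot separate parental origin from genotypes alone and are
excluded.

# Embryo linkage

`assignEmbryoAlleles()` resolves each informative SNP into the transmitted
carrier allele and records a risk / non-risk vote. Missing genotypes
abstain. Genotypes that are impossible given the parents — typically a
homozygote missing the other parent's obligate allele, the signature of ADO
— abstain and increment a Mendelian-error counter; if more than 10% of
informative sites are Mendelian-inconsistent the whole embryo is no-called
(possible contamination).

`smoothAndDetectCrossovers()` takes the positional vote sequence, absorbs
any run shorter than `minRun = 3` into its neighbours (flagging those votes
as genotyping error), and reports a crossover between the remaining
opposite-label runs. With `minRun = 3`, a single ADO-driven wrong vote can
never create a crossover or flip a call.

`callInheritance()` applies the flanking-marker safeguard: the label is
called only from the smoothed segments immediately upstream and downstream
of the target, each needing ≥3 concordant votes; if the flanks disagree — a
crossover bracketing the target, the classical misdiagnosis risk — the
result is a no-call. A one-sided call (one flank absent or thin) is allowed
but flagged reduced-confidence, because real workups can be strongly
asymmetric in informative-SNP counts.

`callCarrierStatus()` combines per-parent labels under the inheritance
mode: autosomal dominant (risk from the carrier parent = affected),
autosomal recessive with a shared variant (both = Hom, one = carrier with
parent of origin), and compound heterozygosity (risk from both = compound
het). Any no-call label makes the embryo status no-call. Vote aggregation
is deliberately majority-with-smoothing rather than an HMM: at tens of
informative SNPs per side the transparent rule is equally accurate and
directly auditable; an HMM is a possible extension.

If the ploidy screen (below) is abnormal, linkage refuses with status
*phasing-failure* and reports no genotype — a triploid embryo has three
haplotypes and the biallelic linkage logic is invalid for it.

# Copy number (PGT-A depth channel)

`computeLog2RR()` scales the test sample and each reference to a common
total, takes per-window $\log_2(\text{test}/\text{median reference})$ with
a 0.5 pseudocount, masks windows whose raw median reference count is below
10, and centres the result. Centring is done in two steps: a median shift
(robust to an aneuploid chromosome, which would otherwise bias every other
window through the total-count scaling), then a mean re-centring over
chromosomes consistent with baseline — needed because segment calls work on
segment *means* and the log of an overdispersed count is left-skewed
(mean < median), which would otherwise bias every copy-number inversion by
a few percentage points of mosaic fraction.

`cbsSegment()` is classic circular binary segmentation: over the
circularized window sequence of one chromosome, find the arc maximizing the
pooled-variance two-sample $t$ statistic between arc and complement
(exhaustive over admissible cut pairs, minimum segment width 3 windows),
accept the split when its permutation p-value (1000 within-segment
shuffles) is below $\alpha = 0.01$, and recurse. Breakpoints are
deterministic given the seed.

`mergeAndCall()` merges adjacent segments whose means differ by <0.1,
inverts each segment mean to a mosaic fraction under the linear
cell-mixture model

$$f_\text{gain} = 2\cdot 2^{\bar r} - 2, \qquad
  f_\text{loss} = 2 - 2\cdot 2^{\bar r},$$

and assigns states by banding: $f < 0.2$ normal, $0.2 \le f < 0.8$ mosaic
(reported as a percentage), $f \ge 0.8$ full event with integer copy number
$\mathrm{round}(2 \cdot 2^{\bar r})$. The clinical mosaics this is meant to
report (30–55%) sit comfortably inside the band. One addition is a
baseline-deviation gate: a segment may be called abnormal only if
$|\bar r| \ge 3\,\hat\sigma/\sqrt{n}$, with $\hat\sigma$ the genome-wide
MAD of window log-ratios. The CBS permutation test guards *internal*
change-points but never tests a whole-chromosome segment against baseline;
without the gate, chromosome-mean noise at the default simulation noise
level crosses the 0.2 band on a few percent of chromosomes and spurious
"mosaic" calls appear in most cohorts. The factor 3 echoes the Z ≥ 3
convention used elsewhere in the method.

# Ploidy Z scores (genotype channel)

Depth ratios cannot see a uniform ploidy change — a triploid is "euploid"
in relative depth. The genotype channel can: `chromStats()` computes, per
chromosome over callable sites (depth ≥ 8, ≥ 50 sites), the heterozygous
call proportion and the mean $|BAF - 0.5|$ over het calls.
`zScores()` standardizes both against a panel of ≥10 diploid embryos and
flags a chromosome when $\max(|z_\text{het}|, |z_\text{BAF}|) \ge 3$. A
genome-wide call requires ≥80% of informative autosomes flagged in a
consistent direction: depressed heterozygosity → haploid-suspect (haploids
retain only error-driven het calls); elevated BAF deviation with the het
BAF mass pulled toward 1/3 and 2/3 (median chromosome BAF deviation ≥0.12,
the tri-modality guard) → triploid-suspect, reported as a "69,XNN"-style
string; anything else genome-wide → abnormal-unspecified. The 80% rule
exists so that one aneuploid chromosome can never masquerade as a ploidy
change. How to combine the two statistics is not prescribed anywhere;
taking the per-chromosome max with one shared threshold reproduces both
stated uses (haploidy via het loss, triploidy via BAF) with a single knob.

# Runs of homozygosity

`windowHetFraction()` computes per-window heterozygous fractions (1 Mb
grid, ≥20 callable sites, depth ≥ 8); the reference track is the panel
median per window. A window is an ROH candidate iff

$$\log_{10}\frac{F_1 + \varepsilon}{F_2 + \varepsilon} \le -1$$

*and* it does not overlap a non-normal copy-number segment — a deletion
explains its own heterozygosity loss and must be reported as CNV, not ROH.
Base 10 is chosen because it makes the printed threshold −1 a round
ten-fold heterozygosity reduction; $\varepsilon = 1/(2 \cdot
\text{callable sites})$ guards $\log 0$ and ties the guard to window
informativeness. Adjacent candidates merge into regions.

# The simulator: what it emulates, and what it does not

The generator produces every input with the statistical structure the
analyses assume:

* **Marker maps** — uniform positions, MAF ~ U(0.2, 0.5) in the workup
  region (U(0.1, 0.5) genome-wide), every marker heterozygous in at least
  one parent; the phasing-workup maps force heterozygosity in the focal
  carrier, because the method's marker set *is* that carrier's het SNPs.
  The default workup density is 800 markers per 5 Mb (one per ~6 kb) —
  conservative against the ~1 per 1.5 kb het density of real ±2 Mb
  windows, but dense enough that 40 kb-scale molecules connect the map.
* **Fragments** — one barcode = one molecule, drawn from one haplotype,
  placed uniformly; lengths are gamma with mean 40 kb (inside the 37–49 kb
  range of real linked-read libraries) and default sd = mean, i.e. the
  exponential law of randomly sheared high-molecular-weight DNA. The
  exponential tail matters: the long molecules are exactly what bridges
  sparse het sites, and with a short-tailed (normal) length model no
  parameter choice at 25× molecule coverage yields the multi-Mb phased
  blocks the method relies on. Per-observation allele error default 0.02.
* **Embryos** — per-chromosome transmitted haplotype with crossovers at
  specified positions; ploidy states diploid, haploid, triploid (extra
  copy = the non-transmitted maternal haplotype, the digynic route),
  whole-chromosome trisomy/monosomy, segmental gain/loss, each with an
  abnormal-cell (mosaic) fraction; forced-homozygous intervals emulate ROH
  as isodisomy of the transmitted maternal allele.
* **Genotypes** — MDA-style: symmetric single-allele dropout per
  heterozygous site (default 0.10), Poisson depth (default 30), binomial
  allele counts with per-read error 0.01, naive BAF threshold caller
  (het band 0.2–0.8, "./." at depth 0), plus an optional per-site
  post-hoc miscall rate for residual genotyping error.
* **Window counts** — negative binomial with mean
  $100 \cdot \text{CN}/2$ per 1 Mb window and dispersion 0.05
  (size = 20); mosaic states scale the expected copy number linearly,
  $\text{CN} = 2 + f\,(\text{CN}_\text{abn} - 2)$; the 20-sample
  reference panel is generated identically at CN 2.

Features of real data deliberately *not* modeled: GC and mappability bias
(the reference-median floor stands in for coverage masking), read-level
errors and duplicates (observations are molecule-level), barcode
collisions, gene/pseudogene homology, high-GC dropout, and the genotype
signature of *mosaic* CNVs (mosaic abnormalities act on the depth channel
only; genotypes come from the diploid majority). Passing tests therefore
demonstrate the statistical logic of the pipeline under its stated noise
models — not robustness to alignment artifacts or amplification bias
beyond ADO.

# Numerical and design choices

* Coordinates: 1-based inclusive for variant positions (VCF convention);
  0-based half-open for fragment intervals, windows, and BED output.
* Determinism: every generator takes a seed and restores the caller's RNG
  state; the pipeline derives all sub-seeds from one master seed, and two
  runs with the same seed produce byte-identical artifacts.
* Ties: phasing edges of equal weight are processed in site order;
  zero-weight edges are dropped; spanning fragments that tie between
  haplotypes are excluded from signing consistency.
* Degenerate inputs: no heterozygous sites → empty phase (not an error);
  a homozygous "carrier" or an unphased target → explicit error states;
  an all-masked or all-zero count track → error.
* Small indels are treated as biallelic codes exactly like SNVs throughout
  (the 4 bp deletions and point mutations of typical PGT-M cases share the
  same machinery); events larger than 50 bp belong to the CNV channel.

## Problem sizes in the test suite

The suite exercises the pipeline at desk scale, chosen to keep the
statistics meaningful: 200 random phasing instances against an exhaustive
MEC oracle; 50 phasing/signing workups at 25× coverage and 2% allele
error; 200 embryos (ADO 0.10) for linkage concordance; 100 null
chromosomes for CBS type-I calibration plus 15 trisomy and 20 mosaic-loss
recoveries; a 20-embryo diploid calibration set and one haploid/triploid
pair for the Z screen; and a 3 Mb forced-ROH recovery. The end-to-end
determinism check runs a reduced three-embryo cohort twice.

# Known limitations

* Phase is signed and extended only within the block containing the
  target; no barcode-bridging across block boundaries is attempted.
* Sex chromosomes are not modeled; ploidy karyotype strings report "XN" /
  "XNN" placeholders.
* The mosaic-fraction formula is the linear depth-mixture inversion; real
  biopsies can violate it (clonal structure, amplification bias).
* Breakpoints are window-resolution; no sub-window refinement.
* The linkage voter assumes a biallelic, autosomal locus with an available
  genotype for the other parent.
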