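# phaselink

Proband-independent linked-read haplotyping and integrated preimplantation
genetic testing (PGT), in R.

## The problem

Couples carrying a pathogenic variant can use PGT for monogenic disease
(PGT-M) to select unaffected embryos. Direct genotyping of a few-cell
trophectoderm biopsy is unreliable — multiple displacement amplification
drops one allele of a heterozygote (allele dropout, ADO) often enough to
turn a carrier embryo into an apparent wild type — so clinical practice
reads out *linkage* instead: which parental haplotype, risk or non-risk,
did the embryo inherit around the variant? Classically the phase between
the variant and its flanking markers is anchored on a proband or another
affected relative, which fails exactly for the families that need testing
most: incomplete families, *de novo* variants, suspected germline
mosaicism.

`phaselink` implements the proband-independent route. The carrier parent's
DNA is sequenced as barcoded linked reads; each long molecule co-observes
the variant with nearby heterozygous SNPs; the package assembles the two
parental haplotypes directly from that evidence, signs them *risk* /
*non-risk* by the allele they carry at the target, selects informative
SNPs within ±2 Mb, and votes each embryo's transmitted haplotype from its
genotypes — with crossover detection and explicit no-calls. The aneuploidy
arm (PGT-A) is included: per-window log2 read-count ratios segmented by
circular binary segmentation (CBS) with integer and mosaic copy-number
calls, chromosome-level heterozygosity/BAF Z scores that catch the
haploid/triploid states depth ratios cannot see, and runs-of-homozygosity
detection. A seeded simulator generates every input, so the whole pipeline
is testable without sequencing data.

## The core statistics

* **Phasing**: greedy minimum-error-correction (MEC) assembly. Sites
  co-observed on a molecule are joined with weight
  `w = (#same) − (#opposite)`; components are 2-colored by descending
  |w| and refined by single-site and block-suffix flips against
  `MEC(h) = Σ_f min(d(f,h), d(f,h̄))`.
* **Signing**: molecules spanning the target vote with their allele there;
  risk = the haplotype carrying alt. No-call below 5 spanning molecules or
  80% consistency.
* **Linkage**: per informative SNP (carrier heterozygous, other parent
  homozygous), the embryo genotype resolves the transmitted allele;
  votes are smoothed (runs < 3 absorbed as genotyping error), crossovers
  reported between surviving runs, and the call taken from the two flanks
  of the target — flank disagreement (a crossover at the target) is a
  no-call.
* **CNV**: `log2RR = log2(test/median reference)` per 1 Mb window,
  median-centred; CBS with a permutation test (α = 0.01); mosaic fraction
  from the linear cell-mixture inversion `f_gain = 2·2^r − 2`,
  `f_loss = 2 − 2·2^r`; states banded at f = 0.2 / 0.8.
* **Ploidy**: per chromosome, `z = max(|z_het|, |z_BAF|)` against a
  diploid panel; flagged at z ≥ 3; a consistent flag on ≥ 80% of autosomes
  makes the genome-wide call (haploid-suspect / triploid-suspect,
  "69,XNN").
* **ROH**: windowed heterozygosity ratio; candidate iff
  `log10(F1/F2) ≤ −1` and the window does not overlap a non-normal CNV
  segment.

See `vignettes/phaselink-methods.Rmd` for the full model description,
parameter defaults and limitations.

## Worked example

Run the whole pipeline — family simulation, parental workup, reference
panels, and the integrated report for an eight-embryo cohort — from one
seed:

```r
library(phaselink)
res <- runEndToEnd(defaultConfig(), seed = 7)
res$signed$maternal
#> SignedHaplotypePair (maternal): signed, risk = hap A (consistency 1.00, 23 spanning fragments)
#>   phased span: 2484177 bp upstream / 2497468 bp downstream; 235 informative SNPs
```

The maternal carrier's haplotypes were assembled from ~3,100 simulated
40 kb molecules at 25× coverage: 23 molecules span the pathogenic site and
all of them agree on which haplotype carries it (consistency 1.00), the
phased block extends ~2.5 Mb on both sides, and 235 phased SNPs
(102 upstream / 133 downstream) are informative for embryo linkage.

```r
print(res$cohort, row.names = FALSE)
#>  embryo     pgtm      pgtmStatus                        cnv           ploidy rohRegions
#>      E1       WT      unaffected                    Euploid           normal          0
#>      E2 Het, Mat        affected                    Euploid           normal          0
#>      E3 Het, Mat        affected                    Euploid           normal          0
#>      E4       WT      unaffected                         +4           normal          0
#>      E5 Het, Mat        affected         -(mosaic)(9) (39%)           normal          0
#>      E6       WT      unaffected                    Euploid           normal          1
#>      E7       WT      unaffected dup(9)(7000001-20000000)x3           normal          0
#>      E8        - phasing-failure                     69,XNN triploid-suspect          0
```

Reading the cohort: the simulated family is an autosomal-dominant maternal
carrier, so embryos that inherited the maternal risk haplotype are
`Het, Mat` (affected); E2 carries a crossover upstream of the target that
the smoother detects without changing the call. On the PGT-A side, E4 is a
whole-chromosome trisomy (`+4`), E5 a 30% mosaic monosomy of chromosome 9
(called at 39% from its segment mean), E7 a 10 Mb segmental duplication,
E6 carries a 3 Mb run of homozygosity, and E8 is a triploid: its depth
profile is euploid, the Z-score screen flags every chromosome
(`69,XNN`), and linkage correctly refuses with `phasing-failure` instead
of reporting a genotype. With `outDir =` set, every artifact (parental
VCF, fragment TSVs, signed-haplotype JSON, embryo VCFs, window-count
TSVs, segment/ROH BED, per-embryo report JSON, cohort TSV) is written to
disk; two runs with the same seed are byte-identical.

A thin command-line wrapper over the same functions is installed at
`inst/cli/phaselink.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/phaselink.R", package="phaselink"))')" \
    end-to-end --seed 7 --out-dir out/
```

with stage subcommands (`simulate`, `phase`, `linkage`, `cnv`, `ploidy`,
`roh`) operating on the on-disk formats. File formats: VCF 4.2
(biallelic; phased `|` genotypes for parents, `GT:DP:AD` for embryos),
fragment TSV (`barcode, chrom, start, end, site:allele:qual;...`),
window-count TSV (0-based half-open windows, one column per reference
sample), BED for segments and ROH regions, JSON for all reports.

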