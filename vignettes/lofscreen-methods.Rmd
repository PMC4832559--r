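---
title: "Methods: loss-of-function screening and fertility association"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: loss-of-function screening and fertility association}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lofscreen)
```

## The problem

Recessive variants that abolish the function of a gene needed for male
fertility are expected to be rare, to be carried only heterozygously by
fertile sires, and to never appear homozygous in a fertile population —
homozygotes, if viable, end up infertile and are never sampled. The
screen implemented here exploits exactly that signature. A small
*detection panel* of sequenced genomes is searched for SNVs inside
candidate genes; a variant survives when it is

1. located inside a candidate-gene transcript span,
2. absent from known-variant databases (novel),
3. never homozygous mutant in the panel while the mutant allele is seen
   in at least one heterozygote, and
4. predicted to be high-impact: stop gained, stop lost, start lost, or a
   splice donor/acceptor disruption.

Survivors are genotyped in a large multi-breed *validation cohort* and
characterised by frequency statistics, Hardy–Weinberg tests, breed
sharing, association with breeding values, and finally a three-class
verdict.

## Consequence classification

The classifier evaluates one annotated transcript per gene. Coding
positions are mapped to a 1-based offset in the spliced coding sequence
(strand-aware: minus-strand transcripts are read right to left with
complemented bases), the affected codon is mutated, and categories are
assigned by codon comparison under the standard genetic code. Protein
notation follows the usual one-letter convention (`p.W155*`, `p.M1T`).
Splice-site disruption is positional: the first two and last two bases of
an intron, in transcript orientation, corresponding to the essential
GT/AG dinucleotides.

Choices made where the design was open:

* **Splice window.** Two intronic bases per side is the conventional
  definition of an essential splice site and is what a HIGH-impact
  filter targets; the width is nevertheless a parameter
  (`splice_window`), and the tests exercise a zero-width window.
* **Start loss.** Any mutated initiator codon other than `ATG` is a
  start loss, including third-base changes; there is no rescue logic for
  downstream in-frame starts.
* **One transcript per gene.** No canonical-transcript election; the
  annotation provides the transcript to judge against.
* **SNVs only.** Frameshift and exon-loss categories concern indels,
  which are outside the analysis scope.
* **Micro-introns.** If an intron is narrower than twice the splice
  window a position could sit in both footprints; it is attributed to
  the nearer intron end, donor on ties. The generator never emits such
  introns; the rule only guards degenerate annotations.

The classifier is verified against an independent oracle that rebuilds
the reference and mutated coding sequences in full, translates both with
an unrelated codon implementation, and diffs the proteins — over random
multi-exon genes on both strands.

## Screening rules

Missing genotypes carry no evidence: a site is retained when
`n_hom_alt == 0` and `n_het >= 1` among non-missing calls, so per-site
denominators vary, and a site where every genotyped sample is
heterozygous is retained (only the mutant homozygote is barred). The
novelty filter matches known sites on (chrom, pos, ref, alt) by default;
known lists without allele columns match positionally, and
`match_alleles = FALSE` reproduces a purely positional exclusion. The
filter cascade is order-sound (the genotype filter commutes with the
novelty filter), which the tests assert, and sites inside overlapping
genes yield one record per (site, gene) pair.

## Per-site statistics

With genotype counts $n_{AA}, n_{AB}, n_{BB}$ the mutant allele
frequency is $q = (2n_{BB}+n_{AB})/2n$; HET is $n_{AB}/n$. The HWE test
is the classical 1-df chi-square on the three genotype classes with
expected counts $p^2n, 2pqn, q^2n$ — deliberately without a continuity
correction, which is what reproduces printed chi-squares such as 22.094
and 120.250 from their count tables. Monomorphic sites return
$X^2 = 0$ with an undefined P-value and a flag rather than an error.

The expected mutant-homozygote count $q^2 n_\mathrm{ref}$ exposes
$n_\mathrm{ref}$ as a parameter because two conventions coexist: each
site's own genotyped $n$ (per-site tables) and the full cohort size
(cohort-level expectations). Pipeline outputs label which was used.

MAF groups use a closed group-III interval $[0.01, 0.1]$ so that
frequencies of exactly 0.01 or 0.1 are "low" rather than rare/moderate —
the binning that places observed validation frequencies like 0.0110 and
0.0125 in group III. Panel summaries are unweighted means over sites and
include zero-MAF sites in the denominator.

## Association models

Genotype enters both models as an unordered factor, matching the
genotype-means presentation used for EBV data; no additivity is assumed,
which matters when the interesting signal is a large homozygote
deviation at low frequency. The fixed-effect model is an ordinary
one-way ANOVA: overall F test, $R^2$ = model SS over total SS,
per-genotype means with standard errors.

The mixed model adds a random animal effect with covariance
$\sigma_g^2 K$ from the identity-by-state kinship of a QC-filtered chip
(IBS = average shared-allele fraction per SNP pair: 1 for identical
genotypes, 0.5 for het vs hom, 0 for opposite homozygotes). REML
estimation profiles the restricted likelihood down to the variance ratio
$\delta = \sigma_e^2/\sigma_g^2$ after one spectral decomposition of
$K$, optimising $\log\delta$ on $[\log 10^{-5}, \log 10^{5}]$ (Brent);
the genotype term is tested by an F test comparing genotype and
intercept models under the full-model $\hat\delta$. With $K = I$ the
ratio is unidentifiable but every $\delta$ yields the same covariance up
to scale, and the test reduces exactly to the fixed-effect F test — a
reduction the tests check to $10^{-6}$. A non-positive-semidefinite $K$
(possible after missing-data averaging) is bent by minimal diagonal
inflation with a warning. REML rather than ML avoids the downward bias
in $\sigma_g^2$ at the small fixed-effect ranks used here.

Bonferroni correction is $\min(1, m p)$ with $m$ defaulting to the
number of variants actually tested in the scan; reports carry full
precision so corrected values are reproducible from nominal ones.
De-regressed EBVs are taken as input — no de-regression is implemented —
and the phenotype column is selectable so EBV and de-regressed-EBV
analyses are both pass-through.

## Classification

Class I requires a tested, Bonferroni-significant association at
$\alpha = 0.05$ (the conventional experiment-wide level; the source
material reports significance without stating $\alpha$). Class II
requires the mutant allele observed, the mutant homozygote absent, and
carriers in more than one breed. Everything else — private variants,
monomorphic variants, all-three-genotype variants without association —
is class III. The rules partition any input; variants never tested for
association can still be class II or III.

Applied to the bundled 17-variant validation count table, these rules
give 1 class-I, 9 class-II and 7 class-III variants: the nine
missing-homozygote non-private candidates are exactly the nine the
source narrative names, although its own summary table groups them as
10/6 — an internal inconsistency of that table (its text and discussion
count 9) that the rules cannot and do not reproduce.

## The synthetic study

The generator produces every input the pipeline reads, with the
statistical structure the analysis assumes:

* **Genome and genes** — random contigs carrying multi-exon genes on
  both strands, valid `ATG…stop` coding sequences without internal
  stops, canonical GT/AG introns. Defaults: 15 genes, 2–6 exons,
  120–320 codons, introns 60–400 bp.
* **Detection panel** — 11 samples with the breed composition of a
  mixed sequencing panel (two Hanoverians, Arabian, Sorraia, Dülmen,
  Icelandic, Przewalski, Standardbred, Norwegian Fjord, Arabian mare,
  Thoroughbred reference). Planted variants are constructed to have an
  exact consequence category (verified by classification at plant time)
  and an exact genotype pattern; negative controls include a
  database-known variant, a variant with a homozygous-mutant sample and
  low-impact intronic variants, and the matching known-sites file is
  emitted in the same TSV format as real database exports.
* **Validation cohort** — 337 stallions in 19 breeds, largest breed
  "Hanoverian" with 226 (216 phenotyped), the remainder spread over 18
  breeds. Genotypes per breed follow inbreeding-adjusted frequencies
  $p^2+Fpq,\ 2pq(1-F),\ q^2+Fpq$; each breed carries a planted allele
  with probability `breed_share` (default 0.6), generating realistic
  breed-sharing and private patterns; 1% missingness.
* **Chip and kinship** — 54,602 SNPs (the size of a dense equine
  genotyping array) with MAF drawn uniformly on \[0.01, 0.5\] and 2%
  missingness, sampled within half-sib families (default size 10, the
  AI-sire-centric design): each offspring receives one sire haplotype
  allele plus a population allele per SNP. The pedigree kinship (1 on
  the diagonal, 0.25 between half sibs) is emitted as truth.
* **Phenotypes** — $y = 100 + \text{genotype effects} + u + e$ with
  $u \sim N(0, h^2\sigma^2 K_\mathrm{true})$,
  $e \sim N(0, (1-h^2)\sigma^2)$, standardised to mean 100, SD 20.
  Default $h^2 = 0.5$: de-regressed EBVs are pseudo-phenotypes whose
  information content reflects EBV reliabilities around 0.7, so a
  substantial genetic fraction is the realistic regime (the raw
  per-estrus trait itself is far less heritable). The default planted
  effect shifts heterozygotes by −1 and mutant homozygotes by −41
  phenotype points — a large recessive deviation at moderate allele
  frequency, the configuration the screen is designed to flag.

All randomness flows from one master seed via fixed per-stage streams:
a fixed seed gives byte-identical output files, which the tests assert.

What the generator does **not** emulate: linkage disequilibrium and
recombination maps (chip SNPs are independent given the pedigree),
sequencing error and genotype uncertainty, selection, maternal pedigree
structure, and multi-transcript gene architecture. Passing tests
therefore demonstrate the correctness and calibration of the pipeline's
logic and statistics under the assumed generating model, not robustness
to artefacts of real sequencing data.

## Numerical choices and problem sizes

Tolerances: printed-value checks use the printed rounding; REML uses a
relative tolerance of $10^{-8}$ on $\log\delta$; eigenvalues are
clamped at zero after bending. Degenerate inputs: monomorphic sites are
flagged rather than tested; single-genotype-class sites are marked
untestable with `NA` P-values; sample pairs with no jointly genotyped
chip SNP get `NA` kinship, which the decomposition refuses with a clear
error.

The simulation-based checks run at sizes chosen to balance statistical
resolution against a laptop-scale test run: HWE calibration with 2000
multinomial replicates; mixed-model calibration with 1000 null sites on
300 stallions in 15 half-sib families of 20 with a 2000-SNP chip
(rejection near 0.05 for the mixed model while the uncorrected model
inflates about three-fold); heritability recovery as the mean of five
REML fits at $n = 500$; variance-explained recovery as the mean of 30
fixed-effect fits at $n = 216$ with an effect sized to 11% of variance;
screening recovery across 20 independent seeds; and one full-scale
end-to-end run (337 stallions, 54,602 chip SNPs), which completes in
well under five minutes on a single core.

## Limitations

The classifier judges one transcript per gene and ignores NMD, UTR and
regulatory consequences; the novelty filter is only as good as the
known-site lists; IBS kinship is an affine, not exact, estimate of
additive relatedness, so the heritability parameter is interpretable
only relative to the kinship matrix actually fitted; and the class-II
logic is a screening heuristic — absence of mutant homozygotes in a few
hundred animals is weak evidence at low $q^2 n$, which is exactly why
the expected-count column is reported next to it.
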