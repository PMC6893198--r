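---
title: "Haplotype-derived allele frequencies: model, windows, and accuracy"
author: "hafkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Haplotype-derived allele frequencies: model, windows, and accuracy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the statistical model behind hafkit, the numerical
choices in its implementation, and the assumptions of its simulators. It is
a methods reference, not a tutorial; see the README for a worked example.

## Setting

An evolve-and-resequence population is founded from $H$ fully sequenced,
homozygous inbred lines and evolves for $G$ generations. Because
recombination has had little time to act, every chromosome in the
population is a mosaic of founder haplotypes. Pooled sequencing of $n$
sampled individuals at empirical depth $C$ yields reads whose local origin
is one of the $H$ founder haplotypes; the quantity of interest is the
pool's allele frequency at each of the panel's segregating biallelic sites.

## Window haplotype-frequency model

Within a genomic window small enough to contain no recombination
breakpoint, each read $r$ is an error-prone copy of one founder haplotype.
With window haplotype frequencies $f = (f_1, \dots, f_H)$ on the simplex,
the likelihood of the reads in the window is a mixture:

$$ L(f) = \prod_r \sum_{h=1}^{H} f_h \, P(r \mid h). $$

$P(r \mid h)$ multiplies per-site base terms over the SNPs the read
covers: a base matching founder $h$'s allele contributes $1-\varepsilon$,
a mismatching base (including bases that are neither REF nor ALT)
contributes $\varepsilon/3$, with $\varepsilon = 10^{-Q/10}$ from the base
quality, clamped to $(10^{-12}, 0.75]$. Paired mates are merged into one
observation per template; where mates overlap a site, the higher-quality
base wins. Only SNP positions enter the likelihood: non-SNP bases are
identical across founders and would contribute a constant factor.

$\log L(f)$ is concave in $f$ (a sum of logs of linear functions), so the
maximiser is unique up to flat directions and independent of the interior
starting point. It is found by EM: reads are softly assigned to founders by
posterior probability, and $f_h$ is updated to the mean posterior.
Convergence is declared when the largest frequency change under one EM map
application falls below `tol` (default $10^{-6}$).

### Numerical implementation

- Likelihood assembly is sparse: with ALT/REF indicator triplets
  $(r, j, w)$, where $w = \log(1-\varepsilon) - \log(\varepsilon/3)$, the
  reads-by-founders log-likelihood matrix is
  $L = \text{base} + \text{rowSums}(B) + (A - B) G^\top$ with $A$, $B$
  sparse and $G$ the founder genotype matrix.
- Row maxima are subtracted before exponentiation; they cancel in the
  posteriors and add a constant to the log-likelihood.
- The EM core (C++) is accelerated with SQUAREM extrapolation
  (Varadhan & Roland 2008): two EM steps define an extrapolated point,
  backtracked toward plain EM while outside the simplex and rejected if it
  would decrease the log-likelihood. By concavity this changes only the
  iteration count (measured: identical effective coverage, $\sim$20×
  fewer iterations than plain EM, whose terminal convergence is slow along
  flat directions when founders are locally similar).
- Consecutive overlapping windows share ~90% of their reads, so each
  window's EM is warm-started from the previous window's estimate mixed
  with 5% uniform mass (EM fixes exact zeros, so starts must be interior).
- Windows with no informative read fall back to uniform frequencies with a
  warning.

### Window chunking

The plan generated by `build_plan()` contains both the frequency windows
and larger "likelihood windows" (10× the size, stepping by half). In
workflows built on external haplotype-inference engines the likelihood
model is materialised per likelihood window and shared by the frequency
windows inside it. In hafkit the per-read likelihood is exact and cheap to
subset, so observations are extracted once per chromosome and subset per
frequency window; the likelihood windows are kept in the plan as a
chunking contract. Results are identical to computing each window's
likelihood directly (unit-tested).

## From window frequencies to HAFs

The frequency windows tile the chromosome with a step of 10% of the window
size, so interior sites are covered by exactly ten windows. The weight
vector at a site is the unweighted mean of the frequency vectors of all
windows containing it, and the haplotype-derived allele frequency is

$$ \mathrm{HAF}(s) = \sum_{h} w_h(s) \, a_h(s), $$

where $a_h(s)$ is 1 if founder $h$ carries ALT, 0 if REF, and — when
founder $h$'s call at $s$ is missing — the ALT fraction among the founders
genotyped at $s$. The fractional fallback uses the *original* founder
table even when inference ran on an imputed copy, so imputation choices
never leak into the per-site allele encoding. Terminal windows are clipped
at the chromosome end rather than dropped, so edge sites are covered by at
least one window (with fewer windows averaged, hence noisier estimates —
visible as slightly elevated error within one window size of the ends).

## Window sizing

Unrecombined fragment lengths after $G$ generations at per-bp
recombination rate $R$ on a chromosome of length $L$ are modelled as
exponential with rate

$$ \lambda = \frac{L R G + 1}{L}, $$

the $+1$ accounting for chromosome ends. The window size is the $q$-th
quantile `qexp(q, lambda)` (default $q = 0.18$), rounded to the nearest
kb, floored at 1 kb, capped at $L$: about 18% of fragments are then
shorter than a window. The model is an idealisation in two respects worth
knowing: (i) it is calibrated to the mean (the true spacing distribution
includes boundary-censored segments); (ii) simulated or real populations
founded from homozygous lines hide first-meiosis crossovers (identical
homologs), so early-generation fragments run longer than the model by
roughly a factor $G/(G-1)$ — negligible for the $G \gtrsim 10$ regimes
where adaptive sizing matters.

## Accuracy metric

For estimates $\hat p$ against known truth $p$ over $n$ sites,
effective coverage is

$$ \mathrm{EC} = \frac{\sum_s p_s (1-p_s)}{\sum_s (\hat p_s - p_s)^2}, $$

the binomial sampling depth that would produce the same total squared
error. Taking the ratio per site-set makes EC invariant to the underlying
allele-frequency spectrum (unit-tested against uniform and U-shaped
spectra). Fixed sites ($p \in \{0, 1\}$) are included by default: they add
nothing to the numerator but their estimation error counts, which is the
conservative choice and matters at late generations when a large fraction
of sites has fixed. `accuracy_report(..., drop_fixed = TRUE)` is available
for the alternative convention.

## Simulators

The built-in simulators exist to validate the estimator and measure EC at
known truth:

- **Panel**: sites placed uniformly at a chosen density; the ALT-carrier
  count $k$ at each site is drawn from a neutral spectrum
  $P(k) \propto 1/k$ (or uniform), carriers chosen independently per site.
  This independence is a deliberate simplification: real inbred panels
  share long haplotype blocks, which concentrate read information
  locally. Estimation under the independent-sites panel is therefore
  *harder* at a given read budget than on real panels — synthetic ECs are
  conservative relative to experiments with comparable parameters.
- **Forward simulation**: $N$ diploids, non-overlapping generations,
  founders assigned homozygous at random. Trait
  $T = s \cdot \#\text{ALT alleles at selected sites} + N(0, V_e)$
  (so genotypes contribute $0/s/2s$), fitness $\max(0, 1 - |1 - T|)$,
  parents drawn with probability proportional to fitness (selfing
  allowed), Poisson($LR$) crossovers per transmitted gamete placed
  uniformly. Note that early in a simulation the population mean trait is
  far from the optimum, so fitness is dominated by the environmental noise
  and the $\max(0,\cdot)$ truncation — effectively strong viability
  selection on noise, which depresses the effective population size and
  accelerates drift/fixation relative to a neutral Wright–Fisher model
  with the same census size.
- **Reads**: 150 bp paired-end; fragment length uniform on 450–500 bp
  (read as total fragment length); fragment start uniform; source
  chromosome uniform over the pool; per-base error rate 0.002 with
  erroneous bases assigned Q10 and correct bases Q30; alignments are
  emitted as SAM at the true positions with all-match CIGARs, so no
  aligner is needed. The SNP-observation decoder nonetheless handles
  arbitrary CIGARs (deletions spanning a SNP leave it unobserved).

## EC prediction model

Across simulation grids, $\log_{10}(\mathrm{EC})$ is approximately linear
in $\log_{10}(R_{win})$ (mean reads overlapping at least one SNP per
frequency window) and $\log_{10}(1 + M)$ ($M$ = percent of founder calls
missing, 0–100 scale — the $1+M$ transform is scale-sensitive, so the
units matter):

$$ \log_{10}(\mathrm{EC}) = a \log_{10}(R_{win}) + b \log_{10}(1+M) + c. $$

The model is linear in $(a, b, c)$ after the transforms, so `ec_fit()`
solves it by ordinary least squares on the log scale (equivalent to
nonlinear least squares on that objective). Degenerate designs (a single
distinct $R_{win}$ or $M$ value) are rejected by name.

## Problem sizes and runtime

The reference measurement scale is a 5 Mb chromosome with 99 founders at
~12.3 SNPs/kb (~61,600 sites). On one CPU: 1x reads with 1000 kb windows
run in ~20 s end to end (simulation included); 10x reads with 100 kb
windows (500 windows, ~3,200 informative templates each) in ~70 s; a
50-generation forward simulation of 1,000 diploids plus 5x inference with
adaptive (~142 kb) windows in ~40 s per replicate.

## Limitations

- Missing founder genotype imputation (`nearest_neighbor`: majority vote
  over the k = 20 founders sharing the most genotyped sites, ties broken
  toward the site's major allele, then REF) is a pragmatic default, not a
  validated genotype imputation method.
- The independent-sites panel generator bounds realism: it cannot emulate
  panel LD, population structure among founders, or genotyping error.
- The error model treats bases as independent given the source haplotype;
  indels and mapping error are out of scope (reads are pre-aligned).
- At late generations, accuracy is dominated by regions where selection
  makes local haplotype frequencies change steeply; window-averaged
  weights smooth across such gradients, and EC becomes strongly
  seed-dependent there.
- EC quantifies read-sampling error against the *sampled pool's* truth;
  individual-sampling variance (pool vs population) is a separate, additive
  consideration not treated here.
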