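# hafkit

Haplotype-derived allele frequencies for evolve-and-resequence (E+R)
experiments.

## What it does

E+R experiments found a population from a modest panel of fully sequenced
inbred lines, let it evolve for tens of generations, and track allele
frequencies from pooled sequencing. For those short timescales every genome
in the population is a mosaic of founder haplotypes, so the pool's allele
frequencies are determined by local founder-haplotype frequencies. hafkit
exploits this: instead of estimating each site's frequency from the handful
of reads covering it (the raw pileup), it

1. estimates the frequency of every founder haplotype in overlapping
   genomic windows, by an EM fit of a mixture model in which each read is
   probabilistically assigned to founders via a per-base error model;
2. computes the **haplotype-derived allele frequency (HAF)** at every
   segregating site as the weighted sum of the founders' alleles,
   `HAF(site) = Σ_h w_h · a_h`, where the weights average the frequency
   estimates of all windows overlapping the site (interior sites fall in
   exactly 10 windows, since windows step by 10% of their size) and `a_h`
   is founder *h*'s allele (the alt fraction among genotyped founders when
   *h*'s call is missing).

Every read in a window then informs every site in it, which multiplies the
effective information per site by orders of magnitude at low sequencing
depth.

Two supporting pieces make this practical:

- **Recombination-scaled windows.** Haplotype inference assumes no
  recombination breakpoint inside a window. Unrecombined fragment lengths
  after `G` generations at recombination rate `R` on a chromosome of length
  `L` are modelled as exponential with rate `λ = (L·R·G + 1)/L`; window
  size is set to the q-th quantile (default q = 0.18) of that distribution,
  so windows shrink as recombination proceeds.
- **Effective coverage (EC).** Accuracy is reported as the binomial
  sequencing depth that would produce the same error:
  `EC = Σ p(1−p) / Σ (p̂ − p)²` over sites with known truth. EC is
  invariant to the allele-frequency spectrum and directly comparable to
  empirical depth.

The package also ships a forward-in-time simulator (founder mosaics,
Poisson crossovers, additive trait with an optimum, fitness-proportional
reproduction), a pooled read simulator emitting pre-aligned SAM, a
log-linear EC prediction model (`log10(EC) = a·log10(Rwin) +
b·log10(1+M) + c`, with `Rwin` the mean informative reads per window and
`M` the percent of missing founder calls), and a command-line interface.

## Worked example

Twenty founders on a 1 Mb chromosome, 12 generations of neutral
recombination, 100 diploids pooled and sequenced at 5x:

```r
library(hafkit)

# 1. founder panel: 20 inbred founders on a 1 Mb chromosome
panel <- generate_panel(n_founders = 20, L = 1e6, snp_density = 0.005,
                        seed = 42)
print(panel)
#> founder_panel: 1000000 bp reference; snp_table: 20 founders x 5000 sites on chrSim (78-999777)
#>   missing calls: 0 (0.00%)

# 2. an evolved, pooled sample
pop <- forward_simulate(panel, G = 12, R = 1e-7, N = 500, seed = 43)
print(pop)
#> population: 500 diploids at generation 12; mean 2.0 founder segments per chromosome
pool <- sample_pool(pop, panel$table, n_individuals = 100, seed = 44)
sam <- tempfile(fileext = ".sam")
simulate_reads(pool, panel, panel$table, coverage = 5, file = sam, seed = 45)

# 3. recombination-scaled windows and haplotype inference
plan <- build_plan(window_params(L = 1e6, R = 1e-7, G = 12))
print(plan)
#> window_plan: 112 frequency windows of 90000 bp (step 9000 bp), 3 likelihood windows of 900000 bp on [0, 1e+06)
hf <- infer_chromosome(sam, panel$table, plan)
print(hf)
#> hap_freqs: 112 windows x 20 founders on chrSim; 112/112 windows converged; median reads/window 1168

# 4. haplotype-derived vs raw allele frequencies, scored against the truth
haf   <- haf_chromosome(hf, panel$table)
raw   <- raw_af(sam, panel$table)
truth <- truth_track(pool, panel$table)
print(accuracy_report(haf, truth))
#> accuracy_report: 5000 sites (0 excluded)
#>   RMSE 0.02474 | effective coverage 216.0x
print(accuracy_report(raw, truth))
#> accuracy_report: 4976 sites (24 excluded)
#>   RMSE 0.18308 | effective coverage 3.9x
```

At 5x depth the raw pileup achieves an effective coverage of 3.9x; the
HAF track achieves 216x — a 55-fold accuracy gain, enough to detect
strong selection from very cheap sequencing.

`run_end_to_end()` wraps steps 1–4 (plus optional missing-call masking and
imputation) into one deterministic call and can write all artifacts with an
md5 manifest.

## Command line

`inst/scripts/hafkit.R` exposes the pipeline as subcommands:

```sh
Rscript inst/scripts/hafkit.R simulate --out-dir demo --n-founders 12 \
    --length 300000 --snp-density 0.003 --coverage 5 --seed 7
Rscript inst/scripts/hafkit.R infer --sam demo/pool.sam \
    --snp-table demo/founders.snp --length 300000 --window-size 50000 \
    --out demo/freqs.tsv
Rscript inst/scripts/hafkit.R haf --freqs demo/freqs.tsv \
    --snp-table demo/founders.snp --out demo/haf.tsv
Rscript inst/scripts/hafkit.R ec --est demo/haf.tsv --truth demo/truth.tsv
# {"n_sites":900,"rmse":0.0371...,"effective_coverage":111.4...}
```

`founders` converts a VCF of genotyped lines into the SNP-table format,
`windows` prints/exports a window plan, `rawaf` computes the pileup track,
and `ecmodel fit`/`ecmodel predict` handle the EC prediction model.

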