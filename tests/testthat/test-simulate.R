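test_that("panel generation honours spectrum, density and missingness", {
  panel <- generate_panel(10, 2e5, snp_density = 0.002, seed = 1)
  tab <- panel$table
  expect_equal(length(tab$pos), 400L)
  expect_false(anyNA(tab$geno))
  expect_true(all(diff(tab$pos) > 0))
  expect_true(all(tab$ref != tab$alt))
  # reference sequence carries the REF alleles
  expect_equal(substring(panel$ref, tab$pos[1:50], tab$pos[1:50]),
               tab$ref[1:50])
  # n = 2 founders: every site has exactly one ALT carrier
  p2 <- generate_panel(2, 1e5, snp_density = 0.002, seed = 2)
  expect_true(all(colSums(p2$table$geno) == 1L))
  # missing calls at the requested rate
  pm <- generate_panel(10, 2e5, snp_density = 0.002, missing_rate = 0.05,
                       seed = 3)
  expect_equal(mean(is.na(pm$table$geno)), 0.05, tolerance = 0.01)
  expect_true(all(colSums(!is.na(pm$table$geno)) > 0))
  # complete truth genotypes agree with the masked table where observed
  expect_false(anyNA(pm$truth_table$geno))
  keep <- !is.na(pm$table$geno)
  expect_equal(pm$table$geno[keep], pm$truth_table$geno[keep])
})

test_that("neutral spectrum follows the 1/k law", {
  set.seed(4)
  panel <- generate_panel(12, 5e6, snp_density = 0.01, seed = 4)
  k <- colSums(panel$table$geno)      # 50k sites
  expected <- (1 / 1:11) / sum(1 / 1:11)
  obs <- tabulate(k, nbins = 11)
  chi <- suppressWarnings(chisq.test(obs, p = expected))
  expect_gt(chi$p.value, 0.001)
})

test_that("generation 0 populations are unrecombined founder copies", {
  panel <- generate_panel(6, 1e5, snp_density = 0.002, seed = 5)
  pop <- forward_simulate(panel, G = 0, R = 1e-8, N = 20, seed = 6)
  expect_equal(length(pop$chroms), 40L)
  expect_true(all(vapply(pop$chroms, function(ch) length(ch$fid), 1L) == 1L))
  # diploid individuals start homozygous
  fids <- vapply(pop$chroms, function(ch) ch$fid, 1L)
  expect_equal(fids[seq(1, 39, 2)], fids[seq(2, 40, 2)])
})

test_that("neutral allele frequencies are martingales across replicates", {
  panel <- generate_panel(8, 5e4, snp_density = 0.004, seed = 7)
  site <- which(colSums(panel$table$geno) == 4L)[1L]  # AF 0.5 site
  regime <- selection_regime(site, s = 0, Ve = 0.01)
  set.seed(8)
  finals <- replicate(200, {
    pop <- forward_simulate(panel, G = 10, R = 1e-8, N = 50,
                            regime = regime, track_af = TRUE)
    pop$af_trajectory[11, 1]
  })
  inits <- 0.5  # expected initial AF from random homozygous founder draws
  se <- sd(finals) / sqrt(length(finals))
  expect_lt(abs(mean(finals) - inits), 3 * se)
})

test_that("positive selection drives the selected allele upward", {
  panel <- generate_panel(2, 5e4, snp_density = 0.004, seed = 9)
  site <- 10L   # one founder carries ALT -> initial AF ~0.5
  regime <- selection_regime(site, s = 0.1)
  set.seed(10)
  finals <- replicate(50, {
    pop <- forward_simulate(panel, G = 25, R = 1e-8, N = 100,
                            regime = regime, track_af = TRUE)
    c(pop$af_trajectory[1, 1], pop$af_trajectory[26, 1])
  })
  delta <- finals[2, ] - finals[1, ]
  tt <- t.test(delta, alternative = "greater")
  expect_lt(tt$p.value, 0.01)
})

test_that("pool sampling gives exact fractional truth", {
  panel <- generate_panel(6, 1e5, snp_density = 0.002, seed = 11)
  pop <- forward_simulate(panel, G = 5, R = 1e-7, N = 30, seed = 12)
  pool <- sample_pool(pop, panel$table, n_individuals = 10, seed = 13)
  expect_equal(length(pool$chroms), 20L)
  expect_true(all(abs(pool$true_af * 20 - round(pool$true_af * 20)) < 1e-9))
  # sampling the whole population reproduces the population frequency
  all_pool <- sample_pool(pop, panel$table, n_individuals = 30)
  manual <- rowMeans(vapply(pop$chroms, function(ch) {
    fid <- hafkit:::founder_at(ch, panel$table$pos)
    panel$table$geno[cbind(fid, seq_along(panel$table$pos))]
  }, numeric(length(panel$table$pos))))
  expect_equal(all_pool$true_af, manual)
  # unrecombined equal founder pool: truth = founder alt fraction
  fp <- founder_pool(panel)
  expect_equal(fp$true_af, unname(alt_fraction(panel$table)))
})

test_that("error-free reads copy their source haplotype exactly", {
  panel <- generate_panel(5, 1e5, snp_density = 0.003, seed = 14)
  tab <- panel$table
  # single-founder pool makes every read's source haplotype known
  pool <- structure(list(chroms = list(list(bp = 1e5, fid = 2L)),
                         true_af = as.numeric(tab$geno[2, ]),
                         generation = 0L, chrom = tab$chrom),
                    class = "pool_sample")
  sam <- tempfile(fileext = ".sam")
  simulate_reads(pool, panel, tab, coverage = 2, file = sam,
                 error_rate = 0, seed = 15)
  obs <- extract_observations(sam, tab)
  expect_true(all(obs$allele == tab$geno[2, obs$site]))
  expect_true(all(obs$eps == 1e-3))
})

test_that("sequencing errors appear at the configured rate and quality", {
  panel <- generate_panel(5, 2e5, snp_density = 0.002, seed = 16)
  tab <- panel$table
  pool <- structure(list(chroms = list(list(bp = 2e5, fid = 1L)),
                         true_af = as.numeric(tab$geno[1, ]),
                         generation = 0L, chrom = tab$chrom),
                    class = "pool_sample")
  sam <- tempfile(fileext = ".sam")
  simulate_reads(pool, panel, tab, coverage = 8, file = sam,
                 error_rate = 0.002, seed = 17)
  lines <- readLines(sam)
  recs <- lines[!startsWith(lines, "@")]
  f <- do.call(rbind, strsplit(recs, "\t", fixed = TRUE))
  pos <- as.integer(f[, 4])
  hap <- vapply(seq_along(pos), function(i)
    hap_seq(strsplit(panel$ref, "")[[1]], tab, 1L, pos[i], pos[i] + 149L),
    character(1))
  nbases <- 150 * length(pos)
  mism <- sum(vapply(seq_along(pos), function(i) {
    sum(strsplit(f[i, 10], "")[[1]] != strsplit(hap[i], "")[[1]])
  }, numeric(1)))
  rate <- mism / nbases
  sd3 <- 3 * sqrt(0.002 * 0.998 / nbases)
  expect_lt(abs(rate - 0.002), sd3 + 1e-4)
  # error bases carry the lower quality score
  q10 <- rawToChar(as.raw(10 + 33))
  has_err <- grepl(q10, f[, 11], fixed = TRUE)
  expect_gt(sum(has_err), 0)
  # mean depth near the target
  expect_equal(nbases / 2e5, 8, tolerance = 0.05)
})

test_that("fragment lengths match the exponential window-sizing model", {
  # many founders and a large population keep crossovers between locally
  # identical haplotypes (which leave no visible breakpoint) rare, so the
  # observed founder-segment lengths can be compared to the model
  panel <- generate_panel(99, 2e7, snp_density = 2e-5, seed = 18)
  L <- 2e7; R <- 6e-8
  # the model's rate is calibrated to the mean: 1/lambda = L/(LRG+1);
  # founders start homozygous so first-meiosis crossovers switch between
  # identical homologs and leave no visible breakpoint -- fragments run
  # longer than the model early on (roughly G-1 effective generations) and
  # converge to it as G grows
  pop4 <- forward_simulate(panel, G = 4, R = R, N = 1000, seed = 19)
  lam4 <- fragment_rate(window_params(L, R, 4))
  fl4 <- fragment_lengths(pop4)
  expect_gt(mean(fl4), 1 / lam4)           # hidden early crossovers
  expect_lt(mean(fl4), 1.5 / lam4)         # but of the right magnitude
  pop12 <- forward_simulate(panel, G = 12, R = R, N = 1000, seed = 21)
  lam12 <- fragment_rate(window_params(L, R, 12))
  fl12 <- fragment_lengths(pop12)
  expect_lt(abs(mean(fl12) - 1 / lam12) / (1 / lam12), 0.10)
  # shape: an exponential fit is not rejected on a modest subsample
  set.seed(20)
  ks <- suppressWarnings(ks.test(sample(fl12, 150), "pexp", lam12))
  expect_gt(ks$p.value, 0.001)
  # more generations -> shorter fragments
  expect_lt(mean(fl12), mean(fl4))
})
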