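# table with 2 SNPs 40 bp apart for decoding tests
obs_table <- function() {
  snp_table("chrT", c(120L, 160L), c("A", "C"), c("G", "T"),
            rbind(c(0L, 0L), c(1L, 1L), c(1L, 0L)))
}

test_that("SAM decoding reports covered SNPs with base-quality errors", {
  tab <- obs_table()
  seq1 <- strrep("A", 150)
  substr(seq1, 20, 20) <- "G"   # ALT at site 120 (read pos 101..?)
  # read at pos 101 covers 101..250: site 120 at offset 20, site 160 at 60
  substr(seq1, 60, 60) <- "C"   # REF at site 160
  sam <- write_toy_sam(list(
    list(qname = "r1", flag = 0L, pos = 101L, cigar = "150M",
         seq = seq1, qual = qstr(30, 150)),
    # overlaps no SNP -> omitted
    list(qname = "r2", flag = 0L, pos = 5000L, cigar = "150M",
         seq = strrep("A", 150), qual = qstr(30, 150)),
    # secondary alignment -> skipped
    list(qname = "r3", flag = 256L, pos = 101L, cigar = "150M",
         seq = seq1, qual = qstr(30, 150))))
  obs <- extract_observations(sam, tab)
  expect_equal(attr(obs, "n_reads"), 1L)
  expect_equal(nrow(obs), 2L)
  expect_equal(obs$site, c(1L, 2L))
  expect_equal(obs$allele, c(1L, 0L))
  expect_equal(obs$eps, rep(1e-3, 2), tolerance = 1e-12)
})

test_that("deletions spanning a SNP leave the site unobserved", {
  tab <- obs_table()
  # 50M at 101..150, 20bp deletion over 151..170 (covers site 160), 100M after
  sam <- write_toy_sam(list(
    list(qname = "d1", flag = 0L, pos = 101L, cigar = "50M20D100M",
         seq = strrep("A", 150), qual = qstr(30, 150))))
  obs <- extract_observations(sam, tab)
  expect_equal(obs$site, 1L)   # site 120 observed, site 160 deleted
  # the base at site 120 is offset 20 of the query
  expect_equal(obs$allele, 0L) # 'A' = REF
})

test_that("mates merge into one observation, higher quality wins", {
  tab <- obs_table()
  s_ref <- strrep("A", 150)
  s_alt <- s_ref
  substr(s_alt, 20, 20) <- "G"
  sam <- write_toy_sam(list(
    list(qname = "p1", flag = 99L, pos = 101L, cigar = "150M",
         seq = s_alt, qual = qstr(20, 150)),
    list(qname = "p1", flag = 147L, pos = 101L, cigar = "150M",
         seq = s_ref, qual = qstr(35, 150))))
  obs <- extract_observations(sam, tab)
  expect_equal(attr(obs, "n_reads"), 1L)
  # site 1 observed twice; Q35 (REF) beats Q20 (ALT)
  site1 <- obs[obs$site == 1L, ]
  expect_equal(nrow(site1), 1L)
  expect_equal(site1$allele, 0L)
  expect_equal(site1$eps, 10^(-3.5), tolerance = 1e-12)
})

test_that("read log-likelihood uses match/mismatch error terms", {
  hap <- c(1L, 0L, 1L)
  expect_equal(read_loglik(1:3, c(1L, 0L, 1L), rep(1e-3, 3), hap),
               3 * log(0.999))
  expect_equal(read_loglik(1L, 1L, 0.01, c(0L)), log(0.01 / 3))
  # OTHER counts as mismatch against both carriers
  expect_equal(read_loglik(1L, 2L, 0.01, c(0L)),
               read_loglik(1L, 2L, 0.01, c(1L)))
  # indistinguishable haplotypes within the covered span
  h1 <- c(0L, 1L, 0L); h2 <- c(0L, 1L, 1L)
  expect_equal(read_loglik(1:2, c(0L, 1L), c(1e-2, 1e-3), h1),
               read_loglik(1:2, c(0L, 1L), c(1e-2, 1e-3), h2))
})

# build a loglik matrix directly from synthetic observations
toy_loglik <- function(geno, sites, alleles, eps) {
  t(vapply(seq_len(nrow(geno)), function(h)
    vapply(seq_along(sites), function(r)
      read_loglik(sites[[r]], alleles[[r]], eps[[r]], geno[h, ]),
      numeric(1)),
    numeric(length(sites))))
}

test_that("EM recovers a point-mass pool and the two-haplotype closed form", {
  geno <- rbind(c(0L, 0L, 0L), c(1L, 0L, 1L), c(0L, 1L, 1L))
  # 30 noise-free reads from founder 2 covering all three sites
  L <- do.call(rbind, replicate(30, {
    vapply(1:3, function(h)
      read_loglik(1:3, geno[2, ], rep(1e-9, 3), geno[h, ]), numeric(1))
  }, simplify = FALSE))
  fit <- em_frequencies(L)
  expect_true(fit$converged)
  expect_equal(fit$freqs, c(0, 1, 0), tolerance = 1e-6)

  # 2 founders differing at one site; 70 ALT and 30 REF reads
  g2 <- rbind(1L, 0L)
  L2 <- rbind(
    matrix(rep(vapply(1:2, function(h)
      read_loglik(1L, 1L, 1e-9, g2[h, , drop = TRUE]), numeric(1)), 70),
      70, 2, byrow = TRUE),
    matrix(rep(vapply(1:2, function(h)
      read_loglik(1L, 0L, 1e-9, g2[h, , drop = TRUE]), numeric(1)), 30),
      30, 2, byrow = TRUE))
  fit2 <- em_frequencies(L2)
  expect_equal(fit2$freqs, c(0.7, 0.3), tolerance = 1e-6)
})

test_that("EM log-likelihood is monotone and matches a simplex grid search", {
  set.seed(5)
  for (rep in 1:5) {
    H <- sample(2:3, 1)
    geno <- matrix(sample(0:1, H * 6, replace = TRUE), H, 6)
    truth <- as.vector(stats::rmultinom(1, 50, rep(1, H))) / 50
    n_reads <- 20
    sites <- replicate(n_reads, sort(sample(1:6, 3)), simplify = FALSE)
    src <- sample(H, n_reads, replace = TRUE, prob = truth + 0.01)
    alleles <- lapply(seq_len(n_reads), function(r) {
      a <- geno[src[r], sites[[r]]]
      flip <- runif(3) < 0.05
      ifelse(flip, 1L - a, a)
    })
    eps <- replicate(n_reads, rep(0.05, 3), simplify = FALSE)
    L <- t(toy_loglik(geno, sites, alleles, eps))
    fit <- em_frequencies(L, tol = 1e-10, max_iter = 5000)
    expect_true(all(diff(fit$loglik_trace) >= -1e-9))
    expect_equal(sum(fit$freqs), 1, tolerance = 1e-9)
    expect_true(all(fit$freqs >= 0))
    grid_best <- grid_mle_loglik(L, res = 1e-3)
    em_ll <- fit$loglik_trace[length(fit$loglik_trace)]
    # the EM optimum must match the dense grid optimum (grid can only be
    # epsilon better than the continuous maximiser)
    expect_true(em_ll >= grid_best - 1e-6)
    expect_equal(em_ll, grid_best, tolerance = 1e-4)
  }
})

test_that("identical founders split frequency symmetrically", {
  # founders: A, A, B; pool of reads from A and B
  geno <- rbind(c(0L, 1L, 0L), c(0L, 1L, 0L), c(1L, 0L, 1L))
  set.seed(8)
  src <- sample(c(1L, 3L), 60, replace = TRUE, prob = c(0.6, 0.4))
  sites <- replicate(60, 1:3, simplify = FALSE)
  alleles <- lapply(src, function(s) geno[s, ])
  eps <- replicate(60, rep(1e-4, 3), simplify = FALSE)
  L3 <- t(toy_loglik(geno, sites, alleles, eps))
  fit3 <- em_frequencies(L3)
  # merged run with one copy of A
  L2 <- L3[, c(1, 3)]
  fit2 <- em_frequencies(L2)
  expect_equal(fit3$freqs[1] + fit3$freqs[2], fit2$freqs[1], tolerance = 1e-5)
  expect_equal(fit3$freqs[1], fit3$freqs[2], tolerance = 1e-6)
})

test_that("chromosome inference is consistent and label-equivariant", {
  set.seed(21)
  panel <- generate_panel(6, 2e5, snp_density = 0.002)
  tab <- panel$table
  pool <- founder_pool(panel)
  sam <- tempfile(fileext = ".sam")
  simulate_reads(pool, panel, tab, coverage = 4, file = sam, seed = 22)
  obs <- extract_observations(sam, tab)
  # single whole-chromosome window reproduces em_frequencies on all reads
  plan1 <- build_plan(window_params(2e5, 0, 0), override_size = 2e5)
  hf1 <- infer_chromosome(obs, tab, plan1)
  L <- hafkit:::window_loglik(obs, tab$geno, seq_along(tab$pos))
  direct <- em_frequencies(L)
  expect_equal(unname(hf1$freqs[1, ]), direct$freqs, tolerance = 1e-12)
  # permuting founder order permutes the estimates identically
  perm <- c(3, 1, 6, 2, 5, 4)
  tabp <- tab
  tabp$geno <- tab$geno[perm, ]
  tabp$founder_ids <- rownames(tabp$geno)
  obs_p <- extract_observations(sam, tabp)
  hfp <- infer_chromosome(obs_p, tabp, plan1)
  expect_equal(unname(hfp$freqs[1, ]), unname(hf1$freqs[1, perm]),
               tolerance = 1e-9)
  # equal-mix pool at decent coverage: frequencies near uniform
  expect_lt(max(abs(hf1$freqs[1, ] - 1 / 6)), 0.1)
})

test_that("windows without reads fall back to uniform with a warning", {
  tab <- obs_table()
  sam <- write_toy_sam(list(
    list(qname = "r1", flag = 0L, pos = 101L, cigar = "150M",
         seq = strrep("A", 150), qual = qstr(30, 150))))
  obs <- extract_observations(sam, tab)
  plan <- build_plan(window_params(10000, 0, 0), override_size = 1000)
  # many windows are empty here; capture the whole batch of warnings
  w <- capture_warnings(hf <- infer_chromosome(obs, tab, plan))
  expect_true(any(grepl("no informative", w)))
  empty <- which(hf$n_reads == 0)
  expect_true(length(empty) > 0)
  expect_true(all(abs(hf$freqs[empty, ] - 1 / 3) < 1e-12))
})
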