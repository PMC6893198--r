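#' Run the full HAF pipeline on simulated data
#'
#' End-to-end wrapper: generate (or take) a founder panel, simulate a
#' pooled sample (optionally after forward simulation with recombination
#' and selection), simulate reads at a target coverage, infer window
#' haplotype frequencies, compute the HAF track and score it against the
#' exact pool truth. Deterministic given `seed`. When `out_dir` is given,
#' all artifacts (SNP table, SAM, frequency and HAF tracks, truth,
#' accuracy JSON) are written there along with a manifest of md5 checksums.
#'
#' @param panel a `founder_panel` from [generate_panel()], or `NULL` to
#'   generate one from `n_founders`, `L`, `snp_density`.
#' @param coverage target empirical coverage for read simulation.
#' @param G generations of recombination (0 = unrecombined founder pool).
#' @param R recombination rate per bp per gamete (required when `G > 0`).
#' @param regime optional [selection_regime()] for the forward simulation.
#' @param window_size fixed inference window size in bp, or `NULL` to use
#'   the adaptive exponential-quantile sizing at quantile `q`.
#' @param q fragment-length quantile for adaptive sizing.
#' @param n_individuals diploids sampled into the pool when `G > 0`.
#' @param N population size of the forward simulation.
#' @param n_founders,L,snp_density,missing_rate panel parameters when
#'   `panel` is `NULL`; `missing_rate` is the fraction of founder genotype
#'   calls masked as missing (the M covariate of the accuracy model).
#' @param error_rate,impute_method passed through to the respective stages.
#' @param seed RNG seed; every stage's randomness derives from it.
#' @param out_dir optional output directory.
#' @return list with `haf` (the HAF `af_track`), `truth`, `report` (an
#'   `accuracy_report`), `hap_freqs`, `plan`, `rwin` and `paths` (when
#'   written).
#' @export
run_end_to_end <- function(panel = NULL, coverage = 5, G = 0, R = 0,
                           regime = NULL, window_size = NULL, q = 0.18,
                           n_individuals = 100L, N = 1000L,
                           n_founders = 99L, L = 5e6,
                           snp_density = 283437 / 23e6, missing_rate = 0,
                           error_rate = 0.002,
                           impute_method = "nearest_neighbor",
                           seed = 1L, out_dir = NULL) {
  set.seed(seed)
  if (is.null(panel))
    panel <- generate_panel(n_founders, L, snp_density = snp_density,
                            missing_rate = missing_rate)
  table <- panel$table
  imp <- if (anyNA(table$geno)) impute(table, method = impute_method)
         else table
  # truth side: the complete genotypes generate reads and define the pool
  # truth; the inference side only ever sees the (masked, then imputed) table
  truth_tab <- if (!is.null(panel$truth_table)) panel$truth_table else imp
  if (G > 0) {
    pop <- forward_simulate(truth_tab, G = G, R = R, N = N, regime = regime)
    pool <- sample_pool(pop, truth_tab, n_individuals = n_individuals)
  } else {
    pool <- founder_pool(truth_tab, L = panel$L)
  }
  sam <- tempfile(fileext = ".sam")
  simulate_reads(pool, panel, truth_tab, coverage = coverage, file = sam,
                 error_rate = error_rate)
  params <- window_params(panel$L, R, G, q = q)
  plan <- build_plan(params, override_size = window_size,
                     snp_pos = table$pos)
  obs <- extract_observations(sam, imp)
  hf <- infer_chromosome(obs, imp, plan)
  haf <- haf_chromosome(hf, table)
  truth <- truth_track(pool, truth_tab)
  report <- accuracy_report(haf, truth)
  rwin <- compute_rwin(obs, imp, plan)
  out <- list(haf = haf, truth = truth, report = report, hap_freqs = hf,
              plan = plan, rwin = rwin, seed = seed)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- c(
      snp_table = write_snptable(table, file.path(out_dir, "founders.snp")),
      sam = {
        file.copy(sam, file.path(out_dir, "pool.sam"), overwrite = TRUE)
        file.path(out_dir, "pool.sam")
      },
      freqs = write_hap_freqs(hf, file.path(out_dir, "freqs.tsv")),
      haf = write_af_track(haf, file.path(out_dir, "haf.tsv")),
      truth = {
        data.table::fwrite(truth, file.path(out_dir, "truth.tsv"), sep = "\t")
        file.path(out_dir, "truth.tsv")
      },
      report = {
        jsonlite::write_json(
          list(n_sites = report$n_sites, rmse = report$rmse_estimated,
               effective_coverage = report$effective_coverage,
               rwin = rwin, seed = seed),
          file.path(out_dir, "accuracy.json"), auto_unbox = TRUE, digits = NA)
        file.path(out_dir, "accuracy.json")
      })
    manifest <- data.frame(file = basename(paths),
                           md5 = unname(tools::md5sum(paths)))
    utils::write.table(manifest, file.path(out_dir, "manifest.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    out$paths <- paths
  }
  unlink(sam)
  out
}
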