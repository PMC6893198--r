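#' Root-mean-square error of frequency estimates
#'
#' \eqn{RMSE = \sqrt{\sum_i (p_{est,i} - p_{true,i})^2 / n}} over matched
#' sites.
#'
#' @param est,truth numeric vectors of estimated and true frequencies at
#'   the same sites, or two `af_track`/truth data.frames with `pos` and a
#'   frequency column (`est_freq` / `true_af`), matched on position.
#' @return the RMSE.
#' @export
af_rmse <- function(est, truth) {
  m <- match_tracks(est, truth)
  sqrt(mean((m$est - m$truth)^2))
}

#' Effective coverage of a set of frequency estimates
#'
#' The binomial-sampling read depth whose expected error equals the
#' observed error:
#' \deqn{C_{eff} = \frac{\sum_i p_{true,i}(1-p_{true,i})}
#'                      {\sum_i (p_{est,i} - p_{true,i})^2}.}
#' Because expected and observed error are taken over the same set of true
#' frequencies, the ratio does not depend on the underlying
#' allele-frequency spectrum. Fixed sites (`p_true` 0 or 1) contribute
#' nothing to the numerator but keep their estimation error in the
#' denominator; set `drop_fixed = TRUE` to exclude them entirely.
#'
#' @inheritParams af_rmse
#' @param drop_fixed exclude sites with `p_true` of exactly 0 or 1.
#' @return effective coverage (reads); `Inf` with a warning when the
#'   estimates are exact.
#' @export
effective_coverage <- function(est, truth, drop_fixed = FALSE) {
  m <- match_tracks(est, truth)
  if (drop_fixed) {
    keep <- m$truth > 0 & m$truth < 1
    m$est <- m$est[keep]; m$truth <- m$truth[keep]
  }
  num <- sum(m$truth * (1 - m$truth))
  if (num == 0) stop("all true frequencies are fixed; effective coverage undefined")
  den <- sum((m$est - m$truth)^2)
  if (den == 0) {
    warning("zero squared error; effective coverage is infinite")
    return(Inf)
  }
  num / den
}

#' Accuracy report for an estimated track
#'
#' Bundles RMSE, the truth-variance sum and effective coverage for a pair
#' of matched tracks. Sites present in only one track are excluded
#' pairwise and counted.
#'
#' @inheritParams effective_coverage
#' @return an `accuracy_report` list: `n_sites`, `n_excluded`,
#'   `rmse_estimated`, `sum_ptrue_var`, `effective_coverage`.
#' @export
accuracy_report <- function(est, truth, drop_fixed = FALSE) {
  m <- match_tracks(est, truth)
  if (drop_fixed) {
    keep <- m$truth > 0 & m$truth < 1
    m <- list(est = m$est[keep], truth = m$truth[keep],
              n_excluded = m$n_excluded + sum(!keep))
  }
  structure(list(
    n_sites = length(m$est),
    n_excluded = m$n_excluded,
    rmse_estimated = sqrt(mean((m$est - m$truth)^2)),
    sum_ptrue_var = sum(m$truth * (1 - m$truth)),
    effective_coverage = effective_coverage(m$est, m$truth)),
    class = "accuracy_report")
}

#' @export
print.accuracy_report <- function(x, ...) {
  cat(sprintf(
    "accuracy_report: %d sites (%d excluded)\n  RMSE %.5f | effective coverage %.1fx\n",
    x$n_sites, x$n_excluded, x$rmse_estimated, x$effective_coverage))
  invisible(x)
}

# pairwise matching of estimate and truth; accepts bare vectors or
# data.frames carrying pos + est_freq / true_af columns
match_tracks <- function(est, truth) {
  if (is.numeric(est) && is.numeric(truth)) {
    if (length(est) != length(truth))
      stop("estimate and truth vectors differ in length")
    return(list(est = est, truth = truth, n_excluded = 0L))
  }
  e <- as.data.frame(est)
  t_ <- as.data.frame(truth)
  ecol <- intersect(c("est_freq", "freq", "true_af"), names(e))[1L]
  tcol <- intersect(c("true_af", "est_freq", "freq"), names(t_))[1L]
  if (is.na(ecol) || is.na(tcol) || !"pos" %in% names(e) || !"pos" %in% names(t_))
    stop("tracks need 'pos' and a frequency column")
  common <- intersect(e$pos, t_$pos)
  if (!length(common)) stop("tracks share no sites")
  list(est = e[[ecol]][match(common, e$pos)],
       truth = t_[[tcol]][match(common, t_$pos)],
       n_excluded = (nrow(e) - length(common)) + (nrow(t_) - length(common)))
}
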