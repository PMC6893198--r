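#' Mean informative reads per inference window (Rwin)
#'
#' The average, over a plan's frequency windows, of the number of reads
#' (paired mates merged) overlapping at least one SNP site inside the
#' window. Rwin summarises the information available for haplotype
#' inference per window and is the primary driver of HAF accuracy.
#'
#' @param reads SAM/BAM path or a `read_obs` from [extract_observations()].
#' @param table a [snp_table].
#' @param plan a `window_plan`.
#' @return mean informative reads per frequency window.
#' @export
compute_rwin <- function(reads, table, plan) {
  w <- plan$freq_windows
  if (!nrow(w)) stop("empty window plan")
  obs <- if (inherits(reads, "read_obs")) reads
         else extract_observations(reads, table)
  pos <- table$pos
  counts <- vapply(seq_len(nrow(w)), function(i) {
    j1 <- findInterval(w[i, "start"], pos) + 1L
    j2 <- findInterval(w[i, "end"], pos)
    if (j1 > j2) return(0L)
    rows <- findInterval(c(j1 - 1L, j2), obs$site)
    if (rows[2L] <= rows[1L]) return(0L)
    length(unique(obs$read[(rows[1L] + 1L):rows[2L]]))
  }, integer(1L))
  mean(counts)
}

#' Fit the log-linear effective-coverage model
#'
#' Fits `log10(EC) = a log10(Rwin) + b log10(1 + M) + c` by ordinary least
#' squares (the model is linear in its coefficients). `M` is the percent
#' (0-100 scale) of founder genotype calls missing — the `1 + M` transform
#' is scale-sensitive, so percent units matter.
#'
#' @param obs data.frame with columns `Rwin` (> 0), `M` (percent, >= 0) and
#'   `EC` (> 0); at least 3 rows, with at least 2 distinct `Rwin` and 2
#'   distinct `M` values.
#' @return an `ec_model` with coefficients `a`, `b`, `c`, `r_squared` (on
#'   the log10(EC) scale) and `n`.
#' @export
ec_fit <- function(obs) {
  obs <- as.data.frame(obs)
  stopifnot(all(c("Rwin", "M", "EC") %in% names(obs)))
  if (nrow(obs) < 3L) stop("need at least 3 observations")
  if (any(obs$Rwin <= 0) || any(obs$EC <= 0) || any(obs$M < 0))
    stop("Rwin and EC must be positive, M non-negative")
  x1 <- log10(obs$Rwin)
  x2 <- log10(1 + obs$M)
  if (length(unique(x1)) < 2L)
    stop("rank-deficient design: Rwin takes a single value")
  if (length(unique(x2)) < 2L)
    stop("rank-deficient design: M takes a single value")
  y <- log10(obs$EC)
  fit <- stats::lm(y ~ x1 + x2)
  cf <- stats::coef(fit)
  structure(list(a = unname(cf["x1"]), b = unname(cf["x2"]),
                 c = unname(cf["(Intercept)"]),
                 r_squared = summary(fit)$r.squared, n = nrow(obs),
                 lm = fit),
            class = "ec_model")
}

#' @export
print.ec_model <- function(x, ...) {
  cat(sprintf(
    "ec_model: log10(EC) = %.4f log10(Rwin) + %.4f log10(1+M) + %.4f  (R^2 = %.3f, n = %d)\n",
    x$a, x$b, x$c, x$r_squared, x$n))
  invisible(x)
}

#' @export
coef.ec_model <- function(object, ...) {
  c(a = object$a, b = object$b, c = object$c)
}

#' Predict effective coverage
#'
#' @param object an `ec_model`.
#' @param Rwin mean informative reads per window (> 0).
#' @param M percent of founder genotype calls missing (0-100 scale).
#' @param ... unused.
#' @return predicted effective coverage,
#'   `10^(a log10(Rwin) + b log10(1+M) + c)`.
#' @export
predict.ec_model <- function(object, Rwin, M = 0, ...) {
  stopifnot(all(Rwin > 0), all(M >= 0))
  10^(object$a * log10(Rwin) + object$b * log10(1 + M) + object$c)
}

#' Serialize / load an effective-coverage model
#'
#' Coefficients and fit diagnostics are written as JSON, optionally with a
#' free-form provenance note (simulation grid description, seeds).
#'
#' @param model an `ec_model`.
#' @param file path.
#' @param provenance optional list stored alongside the coefficients.
#' @export
write_ec_model <- function(model, file, provenance = NULL) {
  jsonlite::write_json(
    list(a = model$a, b = model$b, c = model$c,
         r_squared = model$r_squared, n = model$n,
         provenance = provenance),
    file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' @rdname write_ec_model
#' @export
read_ec_model <- function(file) {
  j <- jsonlite::read_json(file, simplifyVector = TRUE)
  structure(list(a = j$a, b = j$b, c = j$c, r_squared = j$r_squared,
                 n = j$n, provenance = j$provenance),
            class = "ec_model")
}
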