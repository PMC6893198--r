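#' Recombination-scaled window parameters
#'
#' Window-based haplotype inference assumes no recombination breakpoint
#' falls inside an inference window. Unrecombined fragment lengths after
#' `G` generations of recombination at rate `R` on a chromosome of length
#' `L` are modelled as exponential with rate
#' \deqn{\lambda = (L R G + 1) / L,}
#' the `+1` accounting for the chromosome ends. Window sizes are set to the
#' `q`-th quantile of this distribution so that only a fraction `q` of
#' fragments are expected to be shorter than a window.
#'
#' @param L chromosome length in bp.
#' @param R mean recombination rate (crossovers per bp per generation).
#' @param G generations of recombination since population founding.
#' @param q fragment-length quantile used for window sizing, default 0.18.
#' @return a `window_params` list.
#' @export
window_params <- function(L, R, G, q = 0.18) {
  stopifnot(L > 0, R >= 0, G >= 0, q > 0, q < 1)
  structure(list(L = as.numeric(L), R = as.numeric(R),
                 G = as.numeric(G), q = q),
            class = "window_params")
}

#' Exponential rate of unrecombined fragment lengths
#'
#' @param p a [window_params].
#' @return \eqn{\lambda = (L R G + 1)/L} in 1/bp.
#' @export
fragment_rate <- function(p) {
  (p$L * p$R * p$G + 1) / p$L
}

#' Adaptive inference window size
#'
#' The `q`-th quantile of the exponential fragment-length model,
#' `qexp(q, fragment_rate(p))`, rounded to the nearest kb for
#' reportability, floor-clamped at `min_size` and capped at the chromosome
#' length. Window sizes therefore shrink as recombination proceeds.
#'
#' @param p a [window_params].
#' @param min_size minimum window size in bp (default 1 kb), guarding
#'   against windows with too few SNPs.
#' @return window size in bp.
#' @export
window_size_at_generation <- function(p, min_size = 1000) {
  w <- stats::qexp(p$q, rate = fragment_rate(p))
  w <- round(w / 1000) * 1000
  min(max(w, min_size), p$L)
}

#' Build the sliding-window plan
#'
#' Generates the overlapping frequency-estimation windows (step = 10% of
#' the window size, so interior sites fall in exactly 10 windows) and the
#' enclosing likelihood windows (10x the frequency window size, step = half
#' their size) used to chunk read-likelihood computation. Intervals are
#' 0-based half-open; terminal windows are clipped at `L` rather than
#' dropped so chromosome ends stay covered.
#'
#' @param p a [window_params].
#' @param override_size fixed window size in bp, bypassing the adaptive
#'   quantile sizing (e.g. 1000 kb / 100 kb / 10 kb fixed-window analyses).
#' @param snp_pos optional SNP positions; a warning is issued when the
#'   window size is under 10x the mean inter-SNP distance.
#' @return a `window_plan` with `freq_windows` and `lik_windows` (two-column
#'   matrices of 0-based half-open start/end), `window_size`, `freq_step`,
#'   `lik_step`, and `L`.
#' @export
build_plan <- function(p, override_size = NULL, snp_pos = NULL) {
  size <- if (is.null(override_size)) window_size_at_generation(p)
          else min(as.numeric(override_size), p$L)
  step <- round(0.10 * size)
  if (!is.null(snp_pos) && length(snp_pos) > 1) {
    spacing <- (max(snp_pos) - min(snp_pos)) / (length(snp_pos) - 1)
    if (size < 10 * spacing)
      warning(sprintf(
        "window size %g bp is < 10x mean inter-SNP distance (%.0f bp)",
        size, spacing))
  }
  lik_size <- 10 * size
  lik_step <- lik_size / 2
  structure(list(
    freq_windows = tile_windows(p$L, size, step),
    lik_windows  = tile_windows(p$L, lik_size, lik_step),
    window_size = size, freq_step = step, lik_step = lik_step, L = p$L),
    class = "window_plan")
}

# starts every `step` bp while < L; ends clipped at L; a window spanning
# the whole chromosome degenerates to a single interval
tile_windows <- function(L, size, step) {
  if (size >= L) return(cbind(start = 0, end = L))
  starts <- seq(0, L - 1, by = step)
  ends <- pmin(starts + size, L)
  cbind(start = starts, end = ends)
}

#' @export
print.window_plan <- function(x, ...) {
  cat(sprintf(
    "window_plan: %d frequency windows of %g bp (step %g bp), %d likelihood windows of %g bp on [0, %g)\n",
    nrow(x$freq_windows), x$window_size, x$freq_step,
    nrow(x$lik_windows), 10 * x$window_size, x$L))
  invisible(x)
}

#' Windows overlapping a position
#'
#' @param plan a `window_plan`.
#' @param pos 1-based positions (SNP convention).
#' @return integer list, one element per position, of frequency-window row
#'   indices whose 0-based half-open interval contains the position.
#' @export
windows_overlapping <- function(plan, pos) {
  w <- plan$freq_windows
  p0 <- as.numeric(pos) - 1          # to 0-based
  q <- IRanges::IRanges(start = w[, "start"] + 1L, end = w[, "end"])
  s <- IRanges::IRanges(start = as.integer(p0 + 1L), width = 1L)
  hits <- IRanges::findOverlaps(s, q)
  split(S4Vectors::subjectHits(hits),
        factor(S4Vectors::queryHits(hits), levels = seq_along(pos)))
}

#' Write a window plan as BED
#'
#' @param plan a `window_plan`.
#' @param file output path.
#' @param chrom chromosome name for the BED records.
#' @param which `"freq"` or `"lik"` windows.
#' @export
write_plan_bed <- function(plan, file, chrom = "chr", which = c("freq", "lik")) {
  which <- match.arg(which)
  w <- if (which == "freq") plan$freq_windows else plan$lik_windows
  utils::write.table(
    data.frame(chrom = chrom, start = format(w[, "start"], scientific = FALSE, trim = TRUE),
               end = format(w[, "end"], scientific = FALSE, trim = TRUE)),
    file, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(file)
}
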