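#' Per-site founder weights from overlapping windows
#'
#' The founder weight vector at a site is the unweighted arithmetic mean of
#' the estimated haplotype-frequency vectors of all frequency windows
#' overlapping the site (under the default plan, interior sites are covered
#' by exactly 10 windows).
#'
#' @param hf a `hap_freqs` object from [infer_chromosome()].
#' @param pos 1-based site positions.
#' @return a list with `weights` (sites x founders matrix; rows sum to 1)
#'   and `n_windows` (windows overlapping each site; 0 rows are `NA` and
#'   flagged with a warning).
#' @export
site_haplotype_weights <- function(hf, pos) {
  ov <- windows_overlapping(hf$plan, pos)
  H <- ncol(hf$freqs)
  w <- matrix(NA_real_, length(pos), H,
              dimnames = list(NULL, colnames(hf$freqs)))
  nwin <- lengths(ov)
  # group sites by identical window sets (runs along the chromosome)
  key <- vapply(ov, paste, character(1L), collapse = ",")
  for (rows in split(seq_along(key), key)) {
    idx <- ov[[rows[1L]]]
    if (!length(idx)) next
    w[rows, ] <- matrix(colMeans(hf$freqs[idx, , drop = FALSE]),
                        length(rows), H, byrow = TRUE)
  }
  if (any(nwin == 0L))
    warning(sprintf("%d site(s) covered by no window; skipped",
                    sum(nwin == 0L)))
  list(weights = w, n_windows = nwin)
}

#' Haplotype-derived allele frequency at sites
#'
#' HAF at a site is the weighted sum of founder alleles,
#' \eqn{\sum_h w_h a_h}, with \eqn{a_h = 1} for founders carrying the
#' alternate allele, 0 for reference carriers, and — for founders whose
#' genotype is missing — a fractional count equal to the proportion of
#' genotyped founders carrying the alternate allele. Fractional counts are
#' taken from the original, unimputed table even though frequency inference
#' ran on the imputed one.
#'
#' @param weights sites x founders weight matrix (rows on the simplex).
#' @param table the original (possibly missing-containing) [snp_table].
#' @param sites SNP column indices matching the rows of `weights`.
#' @return numeric vector of HAFs in `[0, 1]`.
#' @export
haf_site <- function(weights, table, sites) {
  a <- table$geno[, sites, drop = FALSE]       # founders x sites
  if (anyNA(a)) {
    frac <- alt_fraction(table, sites)
    na_idx <- which(is.na(a), arr.ind = TRUE)
    a[na_idx] <- frac[na_idx[, 2L]]
  }
  storage.mode(a) <- "double"
  rowSums(weights * t(a))
}

#' HAF track along a chromosome
#'
#' Applies [site_haplotype_weights()] and [haf_site()] over the table's
#' sites, producing an allele-frequency track.
#'
#' @param hf a `hap_freqs` object.
#' @param table the original [snp_table] (used for fractional counts at
#'   missing founder genotypes).
#' @param sites optional SNP column indices to restrict to.
#' @param complete_only if `TRUE`, keep only sites genotyped in every
#'   founder (accuracy assessments often restrict to fully-genotyped
#'   sites).
#' @return an `af_track`: data.frame with `chrom`, `pos`, `ref`, `alt`,
#'   `est_freq`, `support` (overlapping-window count), and attribute
#'   `method = "HAF"`. Sites covered by no window are dropped.
#' @export
haf_chromosome <- function(hf, table, sites = NULL, complete_only = FALSE) {
  if (is.null(sites)) sites <- seq_along(table$pos)
  if (complete_only) {
    full <- colSums(is.na(table$geno[, sites, drop = FALSE])) == 0L
    sites <- sites[full]
  }
  sw <- site_haplotype_weights(hf, table$pos[sites])
  keep <- sw$n_windows > 0L
  est <- haf_site(sw$weights[keep, , drop = FALSE], table, sites[keep])
  af_track(table, sites[keep], est, sw$n_windows[keep], "HAF")
}

af_track <- function(table, sites, est, support, method) {
  out <- data.frame(chrom = table$chrom, pos = table$pos[sites],
                    ref = table$ref[sites], alt = table$alt[sites],
                    est_freq = est, support = support)
  attr(out, "method") <- method
  class(out) <- c("af_track", "data.frame")
  out
}

#' Raw allele frequencies from read pileup
#'
#' The raw allele frequency at a SNP site is the fraction of mapped reads
#' carrying the alternate allele, after discarding reads with neither the
#' reference nor the alternate base. Sites with no informative read are
#' dropped from the track.
#'
#' @param reads SAM/BAM path or `read_obs` from [extract_observations()].
#' @param table a [snp_table].
#' @param sites optional SNP column indices to restrict to.
#' @return an `af_track` with `support` = informative read depth and
#'   attribute `method = "RAW"`.
#' @export
raw_af <- function(reads, table, sites = NULL) {
  obs <- if (inherits(reads, "read_obs")) reads
         else extract_observations(reads, table)
  if (is.null(sites)) sites <- seq_along(table$pos)
  inf <- obs[obs$allele %in% c(0L, 1L) & obs$site %in% sites, ]
  if (!nrow(inf)) return(af_track(table, integer(), numeric(), integer(), "RAW"))
  cnt <- inf[, list(n_alt = sum(allele == 1L), depth = .N), by = "site"]
  data.table::setorderv(cnt, "site")
  af_track(table, cnt$site, cnt$n_alt / cnt$depth, cnt$depth, "RAW")
}

#' @export
print.af_track <- function(x, ...) {
  cat(sprintf("af_track (%s): %d sites on %s, mean frequency %.4f\n",
              attr(x, "method"), nrow(x),
              if (nrow(x)) x$chrom[1L] else "?", mean(x$est_freq)))
  invisible(x)
}

#' Write an allele-frequency track as TSV
#'
#' @param track an `af_track`.
#' @param file output path.
#' @export
write_af_track <- function(track, file) {
  data.table::fwrite(as.data.frame(track), file, sep = "\t")
  invisible(file)
}
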