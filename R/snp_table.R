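#' Founder SNP table
#'
#' A `snp_table` holds the genotypes of a panel of (near-)homozygous founder
#' lines at biallelic SNP sites on a single chromosome. It is the haplotype
#' reference panel that window-based frequency inference and HAF weighting
#' operate on.
#'
#' @param chrom single chromosome identifier.
#' @param pos integer vector of strictly increasing 1-based SNP coordinates.
#' @param ref,alt single-character reference/alternate alleles per site,
#'   `ref != alt` at every site.
#' @param geno integer matrix, founders in rows and sites in columns, coded
#'   0 = REF, 1 = ALT, `NA` = missing call. Row names are founder ids
#'   (generated as `F001..` when absent).
#'
#' @return An object of class `snp_table` with elements `chrom`, `pos`,
#'   `ref`, `alt`, `geno`, `founder_ids`.
#' @export
snp_table <- function(chrom, pos, ref, alt, geno) {
  if (length(chrom) != 1L) stop("'chrom' must be a single identifier")
  pos <- as.integer(pos)
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  n_sites <- length(pos)
  if (ncol(geno) != n_sites)
    stop("genotype matrix must have one column per site")
  if (length(ref) != n_sites || length(alt) != n_sites)
    stop("'ref' and 'alt' must have one allele per site")
  if (n_sites > 1L && any(diff(pos) <= 0L))
    stop("positions must be strictly increasing")
  if (any(ref == alt)) stop("every site must be biallelic (ref != alt)")
  bad <- geno[!is.na(geno)]
  if (length(bad) && !all(bad %in% c(0L, 1L)))
    stop("genotypes must be coded 0 (REF), 1 (ALT) or NA (missing)")
  if (any(colSums(!is.na(geno)) == 0L))
    stop("each site must have at least one genotyped founder")
  if (is.null(rownames(geno)))
    rownames(geno) <- sprintf("F%03d", seq_len(nrow(geno)))
  structure(
    list(chrom = as.character(chrom), pos = pos,
         ref = as.character(ref), alt = as.character(alt),
         geno = geno, founder_ids = rownames(geno)),
    class = "snp_table")
}

#' @export
print.snp_table <- function(x, ...) {
  n_miss <- sum(is.na(x$geno))
  cat(sprintf("snp_table: %d founders x %d sites on %s (%d-%d)\n",
              nrow(x$geno), length(x$pos), x$chrom,
              min(x$pos), max(x$pos)))
  cat(sprintf("  missing calls: %d (%.2f%%)\n",
              n_miss, 100 * n_miss / length(x$geno)))
  if (inherits(x, "imputed_snp_table"))
    cat(sprintf("  imputed calls: %d\n", sum(x$imputed_mask)))
  invisible(x)
}

#' @export
dim.snp_table <- function(x) dim(x$geno)

n_founders <- function(x) nrow(x$geno)
n_sites <- function(x) length(x$pos)

#' Alternate-allele fraction among genotyped founders
#'
#' Fraction of founders carrying the alternate allele at a site, counting
#' only genotyped (non-missing) calls. This is the fractional allele count
#' assigned to founders with missing genotypes during HAF calculation, and
#' the exact pooled frequency of an equal, unrecombined founder pool.
#'
#' @param table a [snp_table].
#' @param sites integer site indices (columns); default all sites.
#' @return numeric vector in `[0, 1]`, one value per requested site.
#' @export
alt_fraction <- function(table, sites = seq_along(table$pos)) {
  g <- table$geno[, sites, drop = FALSE]
  n_gt <- colSums(!is.na(g))
  if (any(n_gt == 0L)) stop("site with no genotyped founder")
  colSums(g, na.rm = TRUE) / n_gt
}

#' Impute missing founder genotypes
#'
#' Window-based haplotype frequency inference requires a complete genotype
#' matrix; missing founder calls (including residual heterozygosity recorded
#' as missing) are filled in before inference. Two methods are provided:
#'
#' * `"nearest_neighbor"` (default): each missing call is copied from the
#'   founder with the fewest mismatches at the `k` nearest genotyped flanking
#'   sites of the focal founder (sites where both founders are genotyped are
#'   compared; ties, or no informative neighbour, fall back to the site's
#'   major allele). This exploits the local haplotype similarity that window
#'   inference itself relies on.
#' * `"major_allele"`: the more common allele among genotyped founders at the
#'   site; exact ties resolve to REF.
#'
#' @param table a [snp_table].
#' @param method `"nearest_neighbor"` or `"major_allele"`.
#' @param k number of genotyped flanking sites (per focal founder) used for
#'   neighbour matching.
#' @return An `imputed_snp_table`: a [snp_table] with no missing calls plus
#'   an `imputed_mask` matrix flagging the filled entries.
#' @export
impute <- function(table, method = c("nearest_neighbor", "major_allele"),
                   k = 20L) {
  method <- match.arg(method)
  g <- table$geno
  mask <- is.na(g)
  if (any(mask)) {
    maj <- major_allele_site(g)
    if (method == "major_allele") {
      idx <- which(mask, arr.ind = TRUE)
      g[mask] <- maj[idx[, 2L]]
    } else {
      g <- impute_nn(g, maj, k)
    }
  }
  out <- snp_table(table$chrom, table$pos, table$ref, table$alt, g)
  out$imputed_mask <- mask
  class(out) <- c("imputed_snp_table", "snp_table")
  out
}

# major allele per site among genotyped founders; ties -> REF (0)
major_allele_site <- function(g) {
  af <- colSums(g, na.rm = TRUE) / colSums(!is.na(g))
  as.integer(af > 0.5)
}

impute_nn <- function(g, maj, k) {
  out <- g
  nf <- nrow(g)
  for (f in seq_len(nf)) {
    miss <- which(is.na(g[f, ]))
    if (!length(miss)) next
    typed <- which(!is.na(g[f, ]))
    for (s in miss) {
      if (!length(typed)) { out[f, s] <- maj[s]; next }
      # k genotyped sites of founder f nearest to s (by site index)
      ord <- order(abs(typed - s))
      flank <- typed[ord[seq_len(min(k, length(typed)))]]
      gf <- g[f, flank]
      gn <- g[-f, flank, drop = FALSE]
      # mismatches over sites genotyped in both; NA comparisons dropped
      cmp <- sweep(gn, 2L, gf, `!=`)
      n_obs <- rowSums(!is.na(cmp))
      mism <- rowSums(cmp, na.rm = TRUE)
      rate <- ifelse(n_obs > 0L, mism / n_obs, Inf)
      cand <- which(rate == min(rate))
      # candidate neighbours must themselves be genotyped at s
      alle <- g[-f, s][cand]
      alle <- alle[!is.na(alle)]
      if (!is.finite(min(rate)) || !length(alle)) { out[f, s] <- maj[s]; next }
      if (length(unique(alle)) > 1L) out[f, s] <- maj[s]
      else out[f, s] <- alle[1L]
    }
  }
  out
}

#' Read founder genotypes from a VCF
#'
#' Converts a one-sample-per-founder VCF into a [snp_table]. Only biallelic
#' SNP records are used; indels, multiallelic records and sites monomorphic
#' across the genotyped founders are dropped. Because founders are expected
#' to be (near-)homozygous inbred lines, heterozygous calls reflect residual
#' heterozygosity and are recorded as missing by default.
#'
#' @param file path to a VCF (v4.x) with a GT field.
#' @param het_policy `"missing"` records heterozygous calls as missing
#'   (default); `"random"` assigns one of the two alleles at random.
#' @param chrom optional chromosome to restrict to; default: the first
#'   chromosome in the file (a `snp_table` is single-chromosome).
#' @return a [snp_table].
#' @export
vcf_to_snptable <- function(file, het_policy = c("missing", "random"),
                            chrom = NULL) {
  het_policy <- match.arg(het_policy)
  v <- tryCatch(vcfR::read.vcfR(file, verbose = FALSE),
                error = function(e) stop("malformed VCF: ", conditionMessage(e)))
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  if (is.null(chrom)) chrom <- fix[1L, "CHROM"]
  gt <- vcfR::extract.gt(v, element = "GT")
  keep <- fix[, "CHROM"] == chrom &
    nchar(fix[, "REF"]) == 1L & !is.na(fix[, "ALT"]) &
    nchar(fix[, "ALT"]) == 1L & !grepl(",", fix[, "ALT"], fixed = TRUE) &
    fix[, "REF"] %in% c("A", "C", "G", "T") &
    fix[, "ALT"] %in% c("A", "C", "G", "T")
  if (!any(keep)) stop("no biallelic SNP records found")
  fix <- fix[keep, , drop = FALSE]
  gt <- gt[keep, , drop = FALSE]
  g <- decode_gt(gt, het_policy)        # sites x founders
  g <- t(g)                             # founders x sites
  # drop sites with no genotyped founder or monomorphic across founders
  n_gt <- colSums(!is.na(g))
  n_alt <- colSums(g, na.rm = TRUE)
  seg <- n_gt > 0L & n_alt > 0L & n_alt < n_gt
  if (!any(seg)) stop("no segregating sites after filtering")
  ord <- order(as.integer(fix[seg, "POS"]))
  cols <- which(seg)[ord]
  snp_table(chrom, as.integer(fix[cols, "POS"]),
            fix[cols, "REF"], fix[cols, "ALT"],
            g[, cols, drop = FALSE])
}

decode_gt <- function(gt, het_policy) {
  a <- sub("^([0-9.])([/|]([0-9.]))?.*$", "\\1", gt)
  b <- sub("^([0-9.])([/|]([0-9.]))?.*$", "\\3", gt)
  b[b == ""] <- a[b == ""]              # haploid calls
  g <- matrix(NA_integer_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  hom0 <- a == "0" & b == "0"
  hom1 <- a == "1" & b == "1"
  g[hom0] <- 0L
  g[hom1] <- 1L
  het <- (a == "0" & b == "1") | (a == "1" & b == "0")
  if (het_policy == "random" && any(het, na.rm = TRUE)) {
    hidx <- which(het)
    g[hidx] <- sample(c(0L, 1L), length(hidx), replace = TRUE)
  }
  g
}

#' Write / read the SNP-table text format
#'
#' One row per site: `chrom`, `pos` (1-based), `ref`, `alt`, then a string of
#' one genotype character per founder (`0` = REF, `1` = ALT, `.` = missing).
#' Founder ids are carried in a `##founders=` header line. The format
#' round-trips exactly and diffs cleanly.
#'
#' @param table a [snp_table].
#' @param file output path.
#' @export
write_snptable <- function(table, file) {
  codes <- matrix(".", nrow(table$geno), ncol(table$geno))
  codes[!is.na(table$geno)] <- as.character(table$geno[!is.na(table$geno)])
  gstr <- apply(codes, 2L, paste0, collapse = "")
  hdr <- c(paste0("##founders=", paste(table$founder_ids, collapse = ",")),
           "#chrom\tpos\tref\talt\tgenotypes")
  body <- paste(table$chrom, table$pos, table$ref, table$alt, gstr, sep = "\t")
  writeLines(c(hdr, body), file)
  invisible(file)
}

#' @rdname write_snptable
#' @return `read_snptable()` returns a [snp_table].
#' @export
read_snptable <- function(file) {
  lines <- readLines(file)
  fhdr <- grep("^##founders=", lines, value = TRUE)
  if (!length(fhdr)) stop("missing ##founders= header")
  ids <- strsplit(sub("^##founders=", "", fhdr[1L]), ",", fixed = TRUE)[[1L]]
  body <- lines[!startsWith(lines, "#")]
  if (!length(body)) stop("empty SNP table")
  parts <- strsplit(body, "\t", fixed = TRUE)
  if (any(lengths(parts) != 5L)) stop("malformed SNP-table row")
  m <- do.call(rbind, parts)
  gchr <- strsplit(m[, 5L], "", fixed = TRUE)
  if (any(lengths(gchr) != length(ids)))
    stop("genotype string length does not match founder count")
  g <- matrix(unlist(gchr), nrow = length(ids),
              dimnames = list(ids, NULL))
  geno <- matrix(NA_integer_, nrow(g), ncol(g), dimnames = dimnames(g))
  geno[g == "0"] <- 0L
  geno[g == "1"] <- 1L
  snp_table(m[1L, 1L], as.integer(m[, 2L]), m[, 3L], m[, 4L], geno)
}

#' Restrict a SNP table to a subset of sites
#'
#' @param table a [snp_table].
#' @param sites integer column indices to keep (in order).
#' @return a [snp_table] (imputation mask subset alongside, if present).
#' @export
subset_sites <- function(table, sites) {
  out <- snp_table(table$chrom, table$pos[sites], table$ref[sites],
                   table$alt[sites], table$geno[, sites, drop = FALSE])
  if (inherits(table, "imputed_snp_table")) {
    out$imputed_mask <- table$imputed_mask[, sites, drop = FALSE]
    class(out) <- class(table)
  }
  out
}
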