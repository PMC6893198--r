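#' Extract SNP observations from aligned reads
#'
#' Decodes a SAM/BAM file into per-read observations at the panel's SNP
#' sites: for every read overlapping at least one SNP, the covered site
#' indices, the observed allele (REF / ALT / OTHER) and the base-error
#' probability \eqn{\epsilon = 10^{-Q/10}} from the base quality. Paired
#' mates are merged into a single observation per template; where mates
#' disagree at an overlapping site the higher-quality base wins. Unmapped,
#' secondary, duplicate and supplementary alignments are skipped. CIGAR
#' operations are respected: bases inserted/clipped relative to the
#' reference are skipped over and deletions spanning a SNP leave that site
#' unobserved.
#'
#' @param file path to a SAM (text) or BAM file.
#' @param table a [snp_table] on the same chromosome/coordinates.
#' @param region optional `c(start, end)` 1-based closed interval limiting
#'   extraction.
#' @return a `read_obs` object: a [data.table::data.table] with columns
#'   `read` (integer template id), `site` (SNP column index in `table`),
#'   `allele` (0 = REF, 1 = ALT, 2 = OTHER) and `eps`, sorted by `site`;
#'   attribute `n_reads` gives the number of informative templates.
#' @export
extract_observations <- function(file, table, region = NULL) {
  bam <- as_bam(file)
  flag <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                 isSecondaryAlignment = FALSE,
                                 isDuplicate = FALSE,
                                 isSupplementaryAlignment = FALSE)
  param <- Rsamtools::ScanBamParam(
    flag = flag,
    what = c("qname", "pos", "cigar", "seq", "qual"))
  b <- Rsamtools::scanBam(bam, param = param)[[1L]]
  n <- length(b$pos)
  if (!n) return(empty_read_obs())
  seqs <- as.character(b$seq)
  quals <- as.character(b$qual)
  simple <- grepl("^[0-9]+M$", b$cigar)

  # aligned blocks: (ref start, ref end, query offset of block start)
  blk <- aligned_blocks(b$pos, b$cigar, simple)
  site_pos <- table$pos
  if (!is.null(region)) {
    keep_site <- site_pos >= region[1L] & site_pos <= region[2L]
    site_idx_map <- which(keep_site)
  } else {
    site_idx_map <- seq_along(site_pos)
  }
  sp <- site_pos[site_idx_map]
  if (!length(sp)) return(empty_read_obs())

  hits <- IRanges::findOverlaps(
    IRanges::IRanges(start = sp, width = 1L),
    IRanges::IRanges(start = blk$rstart, end = blk$rend))
  if (!length(hits)) return(empty_read_obs())
  si <- S4Vectors::queryHits(hits)    # index into sp
  bi <- S4Vectors::subjectHits(hits)  # index into blocks
  ri <- blk$read[bi]                  # alignment record index
  off <- blk$qoff[bi] + (sp[si] - blk$rstart[bi])
  base <- substr(seqs[ri], off, off)
  qch <- substr(quals[ri], off, off)
  q <- as.integer(charToRaw(paste(qch, collapse = ""))) - 33L
  eps <- pmin(pmax(10^(-q / 10), 1e-12), 0.75)
  site <- site_idx_map[si]
  allele <- ifelse(base == table$alt[site], 1L,
                   ifelse(base == table$ref[site], 0L, 2L))

  dt <- data.table::data.table(
    qname = b$qname[ri], site = site, allele = allele, eps = eps)
  # merge mates: one observation per (template, site); lowest eps wins
  data.table::setorderv(dt, c("qname", "site", "eps"))
  dt <- unique(dt, by = c("qname", "site"))
  dt[, read := as.integer(factor(qname, levels = unique(qname)))]
  nr <- dt[.N, read]
  dt[, qname := NULL]
  data.table::setorderv(dt, c("site", "read"))
  data.table::setattr(dt, "n_reads", nr)
  data.table::setattr(dt, "class", c("read_obs", class(dt)))
  dt[]
}

empty_read_obs <- function() {
  dt <- data.table::data.table(read = integer(), site = integer(),
                               allele = integer(), eps = numeric())
  data.table::setattr(dt, "n_reads", 0L)
  data.table::setattr(dt, "class", c("read_obs", class(dt)))
  dt
}

# convert SAM text to (sorted, indexed) BAM in tempdir when needed
as_bam <- function(file) {
  if (grepl("\\.bam$", file, ignore.case = TRUE)) return(file)
  dest <- tempfile(fileext = "")
  Rsamtools::asBam(file, destination = dest, overwrite = TRUE,
                   indexDestination = TRUE)
}

# decompose alignments into blocks matched to the reference (M ops),
# tracking the query offset of each block; fast path for k-M cigars
aligned_blocks <- function(pos, cigar, simple) {
  reads <- which(simple)
  if (length(reads)) {
    len <- as.integer(sub("M$", "", cigar[simple]))
    out <- list(read = reads, rstart = pos[simple],
                rend = pos[simple] + len - 1L, qoff = rep(1L, length(reads)))
  } else {
    out <- list(read = integer(), rstart = integer(), rend = integer(),
                qoff = integer())
  }
  hard <- which(!simple)
  if (length(hard)) {
    ops <- GenomicAlignments::cigarRangesAlongReferenceSpace(
      cigar[hard], pos = pos[hard], ops = "M")
    qops <- GenomicAlignments::cigarRangesAlongQuerySpace(
      cigar[hard], ops = "M", after.soft.clipping = FALSE)
    nblk <- lengths(ops)
    ropsu <- unlist(ops)
    qopsu <- unlist(qops)
    out$read <- c(out$read, rep(hard, nblk))
    out$rstart <- c(out$rstart, IRanges::start(ropsu))
    out$rend <- c(out$rend, IRanges::end(ropsu))
    out$qoff <- c(out$qoff, IRanges::start(qopsu))
  }
  out
}

#' Log-likelihood of one read observation against one haplotype
#'
#' Per-site independent error model: an observed base matching the
#' haplotype's allele contributes \eqn{\log(1-\epsilon)}, a mismatching
#' base (including bases that are neither REF nor ALT) contributes
#' \eqn{\log(\epsilon/3)}.
#'
#' @param sites SNP column indices covered by the read.
#' @param alleles observed alleles at those sites (0 = REF, 1 = ALT,
#'   2 = OTHER).
#' @param eps per-site base-error probabilities.
#' @param hap full 0/1 haplotype vector (a row of an imputed genotype
#'   matrix; no missing calls).
#' @return the log-probability of the read given the haplotype.
#' @export
read_loglik <- function(sites, alleles, eps, hap) {
  h <- hap[sites]
  if (anyNA(h)) stop("haplotype has missing calls; impute first")
  match <- alleles == h          # OTHER (2) never matches 0/1
  sum(ifelse(match, log1p(-eps), log(eps / 3)))
}

# reads x founders log-likelihood matrix for the observations falling on
# `sites` (SNP column indices), via sparse accumulation:
#   L[r,h] = sum_t log(eps/3) + w_t * [G[h,j_t] == a_t],
#   w_t = log(1-eps_t) - log(eps_t/3)
window_loglik <- function(obs, geno, sites) {
  sub <- obs[obs$site %in% sites, ]
  if (!nrow(sub)) return(NULL)
  rid <- match(sub$read, unique(sub$read))
  jid <- match(sub$site, sites)
  nr <- max(rid)
  ns <- length(sites)
  w <- log1p(-sub$eps) - log(sub$eps / 3)
  base <- rowsum(log(sub$eps / 3), rid)[, 1L]
  Gt <- t(geno[, sites, drop = FALSE])   # sites x founders, 0/1
  is_alt <- sub$allele == 1L
  is_ref <- sub$allele == 0L
  A <- Matrix::sparseMatrix(i = rid[is_alt], j = jid[is_alt],
                            x = w[is_alt], dims = c(nr, ns))
  B <- Matrix::sparseMatrix(i = rid[is_ref], j = jid[is_ref],
                            x = w[is_ref], dims = c(nr, ns))
  L <- as.matrix((A - B) %*% Gt) + base + Matrix::rowSums(B)
  rownames(L) <- NULL
  L
}

#' Maximum-likelihood haplotype frequencies for one window
#'
#' Fits the mixture over founder haplotypes by EM: each read is
#' probabilistically assigned to founders from its per-site likelihoods,
#' and frequencies are updated as the mean posterior assignment. The data
#' log-likelihood is non-decreasing over iterations; convergence is
#' declared when the largest frequency change falls below `tol`.
#'
#' @param loglik reads x founders matrix of log P(read | haplotype).
#' @param tol convergence tolerance on max absolute frequency change.
#' @param max_iter iteration cap.
#' @param init initial frequency vector; default uniform.
#' @return a `window_freqs` list: `freqs` (simplex over founders),
#'   `n_reads`, `converged`, `n_iter`, `loglik_trace`.
#' @export
em_frequencies <- function(loglik, tol = 1e-6, max_iter = 500L, init = NULL) {
  H <- ncol(loglik)
  if (is.null(init)) init <- rep(1 / H, H)
  if (is.null(loglik) || nrow(loglik) == 0L) {
    warning("no reads in window; returning uniform frequencies")
    return(structure(list(freqs = rep(1 / H, H), n_reads = 0L,
                          converged = FALSE, n_iter = 0L,
                          loglik_trace = numeric()),
                     class = "window_freqs"))
  }
  rmax <- apply(loglik, 1L, max)
  expL <- exp(loglik - rmax)
  fit <- .em_core(expL, init, tol, as.integer(max_iter))
  structure(list(freqs = fit$freqs, n_reads = nrow(loglik),
                 converged = fit$converged, n_iter = fit$n_iter,
                 loglik_trace = fit$loglik_trace + sum(rmax)),
            class = "window_freqs")
}

#' Infer haplotype frequencies along a chromosome
#'
#' Runs the per-window EM over every frequency window of a plan. Read
#' observations are extracted once and shared across windows, so results
#' are identical to computing each window's likelihood matrix directly.
#' Because consecutive windows share most of their reads, each window's EM
#' is warm-started from the previous window's estimate (mixed with a small
#' uniform mass to stay interior to the simplex); the per-window
#' log-likelihood is concave in the frequency vector, so the optimum does
#' not depend on the initial point and warm starts only change the
#' iteration count. Windows containing no informative read fall back to
#' uniform frequencies with a warning.
#'
#' @param reads a SAM/BAM path or a precomputed `read_obs` from
#'   [extract_observations()].
#' @param table an imputed [snp_table] (no missing calls).
#' @param plan a `window_plan` from [build_plan()].
#' @param tol,max_iter EM controls, see [em_frequencies()].
#' @return a `hap_freqs` object: `freqs` (windows x founders matrix),
#'   `windows` (0-based half-open intervals), `n_reads`, `converged`,
#'   `n_iter` per window, plus `founder_ids` and `chrom`.
#' @export
infer_chromosome <- function(reads, table, plan, tol = 1e-6, max_iter = 500L) {
  if (anyNA(table$geno))
    stop("founder table has missing calls; impute() before inference")
  obs <- if (inherits(reads, "read_obs")) reads
         else extract_observations(reads, table)
  w <- plan$freq_windows
  nw <- nrow(w)
  H <- nrow(table$geno)
  freqs <- matrix(NA_real_, nw, H, dimnames = list(NULL, table$founder_ids))
  n_reads <- integer(nw)
  converged <- logical(nw)
  n_iter <- integer(nw)
  # contiguous triplet blocks per window: obs is sorted by site
  site_of_row <- obs$site
  pos <- table$pos
  warm <- NULL
  for (i in seq_len(nw)) {
    j1 <- findInterval(w[i, "start"], pos) + 1L       # first pos > start (0-based window)
    j2 <- findInterval(w[i, "end"], pos)              # last pos <= end
    sites <- if (j1 <= j2) seq.int(j1, j2) else integer()
    L <- if (length(sites)) {
      rows <- findInterval(c(j1 - 1L, j2), site_of_row)
      if (rows[2L] > rows[1L])
        window_loglik(obs[(rows[1L] + 1L):rows[2L], ], table$geno, sites)
      else NULL
    } else NULL
    init <- if (is.null(warm)) NULL else 0.95 * warm + 0.05 / H
    fit <- suppressWarnings(
      em_frequencies(if (is.null(L)) matrix(0, 0, H) else L,
                     tol = tol, max_iter = max_iter, init = init))
    if (fit$n_reads == 0L)
      warning(sprintf("window %d [%g, %g) has no informative reads",
                      i, w[i, "start"], w[i, "end"]))
    else warm <- fit$freqs
    freqs[i, ] <- fit$freqs
    n_reads[i] <- fit$n_reads
    converged[i] <- fit$converged
    n_iter[i] <- fit$n_iter
  }
  structure(list(freqs = freqs, windows = w, n_reads = n_reads,
                 converged = converged, n_iter = n_iter,
                 founder_ids = table$founder_ids, chrom = table$chrom,
                 plan = plan),
            class = "hap_freqs")
}

#' @export
print.hap_freqs <- function(x, ...) {
  cat(sprintf(
    "hap_freqs: %d windows x %d founders on %s; %d/%d windows converged; median reads/window %d\n",
    nrow(x$freqs), ncol(x$freqs), x$chrom, sum(x$converged),
    length(x$converged), as.integer(stats::median(x$n_reads))))
  invisible(x)
}

#' Read or write window haplotype frequencies as TSV
#'
#' Long format: chrom, window start/end (0-based half-open), founder id,
#' frequency. [read_hap_freqs()] reconstructs a `hap_freqs` object from the
#' file; per-window diagnostics (`n_reads`, `converged`, `n_iter`) are not
#' stored in the file and come back as `NA`.
#'
#' @param hf a `hap_freqs` object.
#' @param file output path.
#' @export
write_hap_freqs <- function(hf, file) {
  nw <- nrow(x <- hf$freqs)
  dt <- data.table::data.table(
    chrom = hf$chrom,
    start = rep(hf$windows[, "start"], each = ncol(x)),
    end = rep(hf$windows[, "end"], each = ncol(x)),
    founder = rep(colnames(x), nw),
    freq = as.vector(t(x)))
  data.table::fwrite(dt, file, sep = "\t")
  invisible(file)
}

#' @rdname write_hap_freqs
#' @export
read_hap_freqs <- function(file) {
  dt <- data.table::fread(file, sep = "\t")
  stopifnot(all(c("chrom", "start", "end", "founder", "freq") %in% names(dt)))
  founders <- unique(dt$founder)
  key <- paste(dt$start, dt$end)
  wkey <- unique(key)
  freqs <- matrix(NA_real_, length(wkey), length(founders),
                  dimnames = list(NULL, founders))
  freqs[cbind(match(key, wkey), match(dt$founder, founders))] <- dt$freq
  if (anyNA(freqs)) stop("incomplete window x founder grid in ", file)
  w <- unique(data.frame(start = dt$start, end = dt$end))
  nw <- nrow(w)
  wm <- cbind(start = w$start, end = w$end)
  size <- max(wm[, "end"] - wm[, "start"])
  L <- max(wm[, "end"])
  plan <- structure(list(
    freq_windows = wm, lik_windows = cbind(start = 0, end = L),
    window_size = size,
    freq_step = if (nw > 1L) wm[2L, "start"] - wm[1L, "start"] else size,
    lik_step = L, L = L), class = "window_plan")
  structure(list(freqs = freqs, windows = wm,
                 n_reads = rep(NA_integer_, nw),
                 converged = rep(NA, nw),
                 n_iter = rep(NA_integer_, nw),
                 founder_ids = founders, chrom = dt$chrom[1L], plan = plan),
            class = "hap_freqs")
}
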