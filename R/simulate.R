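#' Generate a synthetic founder panel
#'
#' Builds a random reference sequence and a founder genotype panel that
#' emulates a set of sequenced, homozygous inbred lines: biallelic SNPs at
#' a chosen density, alternate-allele counts drawn from a site-frequency
#' spectrum, and (optionally) missing genotype calls placed uniformly at
#' random.
#'
#' @param n_founders number of founder haplotypes.
#' @param L chromosome length in bp.
#' @param snp_density SNPs per bp; the default matches a dense panel of
#'   ~283k segregating sites on a 23 Mb chromosome (~12.3 SNPs/kb).
#' @param af_spectrum `"neutral"` draws the alternate count `k` with
#'   probability proportional to `1/k` (`k` in `1..n_founders-1`);
#'   `"uniform"` draws `k` uniformly.
#' @param missing_rate fraction of genotype calls set to missing
#'   (0 to 0.15).
#' @param chrom chromosome name.
#' @param seed optional RNG seed.
#' @return a `founder_panel`: list with `table` (a [snp_table], containing
#'   any missing calls), `truth_table` (the complete genotypes, used for
#'   read simulation and pool truth) and `ref` (reference sequence as a
#'   single character string with the reference alleles embedded).
#' @export
generate_panel <- function(n_founders, L, snp_density = 283437 / 23e6,
                           af_spectrum = c("neutral", "uniform"),
                           missing_rate = 0, chrom = "chrSim", seed = NULL) {
  af_spectrum <- match.arg(af_spectrum)
  stopifnot(n_founders >= 2, missing_rate >= 0, missing_rate <= 0.15)
  n_sites <- round(snp_density * L)
  if (n_sites < 100) stop("panel must have at least 100 SNP sites")
  if (!is.null(seed)) set.seed(seed)
  bases <- c("A", "C", "G", "T")
  ref_vec <- sample(bases, L, replace = TRUE)
  pos <- sort(sample.int(L, n_sites))
  ref <- ref_vec[pos]
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), character(1L))
  kmax <- n_founders - 1L
  prob <- switch(af_spectrum,
                 neutral = (1 / seq_len(kmax)) / sum(1 / seq_len(kmax)),
                 uniform = rep(1 / kmax, kmax))
  k <- sample.int(kmax, n_sites, replace = TRUE, prob = prob)
  geno <- matrix(0L, n_founders, n_sites)
  carrier <- lapply(k, function(ki) sample.int(n_founders, ki))
  geno[cbind(unlist(carrier), rep.int(seq_len(n_sites), k))] <- 1L
  geno_full <- geno
  if (missing_rate > 0) {
    nmiss <- round(missing_rate * length(geno))
    idx <- sample.int(length(geno), nmiss)
    geno[idx] <- NA_integer_
    # keep every site genotyped in at least one founder by unmasking one call
    dead <- which(colSums(!is.na(geno)) == 0L)
    for (j in dead) {
      i <- sample.int(n_founders, 1L)
      geno[i, j] <- geno_full[i, j]
    }
  }
  tab <- snp_table(chrom, pos, ref, alt, geno)
  structure(list(
    table = tab,
    truth_table = if (missing_rate > 0) snp_table(chrom, pos, ref, alt,
                                                  geno_full)
                  else tab,
    ref = paste(ref_vec, collapse = ""), L = L),
    class = "founder_panel")
}

#' @export
print.founder_panel <- function(x, ...) {
  cat(sprintf("founder_panel: %d bp reference; ", x$L))
  print(x$table)
  invisible(x)
}

#' Write the panel reference as FASTA
#'
#' @param panel a `founder_panel`.
#' @param file output path.
#' @export
write_panel_fasta <- function(panel, file) {
  s <- Biostrings::DNAStringSet(panel$ref)
  names(s) <- panel$table$chrom
  Biostrings::writeXStringSet(s, file)
  invisible(file)
}

#' Selection regime for the forward simulator
#'
#' Selected loci contribute additively to a quantitative trait: genotypes
#' homozygous reference / heterozygous / homozygous alternate contribute
#' 0, `s`, `2s` respectively, plus environmental noise of variance `Ve`.
#' Fitness decays linearly with distance from the trait optimum:
#' `w = max(0, 1 - |optimum - T|)`.
#'
#' @param sites SNP column indices under selection (must be genotyped in
#'   every founder).
#' @param s selection coefficient per alternate allele.
#' @param Ve environmental variance of the trait.
#' @param optimum trait optimum.
#' @return a `selection_regime` list.
#' @export
selection_regime <- function(sites, s, Ve = 0.01, optimum = 1) {
  stopifnot(length(sites) >= 1, !anyDuplicated(sites), s >= 0, Ve >= 0)
  structure(list(sites = as.integer(sites), s = s, Ve = Ve,
                 optimum = optimum), class = "selection_regime")
}

# founder id at 1-based positions on a mosaic chromosome
# chrom: list(bp = segment end coordinates (last == L), fid = founder ids)
founder_at <- function(chrom, pos) {
  chrom$fid[findInterval(pos - 0.5, chrom$bp) + 1L]
}

# recombine two parental chromosomes at crossover positions (sorted not
# required); gamete starts on a random chromosome when start is NA
recombine <- function(c1, c2, xo, L, start = NULL) {
  if (is.null(start)) start <- sample.int(2L, 1L)
  if (!length(xo)) return(if (start == 1L) c1 else c2)
  cs <- list(c1, c2)
  cur <- start
  bounds <- c(sort(xo), L)
  bp <- numeric(0)
  fid <- integer(0)
  a <- 0
  for (b in bounds) {
    ch <- cs[[cur]]
    i1 <- findInterval(a, ch$bp) + 1L
    # last segment with start < b: strict inequality avoids stepping past
    # the end when b coincides with a segment boundary
    i2 <- findInterval(b, ch$bp, left.open = TRUE) + 1L
    bp <- c(bp, pmin(ch$bp[i1:i2], b))
    fid <- c(fid, ch$fid[i1:i2])
    a <- b
    cur <- 3L - cur
  }
  # merge adjacent segments from the same founder
  n <- length(fid)
  keep <- c(fid[-1L] != fid[-n], TRUE)
  list(bp = bp[keep], fid = fid[keep])
}

#' Forward-in-time simulation of recombination and selection
#'
#' Simulates a constant-size, randomly mating population of `N` diploids
#' over `G` non-overlapping generations. Each individual starts as a
#' homozygous copy of a randomly chosen founder haplotype. Every offspring
#' draws two parents independently with probability proportional to
#' fitness (selfing allowed); each transmitted gamete receives a
#' Poisson(`L * R`) number of crossovers placed uniformly, applied to the
#' parent's two chromosomes. The single rate `R` is applied in all gametes
#' (i.e. the female rate everywhere), a conservative choice for organisms
#' with achiasmatic males. With `regime = NULL` (or `s = 0`) the trait is
#' pure noise and parent choice is independent of genotype, so allele
#' frequencies drift neutrally.
#'
#' @param panel a `founder_panel` or [snp_table]; genotypes at selected
#'   sites must be complete (impute first if needed).
#' @param G generations to simulate.
#' @param R recombination rate in crossovers per bp per gamete.
#' @param N diploid population size.
#' @param regime a [selection_regime()] or `NULL` for neutrality.
#' @param seed optional RNG seed.
#' @param track_af record the selected-site allele-frequency trajectory.
#' @return a `population`: list of `2N` mosaic chromosomes (`chroms`,
#'   consecutive pairs forming individuals), `generation`, `L`,
#'   `n_founders`, and (with `track_af`) `af_trajectory`, a
#'   `(G+1) x n_sites` matrix.
#' @export
forward_simulate <- function(panel, G, R, N = 1000L, regime = NULL,
                             seed = NULL, track_af = !is.null(regime)) {
  table <- if (inherits(panel, "founder_panel")) panel$table else panel
  L <- if (inherits(panel, "founder_panel")) panel$L else max(table$pos)
  nf <- nrow(table$geno)
  if (!is.null(seed)) set.seed(seed)
  if (!is.null(regime)) {
    gsel <- table$geno[, regime$sites, drop = FALSE]
    if (anyNA(gsel)) stop("selected sites must be genotyped in all founders")
  }
  founders_init <- sample.int(nf, N, replace = TRUE)
  chroms <- vector("list", 2L * N)
  for (i in seq_len(N)) {
    ch <- list(bp = L, fid = founders_init[i])
    chroms[[2L * i - 1L]] <- ch
    chroms[[2L * i]] <- ch
  }
  traj <- if (track_af && !is.null(regime))
    matrix(NA_real_, G + 1L, length(regime$sites)) else NULL
  sel_alleles <- function(chroms) {
    # 2N x n_sel matrix of alleles at the selected sites
    pos <- table$pos[regime$sites]
    al <- vapply(chroms, function(ch) {
      fid <- founder_at(ch, pos)
      gsel[cbind(fid, seq_along(pos))]
    }, numeric(length(pos)))
    if (is.matrix(al)) t(al) else matrix(al, ncol = 1L)
  }
  if (!is.null(traj)) traj[1L, ] <- colMeans(sel_alleles(chroms))
  for (g in seq_len(G)) {
    if (is.null(regime) || regime$s == 0 && regime$Ve == 0) {
      fit <- rep(1, N)
    } else {
      al <- sel_alleles(chroms)
      gt <- al[seq(1L, 2L * N, by = 2L), , drop = FALSE] +
            al[seq(2L, 2L * N, by = 2L), , drop = FALSE]
      trait <- regime$s * rowSums(gt) +
        stats::rnorm(N, 0, sqrt(regime$Ve))
      fit <- pmax(0, 1 - abs(regime$optimum - trait))
      if (all(fit == 0))
        stop(sprintf("all fitness values are zero at generation %d", g))
    }
    parents <- matrix(sample.int(N, 2L * N, replace = TRUE, prob = fit),
                      ncol = 2L)
    nxo <- stats::rpois(2L * N, L * R)
    nxt <- vector("list", 2L * N)
    for (i in seq_len(N)) {
      for (m in 1:2) {
        p <- parents[i, m]
        k <- nxo[2L * (i - 1L) + m]
        xo <- if (k > 0L) stats::runif(k, 0, L) else numeric()
        nxt[[2L * (i - 1L) + m]] <-
          recombine(chroms[[2L * p - 1L]], chroms[[2L * p]], xo, L)
      }
    }
    chroms <- nxt
    if (!is.null(traj)) traj[g + 1L, ] <- colMeans(sel_alleles(chroms))
  }
  structure(list(chroms = chroms, generation = G, L = L, n_founders = nf,
                 N = N, af_trajectory = traj,
                 regime = regime),
            class = "population")
}

#' @export
print.population <- function(x, ...) {
  nseg <- vapply(x$chroms, function(ch) length(ch$fid), integer(1L))
  cat(sprintf(
    "population: %d diploids at generation %d; mean %.1f founder segments per chromosome\n",
    x$N, x$generation, mean(nseg)))
  invisible(x)
}

#' Unrecombined founder-fragment lengths
#'
#' Segment lengths of the founder mosaics of a population's chromosomes;
#' their distribution links the simulator to the exponential
#' fragment-length model used for window sizing.
#'
#' @param pop a `population` (or list of mosaic chromosomes).
#' @return numeric vector of segment lengths in bp.
#' @export
fragment_lengths <- function(pop) {
  chroms <- if (inherits(pop, "population")) pop$chroms else pop
  unlist(lapply(chroms, function(ch) diff(c(0, ch$bp))))
}

#' Sample a sequencing pool from a population
#'
#' Draws `n_individuals` diploids without replacement and computes the
#' pool's exact true allele frequency at every panel site from the founder
#' mosaics and founder genotypes.
#'
#' @param pop a `population` from [forward_simulate()].
#' @param table the imputed [snp_table] the reads will be simulated from.
#' @param n_individuals diploids to pool.
#' @param seed optional RNG seed.
#' @return a `pool_sample`: `chroms` (2 x n_individuals mosaics),
#'   `true_af` (exact frequencies over all panel sites), `generation`.
#' @export
sample_pool <- function(pop, table, n_individuals = 100L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (pop$N < n_individuals) stop("population smaller than requested pool")
  ind <- sample.int(pop$N, n_individuals)
  idx <- as.vector(rbind(2L * ind - 1L, 2L * ind))
  new_pool(pop$chroms[idx], table, generation = pop$generation)
}

#' Equal-proportion pool of unrecombined founder chromosomes
#'
#' One whole, unrecombined chromosome per founder — the simplest pooled
#' sample, whose true allele frequencies are the founder alternate-allele
#' fractions.
#'
#' @param panel a `founder_panel` or imputed [snp_table].
#' @param L chromosome length; defaults to the panel length or, for a bare
#'   table, the last SNP position.
#' @return a `pool_sample` at generation 0.
#' @export
founder_pool <- function(panel, L = NULL) {
  table <- if (inherits(panel, "founder_panel")) panel$table else panel
  if (is.null(L))
    L <- if (inherits(panel, "founder_panel")) panel$L else max(table$pos)
  chroms <- lapply(seq_len(nrow(table$geno)),
                   function(f) list(bp = L, fid = f))
  new_pool(chroms, table, generation = 0L)
}

new_pool <- function(chroms, table, generation) {
  if (anyNA(table$geno))
    stop("pool truth requires a complete (imputed) genotype table")
  alle <- vapply(chroms, function(ch) {
    fid <- founder_at(ch, table$pos)
    table$geno[cbind(fid, seq_along(table$pos))]
  }, numeric(length(table$pos)))
  structure(list(chroms = chroms, true_af = rowMeans(alle),
                 generation = generation, chrom = table$chrom),
            class = "pool_sample")
}

#' @export
print.pool_sample <- function(x, ...) {
  cat(sprintf(
    "pool_sample: %d chromosomes at generation %d; %d sites, mean true AF %.4f\n",
    length(x$chroms), x$generation, length(x$true_af), mean(x$true_af)))
  invisible(x)
}

#' True allele frequencies as a track
#'
#' @param pool a `pool_sample`.
#' @param table the [snp_table] the pool was built on.
#' @return data.frame with `chrom`, `pos`, `true_af`.
#' @export
truth_track <- function(pool, table) {
  data.frame(chrom = pool$chrom, pos = table$pos, true_af = pool$true_af)
}

#' Simulate pooled paired-end reads as SAM
#'
#' Emits pre-aligned 150 bp paired-end reads sampled uniformly from the
#' pooled chromosomes: fragment positions are uniform, bases are copied
#' from the source founder mosaic (reference sequence with that founder's
#' alternate alleles substituted), and each base is flipped to a uniformly
#' chosen different base with probability `error_rate`, receiving the
#' lower error base quality. Alignments carry all-match CIGARs at the true
#' positions, so no aligner is needed downstream.
#'
#' @param pool a `pool_sample`.
#' @param panel the `founder_panel` providing the reference sequence.
#' @param table the imputed [snp_table] the haplotype sequences are built
#'   from.
#' @param coverage target mean per-base depth; the number of read pairs is
#'   `ceiling(coverage * L / (2 * read_length))`.
#' @param file output SAM path.
#' @param read_length read length in bp.
#' @param insert_range inclusive range of fragment (insert) sizes, sampled
#'   uniformly.
#' @param error_rate per-base sequencing error probability (0 to 0.05).
#' @param q_correct,q_error Phred base qualities for correct and erroneous
#'   bases.
#' @param seed optional RNG seed (recorded in the SAM header).
#' @return the SAM path, invisibly.
#' @export
simulate_reads <- function(pool, panel, table, coverage, file,
                           read_length = 150L, insert_range = c(450L, 500L),
                           error_rate = 0.002, q_correct = 30L,
                           q_error = 10L, seed = NULL) {
  stopifnot(error_rate >= 0, error_rate <= 0.05)
  if (!is.null(seed)) set.seed(seed)
  L <- panel$L
  if (insert_range[2L] > L) stop("chromosome shorter than the insert size")
  chrom <- table$chrom
  n_pairs <- as.integer(ceiling(coverage * L / (2 * read_length)))
  src <- sample.int(length(pool$chroms), n_pairs, replace = TRUE)
  ins <- sample(seq.int(insert_range[1L], insert_range[2L]), n_pairs,
                replace = TRUE)
  fstart <- floor(stats::runif(n_pairs, 1, L - ins + 1 + 1))
  p1 <- as.integer(fstart)
  p2 <- as.integer(fstart + ins - read_length)
  # interleave mates: records 2i-1 and 2i are a pair
  rpos <- as.integer(rbind(p1, p2))
  rsrc <- rep(src, each = 2L)
  n_reads <- 2L * n_pairs
  seqs <- substring(panel$ref, rpos, rpos + read_length - 1L)

  # substitute alternate alleles of the source founder mosaic
  hits <- IRanges::findOverlaps(
    IRanges::IRanges(start = table$pos, width = 1L),
    IRanges::IRanges(start = rpos, width = read_length))
  si <- S4Vectors::queryHits(hits)
  ri <- S4Vectors::subjectHits(hits)
  fid <- integer(length(ri))
  for (g in split(seq_along(ri), rsrc[ri])) {
    fid[g] <- founder_at(pool$chroms[[rsrc[ri[g[1L]]]]], table$pos[si[g]])
  }
  alle <- table$geno[cbind(fid, si)]
  alt_hit <- which(alle == 1L)
  ed_read <- ri[alt_hit]
  ed_off <- table$pos[si[alt_hit]] - rpos[ed_read] + 1L
  ed_base <- table$alt[si[alt_hit]]

  # sequencing errors
  n_err <- stats::rbinom(n_reads, read_length, error_rate)
  err_read <- rep.int(which(n_err > 0L), n_err[n_err > 0L])
  err_off <- integer(length(err_read))
  if (length(err_read)) {
    err_off <- as.integer(ceiling(stats::runif(length(err_read)) * read_length))
  }

  touch <- sort(unique(c(ed_read, err_read)))
  if (length(touch)) {
    cm <- matrix(unlist(strsplit(seqs[touch], "", fixed = TRUE)),
                 nrow = read_length)
    col_of <- integer(n_reads)
    col_of[touch] <- seq_along(touch)
    if (length(ed_read))
      cm[cbind(ed_off, col_of[ed_read])] <- ed_base
    if (length(err_read)) {
      old <- cm[cbind(err_off, col_of[err_read])]
      bases <- c("A", "C", "G", "T")
      shift <- sample.int(3L, length(err_read), replace = TRUE)
      cm[cbind(err_off, col_of[err_read])] <-
        bases[((match(old, bases) - 1L + shift) %% 4L) + 1L]
    }
    seqs[touch] <- do.call(paste0, asplit(cm, 1L))
  }
  quals <- rep(strrep(rawToChar(as.raw(q_correct + 33L)), read_length), n_reads)
  if (length(err_read)) {
    qtouch <- unique(err_read)
    qm <- matrix(unlist(strsplit(quals[qtouch], "", fixed = TRUE)),
                 nrow = read_length)
    qcol <- integer(n_reads)
    qcol[qtouch] <- seq_along(qtouch)
    qm[cbind(err_off, qcol[err_read])] <- rawToChar(as.raw(q_error + 33L))
    quals[qtouch] <- do.call(paste0, asplit(qm, 1L))
  }

  qname <- rep(sprintf("sim%08d", seq_len(n_pairs)), each = 2L)
  flag <- rep(c(99L, 147L), n_pairs)
  pnext <- as.integer(rbind(p2, p1))
  tlen <- as.integer(rbind(ins, -ins))
  cigar <- paste0(read_length, "M")
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", chrom, as.integer(L)),
           sprintf("@CO\thafkit simulate_reads coverage=%g error_rate=%g seed=%s",
                   coverage, error_rate,
                   if (is.null(seed)) "NA" else seed))
  rec <- paste(qname, flag, chrom, rpos, 60L, cigar, "=", pnext, tlen,
               seqs, quals, sep = "\t")
  writeLines(c(hdr, rec), file)
  invisible(file)
}
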