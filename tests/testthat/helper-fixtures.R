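# Small in-code fixtures shared across tests.

# deterministic little panel: nf founders, ns sites at every `spacing` bp
toy_table <- function(nf = 4L, ns = 10L, spacing = 100L, seed = 1L,
                      chrom = "chrT") {
  set.seed(seed)
  pos <- seq.int(spacing, by = spacing, length.out = ns)
  ref <- sample(c("A", "C", "G", "T"), ns, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1L),
                character(1L))
  repeat {
    geno <- matrix(sample(0:1, nf * ns, replace = TRUE), nf, ns)
    if (all(colSums(geno) > 0L & colSums(geno) < nf)) break
  }
  snp_table(chrom, pos, ref, alt, geno)
}

# write a SAM file with given alignments against `table`'s chromosome
# fields: list of lists with qname, flag, pos, cigar, seq, qual
write_toy_sam <- function(records, L = 10000L, chrom = "chrT") {
  lines <- c("@HD\tVN:1.6\tSO:unsorted",
             sprintf("@SQ\tSN:%s\tLN:%d", chrom, L))
  for (r in records) {
    lines <- c(lines, paste(
      r$qname, r$flag, chrom, r$pos, 60L,
      r$cigar, "*", 0L, 0L, r$seq, r$qual, sep = "\t"))
  }
  f <- tempfile(fileext = ".sam")
  writeLines(lines, f)
  f
}

# reference-matching read sequence for a founder haplotype over [start, end]
hap_seq <- function(ref_vec, table, founder, start, end) {
  s <- ref_vec[start:end]
  in_read <- which(table$pos >= start & table$pos <= end)
  alts <- in_read[table$geno[founder, in_read] == 1L]
  s[table$pos[alts] - start + 1L] <- table$alt[alts]
  paste(s, collapse = "")
}

qstr <- function(q, n) strrep(rawToChar(as.raw(q + 33L)), n)

# dense grid search over the simplex (resolution res) maximising the data
# log-likelihood of a reads x founders loglik matrix; H in {2, 3}
grid_mle_loglik <- function(loglik, res = 1e-3) {
  H <- ncol(loglik)
  stopifnot(H %in% c(2L, 3L))
  g <- seq(0, 1, by = res)
  if (H == 2L) {
    fgrid <- cbind(g, 1 - g)
  } else {
    fgrid <- expand.grid(f1 = g, f2 = g)
    fgrid <- fgrid[fgrid$f1 + fgrid$f2 <= 1 + 1e-12, ]
    fgrid <- cbind(fgrid$f1, fgrid$f2, pmax(0, 1 - fgrid$f1 - fgrid$f2))
  }
  rmax <- apply(loglik, 1L, max)
  expL <- exp(loglik - rmax)
  # data loglik for each candidate frequency vector
  ll <- log(expL %*% t(fgrid))
  best <- max(colSums(ll)) + sum(rmax)
  best
}
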