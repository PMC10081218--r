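# Independent brute-force oracles. These deliberately avoid the package's
# interval machinery (and GenomicRanges where possible) so agreement is a
# genuine cross-check, not a tautology.

# per-base boolean cover of a set of [start0, end) intervals on one small
# chromosome of length len
base_cover <- function(start0, end, len) {
  v <- logical(len)
  for (i in seq_along(start0)) {
    if (end[i] > start0[i]) v[(start0[i] + 1):end[i]] <- TRUE
  }
  v
}

# brute-force shared bp between two interval sets laid out per chromosome
oracle_overlap_bp <- function(a_df, b_df, chrom_lens) {
  tot <- 0
  for (ch in names(chrom_lens)) {
    ai <- a_df[a_df$chrom == ch, , drop = FALSE]
    bi <- b_df[b_df$chrom == ch, , drop = FALSE]
    va <- base_cover(ai$start, ai$end, chrom_lens[[ch]])
    vb <- base_cover(bi$start, bi$end, chrom_lens[[ch]])
    tot <- tot + sum(va & vb)
  }
  tot
}

# all-pairs count of a-intervals touching any b-interval
oracle_count_overlapping <- function(a_df, b_df) {
  n <- 0L
  for (i in seq_len(nrow(a_df))) {
    hit <- FALSE
    for (j in seq_len(nrow(b_df))) {
      if (a_df$chrom[i] == b_df$chrom[j] &&
          a_df$start[i] < b_df$end[j] && b_df$start[j] < a_df$end[i]) {
        hit <- TRUE
        break
      }
    }
    n <- n + hit
  }
  n
}

# step-up Benjamini-Hochberg written from the definition:
# q_(i) = min_{j >= i} p_(j) * m / j, capped at 1, returned in input order
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (i in seq_len(m)) q[i] <- min(1, min(ps[i:m] * m / (i:m)))
  out <- numeric(m)
  out[o] <- q
  out
}

# exact two-tailed Fisher p by full enumeration of tables with the observed
# margins; ties within relative tolerance 1e-7 count toward the tail
oracle_fisher_p <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  m1 <- a + b; m2 <- c + d; n1 <- a + c
  lo <- max(0, n1 - m2)
  hi <- min(n1, m1)
  support <- lo:hi
  probs <- dhyper(support, m1, m2, n1)
  p_obs <- dhyper(a, m1, m2, n1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# closed-form pooled-variance two-sample t and its two-sided p
oracle_pooled_t <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp2 <- ((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2)
  t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
  list(t = t, df = nx + ny - 2, p = 2 * pt(-abs(t), nx + ny - 2))
}

# random interval data.frame on a toy genome (0-based half-open)
random_intervals <- function(n, chrom_lens, max_len = 30) {
  ch <- sample(names(chrom_lens), n, replace = TRUE)
  len <- sample.int(max_len, n, replace = TRUE)
  start <- vapply(seq_len(n), function(i)
    sample.int(chrom_lens[[ch[i]]] - len[i] + 1, 1) - 1L, integer(1))
  data.frame(chrom = ch, start = start, end = start + len,
             stringsAsFactors = FALSE)
}

df_to_granges <- function(df, genome = NULL) {
  gr <- GenomicRanges::GRanges(df$chrom,
                               IRanges::IRanges(df$start + 1, df$end))
  if (!is.null(genome)) {
    GenomeInfoDb::seqlevels(gr) <- GenomeInfoDb::seqlevels(genome)
    GenomeInfoDb::seqinfo(gr) <- genome
  }
  gr
}

toy_genome <- function(lens) GenomeInfoDb::Seqinfo(names(lens), unlist(lens))
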