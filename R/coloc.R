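#' Pairwise peak overlap counts (Venn summary)
#'
#' Counts, in each direction, how many peaks of one set share at least 1 bp
#' with the other set — the numbers behind a two-set Venn diagram of binding
#' sites.
#'
#' @param a,b `GRanges` peak sets on the same genome.
#' @return Named list: `n_a`, `n_b`, `n_a_overlapping_b`, `n_a_only`,
#'   `n_b_overlapping_a`, `n_b_only`.
#' @export
venn_counts <- function(a, b) {
  n_a <- length(a); n_b <- length(b)
  ab <- count_overlapping(a, b)
  ba <- count_overlapping(b, a)
  list(n_a = n_a, n_b = n_b,
       n_a_overlapping_b = ab, n_a_only = n_a - ab,
       n_b_overlapping_a = ba, n_b_only = n_b - ba)
}

#' Fisher exact test on a 2x2 contingency table
#'
#' Exact two-tailed p-value by summing, over all tables with the observed
#' margins, the hypergeometric probabilities no larger than that of the
#' observed table (ties within a relative tolerance of 1e-7 count). The
#' reported odds ratio is the sample (cross-product) estimate `ad/bc`, with
#' the conventions `0/0 = NaN`, `x/0 = Inf`.
#'
#' @param tab 2x2 matrix of non-negative integer counts with at least one
#'   positive entry.
#' @return List with `p_two_tailed` and `odds_ratio`.
#' @export
fisher_exact_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2L, 2L))) stop("a 2x2 table is required")
  if (any(tab < 0) || any(tab != floor(tab)))
    stop("table entries must be non-negative integers")
  if (sum(tab) == 0) stop("all-zero table: no data to test")
  p <- fisher.test(tab, alternative = "two.sided")$p.value
  num <- as.numeric(tab[1, 1]) * tab[2, 2]
  den <- as.numeric(tab[1, 2]) * tab[2, 1]
  or <- if (num == 0 && den == 0) NaN else num / den
  list(p_two_tailed = min(p, 1), odds_ratio = or)
}

#' Co-localization test of two peak sets
#'
#' Quantifies how often two sets of binding sites coincide on the genome:
#' directed overlap counts and fractions ([venn_counts()]) plus a Fisher
#' exact test of co-occurrence over a genome binning. The genome is cut into
#' consecutive bins of `bin_width` (the last bin of each chromosome is
#' truncated), each bin is flagged as hit by `a` and/or by `b` (>= 1 bp
#' overlap), and the resulting 2x2 table of bin counts is tested with
#' [fisher_exact_2x2()].
#'
#' @param a,b `GRanges` peak sets, compared by coordinates (any attached
#'   seqinfo is ignored; the binning comes from `genome`).
#' @param genome A `Seqinfo`.
#' @param bin_width Bin size in bp, or `"auto"` (default): the rounded mean
#'   length of the merged intervals of `a` and `b` combined.
#' @return An object of class `peak_coloc`.
#' @examples
#' genome <- GenomeInfoDb::Seqinfo("chr1", 100000)
#' sim <- simulate_peaks(genome, n_query = 40, n_annotation = 40,
#'                       theta = 0.8, peak_median = 400, seed = 3)
#' colocalization_test(sim$query, sim$annotation, genome)
#' @export
colocalization_test <- function(a, b, genome, bin_width = "auto") {
  if (length(a) == 0L || length(b) == 0L)
    stop("both peak sets must be non-empty")
  # compare by coordinates only: the supplied genome governs the binning,
  # so peaks carrying their own (possibly differing) seqinfo still work
  strip <- function(x)
    GRanges(as.character(seqnames(x)), IRanges(start(x), end(x)))
  a <- strip(a); b <- strip(b)
  if (identical(bin_width, "auto")) {
    merged <- reduce(c(a, b), ignore.strand = TRUE)
    bin_width <- round(mean(width(merged)))
  }
  bin_width <- as.numeric(bin_width)
  if (bin_width < 1) stop("bin_width must be >= 1")
  if (bin_width > sum(as.numeric(seqlengths(genome))))
    stop("bin_width exceeds the genome length")
  bins <- tileGenome(seqlengths(genome), tilewidth = bin_width,
                     cut.last.tile.in.chrom = TRUE)
  hit_a <- overlapsAny(bins, a, ignore.strand = TRUE)
  hit_b <- overlapsAny(bins, b, ignore.strand = TRUE)
  tab <- matrix(c(sum(hit_a & hit_b), sum(hit_a & !hit_b),
                  sum(!hit_a & hit_b), sum(!hit_a & !hit_b)),
                nrow = 2, byrow = TRUE,
                dimnames = list(A = c("hit", "miss"), B = c("hit", "miss")))
  ft <- fisher_exact_2x2(tab)
  vc <- venn_counts(a, b)
  structure(c(vc,
              list(fraction_a = vc$n_a_overlapping_b / vc$n_a,
                   fraction_b = vc$n_b_overlapping_a / vc$n_b,
                   bin_width = bin_width,
                   n_bins = length(bins),
                   contingency = tab,
                   fisher_p_two_tailed = ft$p_two_tailed,
                   odds_ratio = ft$odds_ratio)),
            class = "peak_coloc")
}

#' @export
print.peak_coloc <- function(x, ...) {
  cat("Peak co-localization\n")
  cat("  A: ", x$n_a, " peaks, ", x$n_a_overlapping_b, " overlapping B (",
      signif(100 * x$fraction_a, 3), "%)\n", sep = "")
  cat("  B: ", x$n_b, " peaks, ", x$n_b_overlapping_a, " overlapping A (",
      signif(100 * x$fraction_b, 3), "%)\n", sep = "")
  cat("  Fisher test on ", x$n_bins, " genome bins of ", x$bin_width,
      " bp:\n", sep = "")
  cat("    odds ratio ", signif(x$odds_ratio, 3), ", two-tailed p ",
      format(signif(x$fisher_p_two_tailed, 3)), "\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.peak_coloc <- function(x, row.names = NULL, optional = FALSE,
                                     ...) {
  data.frame(n_a = x$n_a, n_b = x$n_b,
             n_a_overlapping_b = x$n_a_overlapping_b, n_a_only = x$n_a_only,
             n_b_overlapping_a = x$n_b_overlapping_a, n_b_only = x$n_b_only,
             fraction_a = x$fraction_a, fraction_b = x$fraction_b,
             bin_width = x$bin_width, n_bins = x$n_bins,
             n_bins_both = x$contingency[1, 1],
             fisher_p_two_tailed = x$fisher_p_two_tailed,
             odds_ratio = x$odds_ratio)
}
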