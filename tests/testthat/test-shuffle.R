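test_that("eligible space is the genome minus merged exclusions", {
  g <- toy_genome(list(chr1 = 100))
  excl <- df_to_granges(data.frame(chrom = "chr1", start = 40, end = 60), g)
  sp <- build_eligible_space(g, excl)
  expect_equal(BiocGenerics::start(sp$segments) - 1, c(0, 60))
  expect_equal(BiocGenerics::end(sp$segments), c(40, 100))
  expect_equal(sp$total, 80)

  sp0 <- build_eligible_space(g, NULL)
  expect_equal(sp0$total, 100)
  all_excl <- df_to_granges(data.frame(chrom = "chr1", start = 0, end = 100), g)
  expect_error(build_eligible_space(g, all_excl), "empty")
})

test_that("placement start positions are uniform over valid starts", {
  g <- toy_genome(list(chr1 = 100))
  sp <- build_eligible_space(g)
  set.seed(99)
  starts <- vapply(1:10000, function(i)
    BiocGenerics::start(place_interval(80, sp)) - 1L, integer(1))
  expect_true(all(starts >= 0 & starts <= 20))
  tab <- table(factor(starts, levels = 0:20))
  expect_gt(chisq.test(tab)$p.value, 0.01)
})

test_that("placement refuses lengths that fit in no segment", {
  g <- toy_genome(list(chr1 = 100, chr2 = 60))
  excl <- df_to_granges(data.frame(chrom = "chr1", start = 50, end = 55), g)
  sp <- build_eligible_space(g, excl)     # segments of 50, 45, 60
  expect_error(place_interval(101, sp), "placement error")
  expect_warning(
    out <- shuffle_intervals(
      df_to_granges(data.frame(chrom = "chr1", start = 0, end = 70), g), sp),
    "dropped")
  expect_length(out, 0L)
  expect_equal(attr(out, "n_dropped"), 1L)
})

test_that("shuffles conserve the length multiset and avoid exclusions", {
  set.seed(202)
  for (rep in 1:100) {
    lens <- list(chrA = sample(2000:6000, 1), chrB = sample(2000:6000, 1))
    g <- toy_genome(lens)
    excl_df <- random_intervals(sample(0:6, 1), lens, max_len = 400)
    excl <- df_to_granges(excl_df, g)
    sp <- build_eligible_space(g, excl)
    peaks <- df_to_granges(random_intervals(sample(5:40, 1), lens,
                                            max_len = 60), g)
    out <- shuffle_intervals(peaks, sp)
    expect_equal(sort(BiocGenerics::width(out)),
                 sort(BiocGenerics::width(peaks)))
    expect_equal(overlap_bp(out, excl), 0)
    expect_equal(attr(out, "n_dropped"), 0L)
  }
})

test_that("shuffling is reproducible from the seed and honours same_chrom", {
  g <- toy_genome(list(chrA = 5000, chrB = 5000))
  sp <- build_eligible_space(g)
  peaks <- df_to_granges(random_intervals(30, list(chrA = 5000, chrB = 5000)),
                         g)
  set.seed(11); s1 <- shuffle_intervals(peaks, sp)
  set.seed(11); s2 <- shuffle_intervals(peaks, sp)
  expect_identical(BiocGenerics::start(s1), BiocGenerics::start(s2))
  set.seed(12)
  s3 <- shuffle_intervals(peaks, sp, same_chrom = TRUE)
  expect_identical(as.character(GenomeInfoDb::seqnames(s3)),
                   as.character(GenomeInfoDb::seqnames(peaks)))
})

test_that("probe density is the covered fraction of the peak", {
  g <- toy_genome(list(chr1 = 1000))
  probes <- df_to_granges(data.frame(chrom = "chr1",
                                     start = c(0, 50), end = c(25, 75)), g)
  peak <- df_to_granges(data.frame(chrom = "chr1", start = 0, end = 100), g)
  expect_equal(probe_density(peak, probes, g), 0.5)
  far <- df_to_granges(data.frame(chrom = "chr1", start = 500, end = 600), g)
  expect_equal(probe_density(far, probes, g), 0)
  tiled <- simulate_probe_map(g, probe_length = 10, spacing = 10)
  expect_equal(probe_density(peak, tiled, g), 1)

  # vectorized, against per-base brute force
  set.seed(31)
  pk <- random_intervals(40, list(chr1 = 1000), max_len = 50)
  pr <- random_intervals(30, list(chr1 = 1000), max_len = 12)
  got <- probe_density(df_to_granges(pk, g), df_to_granges(pr, g), g)
  cov <- base_cover(pr$start, pr$end, 1000)
  want <- vapply(seq_len(nrow(pk)), function(i)
    mean(cov[(pk$start[i] + 1):pk$end[i]]), numeric(1))
  expect_equal(got, want)
})

test_that("probe-matched shuffling reproduces the accept/reject oracle", {
  # probes tile only chr1; peaks sit on chr1, so density ~1 there and 0 on
  # chr2: matching forces relocation onto the tiled chromosome
  g <- toy_genome(list(chr1 = 20000, chr2 = 20000))
  probes <- simulate_probe_map(
    g, probe_length = 25, spacing = 50,
    gap_regions = df_to_granges(data.frame(chrom = "chr2", start = 0,
                                           end = 20000), g))
  sp <- build_eligible_space(g)
  set.seed(5)
  peaks <- df_to_granges(
    data.frame(chrom = "chr1", start = seq(100, 15000, length.out = 25),
               end = seq(100, 15000, length.out = 25) + 200), g)

  set.seed(77)
  got <- shuffle_probe_matched(peaks, sp, probes, probe_tolerance = 0.1,
                               max_attempts = 100)

  # oracle: same sequential stream, densities by per-base brute force
  cov <- c(base_cover(BiocGenerics::start(probes) - 1,
                      BiocGenerics::end(probes), 20000), logical(20000))
  dens <- function(s0, len) mean(cov[(s0 + 1):(s0 + len)])
  off <- c(chr1 = 0, chr2 = 20000)
  d0 <- vapply(seq_along(peaks), function(i)
    dens(off[[as.character(GenomeInfoDb::seqnames(peaks)[i])]] +
           BiocGenerics::start(peaks)[i] - 1,
         BiocGenerics::width(peaks)[i]), numeric(1))
  set.seed(77)
  matched <- logical(length(peaks))
  last_start <- numeric(length(peaks))
  for (i in seq_along(peaks)) {
    for (a in 1:100) {
      iv <- place_interval(BiocGenerics::width(peaks)[i], sp)
      s0 <- off[[as.character(GenomeInfoDb::seqnames(iv))]] +
        BiocGenerics::start(iv) - 1
      last_start[i] <- s0
      if (abs(dens(s0, BiocGenerics::width(peaks)[i]) - d0[i]) <= 0.1) {
        matched[i] <- TRUE
        break
      }
    }
  }
  expect_equal(got$matched_fraction, mean(matched))
  got_lin <- peakperm:::.linearize(got$intervals, g)
  expect_equal(unname(got_lin$s), unname(last_start))
  expect_gte(got$matched_fraction, 0.99)

  # tolerance 1 accepts everything on the first draw
  set.seed(1)
  all_ok <- shuffle_probe_matched(peaks, sp, probes, probe_tolerance = 1)
  expect_equal(all_ok$matched_fraction, 1)
  expect_error(shuffle_probe_matched(peaks, sp, GenomicRanges::GRanges()),
               "non-empty probe map")
})
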