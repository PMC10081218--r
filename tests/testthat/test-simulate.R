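test_that("simulated genomes and exclusions honour their contract", {
  g <- simulate_genome(n_chroms = 3, chrom_length = 1e5,
                       exclusion_fraction = 0.1, seed = 4)
  expect_equal(GenomeInfoDb::seqlevels(g$genome), paste0("chr", 1:3))
  frac <- covered_bp(g$exclusions) / sum(as.numeric(
    GenomeInfoDb::seqlengths(g$genome)))
  expect_lt(abs(frac - 0.1), 0.01)
  # disjoint blocks
  expect_equal(length(merge_intervals(g$exclusions)), length(g$exclusions))

  none <- simulate_genome(n_chroms = 2, chrom_length = 1e4,
                          exclusion_fraction = 0, seed = 4)
  expect_length(none$exclusions, 0L)

  g1 <- simulate_genome(seed = 9)
  g2 <- simulate_genome(seed = 9)
  expect_identical(as.data.frame(g1$exclusions), as.data.frame(g2$exclusions))
  expect_error(simulate_genome(exclusion_fraction = 0.95), "exclusion_fraction")
})

test_that("planted annotation peaks overlap the query as requested", {
  g <- toy_genome(list(chr1 = 2e5, chr2 = 2e5))
  forced <- simulate_peaks(g, n_query = 100, n_annotation = 100, theta = 1,
                           peak_median = 300, seed = 13)
  expect_equal(count_overlapping(forced$annotation, forced$query), 100L)

  none <- simulate_peaks(g, n_query = 100, n_annotation = 100, theta = 0,
                         peak_median = 300, seed = 13)
  expect_false(any(none$planted))

  s1 <- simulate_peaks(g, n_query = 20, n_annotation = 20, theta = 0.5,
                       seed = 3)
  s2 <- simulate_peaks(g, n_query = 20, n_annotation = 20, theta = 0.5,
                       seed = 3)
  expect_identical(as.data.frame(s1$annotation), as.data.frame(s2$annotation))
})

test_that("planted peaks are at least half-contained in a query peak", {
  g <- toy_genome(list(chr1 = 3e5))
  sim <- simulate_peaks(g, n_query = 150, n_annotation = 150, theta = 1,
                        peak_median = 400, peak_sigma = 0.6, seed = 21)
  qm <- merge_intervals(sim$query)
  for (i in seq_along(sim$annotation)) {
    iv <- sim$annotation[i]
    inside <- overlap_bp(iv, qm)
    expect_gte(inside, floor(BiocGenerics::width(iv) / 2))
  }
})

test_that("expected overlap count interpolates between theta and background", {
  g <- toy_genome(list(chr1 = 1e6, chr2 = 1e6))
  n <- 600
  theta <- 0.5
  counts <- numeric(5)
  qfrac <- numeric(5)
  for (r in 1:5) {
    sim <- simulate_peaks(g, n_query = 400, n_annotation = n, theta = theta,
                          peak_median = 300, seed = 500 + r)
    counts[r] <- count_overlapping(sim$annotation, sim$query)
    qfrac[r] <- covered_bp(sim$query) / 2e6
  }
  # background hits occur when an unplanted peak touches the query cover; the
  # touch probability slightly exceeds the covered fraction (edge effects of
  # peak width), so the closed form is a lower bound with a small band
  expected <- theta * n + (1 - theta) * n * mean(qfrac)
  expect_gte(mean(counts), expected - 3 * sqrt(n * 0.25))
  expect_lt(mean(counts), expected + 0.08 * n)
})

test_that("probe maps tile at the requested density and avoid gaps", {
  g <- toy_genome(list(chr1 = 10000, chr2 = 10000))
  full <- simulate_probe_map(g, probe_length = 25, spacing = 25)
  peak <- df_to_granges(data.frame(chrom = "chr1", start = 1000, end = 2000), g)
  expect_equal(probe_density(peak, full, g), 1)

  half <- simulate_probe_map(g, probe_length = 25, spacing = 50)
  expect_equal(probe_density(peak, half, g), 0.5)

  gap <- df_to_granges(data.frame(chrom = "chr2", start = 0, end = 10000), g)
  gapped <- simulate_probe_map(g, probe_length = 25, spacing = 50,
                               gap_regions = gap)
  peak2 <- df_to_granges(data.frame(chrom = "chr2", start = 1000, end = 2000), g)
  expect_equal(probe_density(peak2, gapped, g), 0)
  expect_error(simulate_probe_map(g, probe_length = 50, spacing = 25))
})

test_that("TMT generator plants recoverable fold changes", {
  # generator contract: after removing the recorded channel factors, the
  # planted rows' mean log2 ratio matches log2(fold_change)
  per_seed <- numeric(40)
  for (s in seq_len(40)) {
    sim <- simulate_tmt(n_proteins = 300, n_true_interactors = 6,
                        fold_change = 8, cv = 0.25, seed = 300 + s)
    v <- sweep(sim$matrix$values, 2, sim$channel_factors, `/`)
    lv <- log2(v)
    bait <- sim$matrix$groups == "bait"
    planted <- setdiff(sim$truth, "bait")
    lfc <- rowMeans(lv[planted, bait]) - rowMeans(lv[planted, !bait])
    per_seed[s] <- mean(lfc)
  }
  se <- sd(per_seed) / sqrt(length(per_seed))
  expect_lt(abs(mean(per_seed) - 3), 3 * se)

  s1 <- simulate_tmt(seed = 5)
  s2 <- simulate_tmt(seed = 5)
  expect_identical(s1$matrix$values, s2$matrix$values)
  expect_equal(s1$truth[1], "bait")
})
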