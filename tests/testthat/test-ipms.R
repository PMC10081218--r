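make_mat <- function(values, coiso = NULL, pg = NULL) {
  m <- matrix(values, ncol = 6, byrow = TRUE,
              dimnames = list(paste0("p", seq_len(length(values) / 6)),
                              c("b1", "b2", "b3", "c1", "c2", "c3")))
  abundance_matrix(m, setNames(rep(c("bait", "control"), each = 3),
                               colnames(m)),
                   coisolation = coiso, protein_group = pg)
}

test_that("co-isolation filter excludes strictly above the threshold", {
  x <- make_mat(rep(1, 18), coiso = c(25.0, 25.1, NA))
  f <- filter_coisolation(x, 25)
  expect_equal(rownames(f$values), c("p1", "p3"))   # 25.0 kept, NA kept
  all_out <- filter_coisolation(make_mat(rep(1, 6), coiso = 30), 25)
  expect_equal(nrow(all_out$values), 0L)
  expect_error(ipms_test(make_mat(rep(1, 6), coiso = 30)), "no rows left")
})

test_that("total normalization equalizes channel totals to the grand mean", {
  set.seed(71)
  x <- make_mat(runif(60, 1, 100))
  n <- total_normalize(x)
  totals <- colSums(n$values)
  expect_equal(unname(totals), rep(mean(colSums(x$values)), 6),
               tolerance = 1e-9)
  # worked example: totals [100, 200] -> both 150
  m2 <- abundance_matrix(matrix(c(100, 200), 1), c("bait", "control"))
  expect_equal(unname(colSums(total_normalize(m2)$values)), c(150, 150))
  # idempotence
  expect_equal(total_normalize(n)$values, n$values, tolerance = 1e-12)
  # identity when already equal
  eq <- make_mat(rep(2, 30))
  expect_equal(total_normalize(eq)$values, eq$values)
  zero <- make_mat(c(rep(0, 1), rep(1, 5), rep(0, 1), rep(1, 5)))
  zero$values[, 1] <- 0
  expect_error(total_normalize(zero), "non-positive total")
})

test_that("median normalization equalizes channel medians", {
  set.seed(72)
  for (rep in 1:20) {
    x <- make_mat(rlnorm(6 * 15, 2, 1))
    n <- median_normalize(x)
    meds <- apply(n$values, 2, median)
    expect_equal(unname(meds), rep(median(x$values), 6), tolerance = 1e-9)
  }
  single <- make_mat(c(3, 6, 9, 12, 15, 18))
  out <- median_normalize(total_normalize(single))
  expect_true(all(abs(out$values - out$values[1]) < 1e-9))
})

test_that("peptide aggregation sums members and conserves channel totals", {
  x <- make_mat(c(rep(3, 6), rep(7, 6), rep(5, 6)),
                pg = c("P1", "P1", "P2"))
  agg <- aggregate_to_proteins(x)
  expect_equal(unname(agg$values["P1", ]), rep(10, 6))
  expect_equal(unname(agg$values["P2", ]), rep(5, 6))
  expect_equal(colSums(agg$values), colSums(x$values))
  one <- make_mat(rep(2, 12), pg = c("A", "B"))
  expect_equal(unname(aggregate_to_proteins(one)$values),
               unname(one$values[c("p1", "p2"), ]))
  bad <- make_mat(rep(1, 12), pg = c("A", NA))
  expect_error(aggregate_to_proteins(bad), "unmapped")
})

test_that("two-group t matches the closed form and base conventions", {
  x <- make_mat(c(1, 2, 3, 4, 5, 6))
  res <- two_group_ttest(x, log2_transform = FALSE)
  want <- oracle_pooled_t(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$t, want$t, tolerance = 1e-12)
  expect_equal(res$t, -3.674235, tolerance = 1e-6)
  expect_equal(res$p, want$p, tolerance = 1e-12)
  expect_equal(res$p, 0.0214, tolerance = 1e-2)
  expect_equal(res$p, 2 * pt(-abs(want$t), 4), tolerance = 1e-12)
  expect_false(res$significant)           # enriched calls need log2fc > 0

  ident <- make_mat(rep(c(2, 2, 2), 6)[1:6])
  expect_equal(two_group_ttest(ident)$p, 1)
  expect_equal(two_group_ttest(ident)$t, 0)
  flat_diff <- make_mat(c(8, 8, 8, 2, 2, 2))
  r2 <- two_group_ttest(flat_diff)
  expect_equal(r2$t, Inf)
  expect_gt(r2$p, 0)
  expect_lt(r2$p, 1e-300)

  # label swap flips t, keeps p
  sw <- abundance_matrix(x$values, setNames(rep(c("control", "bait"), each = 3),
                                            colnames(x$values)))
  r3 <- two_group_ttest(sw, log2_transform = FALSE)
  expect_equal(r3$t, -res$t)
  expect_equal(r3$p, res$p)

  # zeros make a row untested on the log scale
  z <- make_mat(c(0, 2, 3, 4, 5, 6))
  expect_false(two_group_ttest(z)$tested)
  expect_true(is.na(two_group_ttest(z)$p))
})

test_that("pipeline recovers planted interactors and controls the background", {
  sig_background <- 0L
  n_background_tests <- 0L
  bait_first <- 0L
  for (s in 1:30) {
    sim <- simulate_tmt(n_proteins = 250, n_true_interactors = 5,
                        fold_change = 8, seed = 100 + s)
    fit <- ipms_test(sim$matrix)
    tab <- as.data.frame(fit)
    bait_first <- bait_first + (tab$protein[1] == "bait")
    planted <- tab$protein %in% sim$truth
    expect_true(all(tab$significant[planted]))
    sig_background <- sig_background + sum(tab$significant[!planted])
    n_background_tests <- n_background_tests + sum(!planted)
  }
  expect_equal(bait_first, 30L)
  expect_lt(sig_background / n_background_tests, 0.05)
})

test_that("huge fold changes dominate the ranking even without noise", {
  sim <- simulate_tmt(n_proteins = 100, n_true_interactors = 3,
                      fold_change = 1e6, bait_fold_change = 4e6,
                      cv = 0, seed = 9)
  fit <- ipms_test(sim$matrix)
  tab <- as.data.frame(fit)
  expect_setequal(tab$protein[1:3], sim$truth)
  # cv = 0: planted rows sit at the minimal representable p. Background rows
  # can tie (under zero noise the normalizations leave them at a constant
  # negative offset, hence -Inf t), but they rank below on |log2fc| and are
  # never called enriched
  expect_true(all(tab$p[1:3] == min(tab$p)))
  expect_true(all(tab$log2fc[1:3] > 0))
  expect_false(any(tab$significant[-(1:3)]))
})

test_that("the TSV reader and run_ipms reproduce an in-memory analysis", {
  sim <- simulate_tmt(n_proteins = 120, n_true_interactors = 4, seed = 77)
  d <- withr::local_tempdir()
  tsv <- file.path(d, "tmt.tsv")
  write.table(data.frame(id = rownames(sim$matrix$values),
                         sim$matrix$values, check.names = FALSE),
              tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  groups <- setNames(sim$matrix$groups, colnames(sim$matrix$values))
  out <- file.path(d, "res.tsv")
  fit <- run_ipms(tsv, out, groups = groups)
  expect_identical(as.data.frame(fit)$protein,
                   as.data.frame(ipms_test(sim$matrix))$protein)
  expect_true(file.exists(out))
  expect_true(file.exists(paste0(out, ".manifest.json")))
  expect_error(run_ipms(tsv, out), "group labels")
})
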