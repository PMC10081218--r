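#' Empirical permutation p-value
#'
#' Rank-based p-value of the observed overlap against the permutation null,
#' with the add-one estimator: for the enriched tail
#' `p = (1 + #\{null >= observed\}) / (N + 1)`, for the depleted tail
#' `p = (1 + #\{null <= observed\}) / (N + 1)`. Ties count toward the
#' extreme; the smallest attainable value is `1/(N+1)`, never 0.
#'
#' @param observed Observed overlap statistic (bp).
#' @param null_values Numeric vector of permuted overlap statistics.
#' @param direction `"enriched"` (upper tail) or `"depleted"` (lower tail).
#' @return The empirical p-value in `[1/(N+1), 1]`.
#' @export
empirical_pvalue <- function(observed, null_values,
                             direction = c("enriched", "depleted")) {
  direction <- match.arg(direction)
  if (length(null_values) == 0L)
    stop("empirical_pvalue: empty null distribution")
  k <- if (direction == "enriched") sum(null_values >= observed)
       else sum(null_values <= observed)
  (1 + k) / (length(null_values) + 1)
}

#' Log2 enrichment of observed over expected overlap
#'
#' `log2(observed / expected)` where the expected overlap is the mean (or
#' median) of the null distribution. A 1 bp pseudocount is applied to both
#' terms only when either is zero, so `observed = expected = 0` gives 0.
#'
#' @inheritParams empirical_pvalue
#' @param expected_stat Summary of the null used as the expectation:
#'   `"mean"` (default) or `"median"`.
#' @return A list with `log2fc`, `expected` and `direction` (`"enriched"` if
#'   observed > expected, else `"depleted"`; a tie is enriched with
#'   `log2fc = 0`).
#' @export
log2_enrichment <- function(observed, null_values,
                            expected_stat = c("mean", "median")) {
  expected_stat <- match.arg(expected_stat)
  if (length(null_values) == 0L)
    stop("log2_enrichment: empty null distribution")
  expected <- if (expected_stat == "mean") mean(null_values)
              else median(null_values)
  eps <- if (observed == 0 || expected == 0) 1 else 0
  log2fc <- log2((observed + eps) / (expected + eps))
  list(log2fc = log2fc,
       expected = expected,
       direction = if (observed >= expected) "enriched" else "depleted")
}

#' Permutation enrichment test of annotations at a query peak set
#'
#' For each annotation peak set, builds the length-matched random-placement
#' null ([build_null()]), and reports observed and expected base-pair
#' overlap with the query set, signed log2 enrichment, the empirical
#' p-values of both tails, the smaller-tail p as the headline `p_empirical`,
#' and Benjamini-Hochberg q-values computed across all annotations in the
#' call (one multiple-testing family per invocation).
#'
#' @param query `GRanges`: the fixed query peak set (e.g. the binding sites
#'   of the factor under study).
#' @param annotations Named list of `GRanges` annotation peak sets, or a
#'   single `GRanges`.
#' @param genome A `Seqinfo` (see [read_chrom_sizes()]).
#' @param exclusions Optional blacklist/gap `GRanges` removed from the
#'   placement space.
#' @param probes Optional probe maps for ChIP-chip annotations: a single
#'   `GRanges` applied to every annotation, or a named list with entries for
#'   the annotations needing probe matching (`NULL` entries mean none).
#' @param n_permutations Permutations per annotation (default 1000).
#' @param seed Master seed; annotation-level seeds are derived from it.
#' @param expected_stat `"mean"` (default) or `"median"` null summary.
#' @param keep_null Keep the per-annotation `null_distribution` objects in
#'   the result (default `TRUE`).
#' @inheritParams build_null
#' @return An object of class `peak_enrichment`: a result table (see
#'   [as.data.frame.peak_enrichment()]) sorted by q, then |log2fc|
#'   descending, then annotation label, plus the null distributions.
#' @examples
#' genome <- GenomeInfoDb::Seqinfo(c("chr1", "chr2"), c(100000, 80000))
#' sim <- simulate_peaks(genome, n_query = 50, n_annotation = 50,
#'                       theta = 0.9, peak_median = 300, seed = 7)
#' fit <- enrichment_test(sim$query, list(mark = sim$annotation), genome,
#'                        n_permutations = 100, seed = 7)
#' fit
#' @export
enrichment_test <- function(query, annotations, genome, exclusions = NULL,
                            probes = NULL, n_permutations = 1000L, seed = 1L,
                            probe_tolerance = 0.1, max_attempts = 100L,
                            required_match_fraction = 0.99,
                            same_chrom = FALSE,
                            expected_stat = c("mean", "median"),
                            keep_null = TRUE) {
  expected_stat <- match.arg(expected_stat)
  if (is(annotations, "GRanges")) annotations <- list(annotation = annotations)
  if (length(annotations) == 0L) stop("at least one annotation set is required")
  if (is.null(names(annotations)) || any(!nzchar(names(annotations))))
    names(annotations) <- paste0("annotation", seq_along(annotations))
  if (length(query) == 0L) stop("query peak set is empty")
  for (nm in names(annotations))
    if (length(annotations[[nm]]) == 0L)
      stop("annotation set '", nm, "' is empty")
  space <- build_eligible_space(genome, exclusions)

  probe_for <- function(nm) {
    if (is.null(probes)) return(NULL)
    if (is(probes, "GRanges")) return(probes)
    probes[[nm]]
  }
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  ann_seeds <- sample.int(2147483646L, length(annotations))

  nulls <- vector("list", length(annotations))
  names(nulls) <- names(annotations)
  rows <- vector("list", length(annotations))
  for (j in seq_along(annotations)) {
    nm <- names(annotations)[j]
    nd <- build_null(query, annotations[[nm]], space,
                     probes = probe_for(nm),
                     n_permutations = n_permutations, seed = ann_seeds[j],
                     probe_tolerance = probe_tolerance,
                     max_attempts = max_attempts,
                     required_match_fraction = required_match_fraction,
                     same_chrom = same_chrom)
    le <- log2_enrichment(nd$observed, nd$null_values, expected_stat)
    p_enr <- empirical_pvalue(nd$observed, nd$null_values, "enriched")
    p_dep <- empirical_pvalue(nd$observed, nd$null_values, "depleted")
    rows[[j]] <- data.frame(
      annotation = nm,
      observed_bp = nd$observed,
      expected_bp = le$expected,
      log2fc = le$log2fc,
      direction = if (p_enr <= p_dep) "enriched" else "depleted",
      p_enriched = p_enr,
      p_depleted = p_dep,
      p_empirical = min(p_enr, p_dep),
      n_perm = n_permutations,
      matched_fraction_min = min(nd$matched_fractions),
      stringsAsFactors = FALSE)
    if (keep_null) nulls[[j]] <- nd
  }
  tab <- do.call(rbind, rows)
  tab$q_bh <- p.adjust(tab$p_empirical, method = "BH")
  ord <- order(tab$q_bh, -abs(tab$log2fc), tab$annotation)
  tab <- tab[ord, c("annotation", "observed_bp", "expected_bp", "log2fc",
                    "direction", "p_enriched", "p_depleted", "p_empirical",
                    "q_bh", "n_perm", "matched_fraction_min")]
  rownames(tab) <- NULL
  structure(list(results = tab,
                 nulls = if (keep_null) nulls else NULL,
                 genome = genome,
                 n_permutations = n_permutations,
                 seed = seed,
                 expected_stat = expected_stat),
            class = "peak_enrichment")
}

#' @export
print.peak_enrichment <- function(x, digits = 3, ...) {
  cat("Permutation enrichment test (", x$n_permutations,
      " permutations per annotation, seed ", x$seed, ")\n\n", sep = "")
  tab <- x$results
  show <- data.frame(annotation = tab$annotation,
                     observed_bp = tab$observed_bp,
                     expected_bp = round(tab$expected_bp, 1),
                     log2fc = signif(tab$log2fc, digits),
                     direction = tab$direction,
                     p = signif(tab$p_empirical, digits),
                     q = signif(tab$q_bh, digits))
  print(show, row.names = FALSE)
  invisible(x)
}

#' @export
summary.peak_enrichment <- function(object, fdr = 0.05, ...) {
  tab <- object$results
  sig <- tab$q_bh < fdr
  cat("Annotations tested: ", nrow(tab), "\n", sep = "")
  cat("Significant at FDR < ", fdr, ": ", sum(sig),
      " (", sum(sig & tab$direction == "enriched"), " enriched, ",
      sum(sig & tab$direction == "depleted"), " depleted)\n", sep = "")
  if (any(sig)) {
    cat("\nSignificant annotations:\n")
    print(data.frame(annotation = tab$annotation[sig],
                     log2fc = signif(tab$log2fc[sig], 3),
                     direction = tab$direction[sig],
                     q = signif(tab$q_bh[sig], 3)), row.names = FALSE)
  }
  invisible(object)
}

#' Result table of a peak enrichment test
#'
#' @param x A `peak_enrichment` object.
#' @param row.names,optional,... Ignored (base-generic signature).
#' @return The full-precision result `data.frame`, one row per annotation,
#'   sorted by q then |log2fc| descending.
#' @export
as.data.frame.peak_enrichment <- function(x, row.names = NULL,
                                          optional = FALSE, ...) {
  x$results
}

#' Barplot of signed log2 enrichment per annotation
#'
#' @param x A `peak_enrichment` object.
#' @param fdr Significance threshold marked with an asterisk (default 0.05).
#' @param ... Passed to [graphics::barplot()].
#' @export
plot.peak_enrichment <- function(x, fdr = 0.05, ...) {
  tab <- x$results[order(x$results$log2fc), ]
  cols <- ifelse(tab$direction == "enriched", "firebrick", "steelblue")
  bp <- barplot(tab$log2fc, names.arg = tab$annotation, horiz = TRUE,
                col = cols, las = 1, xlab = "log2(observed / expected)", ...)
  abline(v = 0)
  sig <- tab$q_bh < fdr
  if (any(sig))
    text(tab$log2fc[sig], bp[sig], "*", pos = ifelse(tab$log2fc[sig] >= 0, 4, 2),
         xpd = NA)
  invisible(x)
}

#' Write an enrichment result table as TSV
#'
#' Machine-readable companion to [print.peak_enrichment()]: full precision,
#' one row per annotation, stable column order.
#'
#' @param x A `peak_enrichment` object.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_enrichment_tsv <- function(x, path) {
  write.table(x$results, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
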