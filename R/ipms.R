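#' Construct a TMT abundance matrix
#'
#' Container for multiplexed IP-MS quantification: a peptide- or
#' protein-level abundance matrix with channel group labels (bait-IP vs
#' control-IP) and optional per-peptide co-isolation interference and
#' peptide-to-protein-group mapping.
#'
#' @param values Numeric matrix, rows = peptides or proteins (unique
#'   rownames), columns = TMT channels; non-negative.
#' @param groups Character/factor vector, one entry per channel, with values
#'   `"bait"` or `"control"`. Named vectors are matched to column names.
#' @param coisolation Optional numeric vector (percent, one per row) of
#'   co-isolation interference; `NA` allowed.
#' @param protein_group Optional character vector (one per row) mapping each
#'   peptide to its protein group.
#' @return An object of class `abundance_matrix`.
#' @export
abundance_matrix <- function(values, groups, coisolation = NULL,
                             protein_group = NULL) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) && nrow(values) > 0L)
    rownames(values) <- paste0("row", seq_len(nrow(values)))
  if (anyDuplicated(rownames(values)))
    stop("row identifiers must be unique")
  if (any(values < 0, na.rm = TRUE)) stop("abundances must be non-negative")
  if (!is.null(names(groups)) && !is.null(colnames(values)))
    groups <- groups[colnames(values)]
  groups <- as.character(groups)
  if (length(groups) != ncol(values))
    stop("one group label per channel is required")
  if (!all(groups %in% c("bait", "control")))
    stop("group labels must be 'bait' or 'control'")
  if (!is.null(coisolation) && length(coisolation) != nrow(values))
    stop("coisolation must have one value per row")
  if (!is.null(protein_group) && length(protein_group) != nrow(values))
    stop("protein_group must have one value per row")
  structure(list(values = values, groups = groups,
                 coisolation = coisolation, protein_group = protein_group),
            class = "abundance_matrix")
}

#' @export
print.abundance_matrix <- function(x, ...) {
  cat("TMT abundance matrix: ", nrow(x$values), " rows x ", ncol(x$values),
      " channels (", sum(x$groups == "bait"), " bait, ",
      sum(x$groups == "control"), " control)\n", sep = "")
  if (!is.null(x$coisolation)) cat("  with co-isolation interference values\n")
  if (!is.null(x$protein_group))
    cat("  peptide level, ", length(unique(x$protein_group)),
        " protein group(s)\n", sep = "")
  invisible(x)
}

#' Read a TMT abundance table from TSV
#'
#' Expects columns `id`, optional `protein_group`, optional
#' `coisolation_pct`, and one numeric column per channel.
#'
#' @param path Input TSV path.
#' @param groups Named character vector mapping channel column names to
#'   `"bait"`/`"control"`; channels absent from `groups` are dropped.
#' @return An `abundance_matrix`.
#' @export
read_abundance_tsv <- function(path, groups) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                   check.names = FALSE)
  if (!"id" %in% names(df)) stop("input table needs an 'id' column")
  chan <- intersect(names(groups), names(df))
  if (length(chan) < 2L)
    stop("fewer than two of the labelled channels found in '", path, "'")
  vals <- as.matrix(df[, chan, drop = FALSE])
  rownames(vals) <- df$id
  abundance_matrix(vals, groups[chan],
                   coisolation = if ("coisolation_pct" %in% names(df))
                     df$coisolation_pct else NULL,
                   protein_group = if ("protein_group" %in% names(df))
                     df$protein_group else NULL)
}

#' Drop peptides with high co-isolation interference
#'
#' Removes rows whose co-isolation interference exceeds the threshold
#' (strictly greater; a row at exactly the threshold is retained). Rows
#' without an interference value are retained.
#'
#' @param x An `abundance_matrix`.
#' @param threshold Percent interference above which a peptide is excluded
#'   (default 25).
#' @return The filtered `abundance_matrix`.
#' @export
filter_coisolation <- function(x, threshold = 25) {
  stopifnot(is(x, "abundance_matrix"))
  if (is.null(x$coisolation)) return(x)
  keep <- is.na(x$coisolation) | x$coisolation <= threshold
  abundance_matrix(x$values[keep, , drop = FALSE], x$groups,
                   coisolation = x$coisolation[keep],
                   protein_group = x$protein_group[keep])
}

#' Equalize total abundance per channel
#'
#' Scales every channel so that all channel totals equal the grand mean of
#' the original totals, removing channel-level loading/labelling differences
#' while preserving within-channel structure.
#'
#' @param x An `abundance_matrix` with positive channel totals.
#' @return The normalized `abundance_matrix`.
#' @export
total_normalize <- function(x) {
  stopifnot(is(x, "abundance_matrix"))
  totals <- colSums(x$values, na.rm = TRUE)
  if (any(totals <= 0))
    stop("channel(s) with non-positive total abundance: ",
         paste(colnames(x$values)[totals <= 0], collapse = ", "))
  target <- mean(totals)
  x$values <- sweep(x$values, 2L, target / totals, `*`)
  x
}

#' Equalize median abundance per channel
#'
#' Divides every channel by its median and multiplies by the grand median
#' (median of all values before normalization), so per-channel medians
#' equalize.
#'
#' @param x An `abundance_matrix` whose channels all have a positive median.
#' @return The normalized `abundance_matrix`.
#' @export
median_normalize <- function(x) {
  stopifnot(is(x, "abundance_matrix"))
  meds <- apply(x$values, 2L, median, na.rm = TRUE)
  if (any(meds <= 0))
    stop("channel(s) with non-positive median abundance: ",
         paste(colnames(x$values)[meds <= 0], collapse = ", "))
  grand <- median(x$values, na.rm = TRUE)
  x$values <- sweep(x$values, 2L, grand / meds, `*`)
  x
}

#' Aggregate peptide abundances to protein groups
#'
#' Sums member-peptide abundances per protein group and channel. Every
#' retained peptide must be mapped.
#'
#' @param x A peptide-level `abundance_matrix`.
#' @param mapping Optional character vector (peptide -> protein group)
#'   overriding `x$protein_group`.
#' @return A protein-level `abundance_matrix`.
#' @export
aggregate_to_proteins <- function(x, mapping = NULL) {
  stopifnot(is(x, "abundance_matrix"))
  if (is.null(mapping)) mapping <- x$protein_group
  if (is.null(mapping))
    stop("no peptide-to-protein mapping available")
  unmapped <- is.na(mapping) | !nzchar(mapping)
  if (any(unmapped))
    stop("unmapped peptide(s): ",
         paste(utils::head(rownames(x$values)[unmapped], 5), collapse = ", "))
  agg <- rowsum(x$values, group = mapping)
  abundance_matrix(agg, x$groups)
}

#' Per-row two-group Student t-tests
#'
#' Pooled-variance two-sided Student t-test of bait vs control channels for
#' every row, on log2-transformed abundances by default. A row is tested
#' only when observed (finite) in every channel; untested rows get `NA`
#' statistics. Degenerate rows whose pooled standard error is numerically
#' zero give `p = 1` when the group means are equal and the smallest
#' representable positive p when they differ.
#'
#' @param x An `abundance_matrix` with >= 2 channels per group.
#' @param log2_transform Test on the log2 scale (default `TRUE`); zeros make
#'   a row untested on the log scale.
#' @param alpha Significance threshold for the `significant` call
#'   (default 0.05).
#' @return `data.frame` with columns `protein`, `log2fc`
#'   (mean bait - mean control, log2 scale), `t`, `p`, `q_info` (BH across
#'   tested rows, informational only), `significant` (`p < alpha` and
#'   `log2fc > 0`), `tested`.
#' @export
two_group_ttest <- function(x, log2_transform = TRUE, alpha = 0.05) {
  stopifnot(is(x, "abundance_matrix"))
  bait <- x$groups == "bait"
  ctrl <- x$groups == "control"
  if (sum(bait) < 2L || sum(ctrl) < 2L)
    stop("at least two channels per group are required")
  v <- x$values
  if (log2_transform) v <- log2(v)
  tested <- apply(is.finite(v), 1L, all)
  n <- nrow(v)
  t_stat <- p <- lfc <- rep(NA_real_, n)
  for (i in which(tested)) {
    xb <- v[i, bait]; xc <- v[i, ctrl]
    lfc[i] <- if (log2_transform) mean(xb) - mean(xc)
              else log2(mean(xb) / mean(xc))
    mb <- mean(xb); mc <- mean(xc)
    s2 <- (sum((xb - mb)^2) + sum((xc - mc)^2)) /
      (length(xb) + length(xc) - 2L)
    se <- sqrt(s2 * (1 / length(xb) + 1 / length(xc)))
    # same degeneracy criterion as stats::t.test, handled instead of erroring
    if (se < 10 * .Machine$double.eps * max(abs(mb), abs(mc))) {
      # means within sqrt(eps) relative are equal: normalization round-off
      # leaves ulp-scale differences on genuinely constant rows
      if (abs(mb - mc) <=
            sqrt(.Machine$double.eps) * max(abs(mb), abs(mc))) {
        t_stat[i] <- 0; p[i] <- 1
      } else {
        t_stat[i] <- sign(mb - mc) * Inf
        p[i] <- .Machine$double.xmin
      }
    } else {
      tt <- t.test(xb, xc, var.equal = TRUE)
      t_stat[i] <- unname(tt$statistic)
      p[i] <- tt$p.value
    }
  }
  q <- rep(NA_real_, n)
  q[tested] <- p.adjust(p[tested], method = "BH")
  data.frame(protein = rownames(v),
             log2fc = lfc, t = t_stat, p = p, q_info = q,
             significant = tested & !is.na(p) & p < alpha & lfc > 0,
             tested = tested,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Differential-enrichment analysis of a TMT IP-MS experiment
#'
#' Runs the full bait-interactor pipeline in its fixed order: co-isolation
#' filtering ([filter_coisolation()]), total-abundance normalization
#' ([total_normalize()]), aggregation of peptides to protein groups when a
#' mapping is present ([aggregate_to_proteins()]), median normalization
#' ([median_normalize()]), then per-protein Student t-tests of bait vs
#' control channels ([two_group_ttest()]). Proteins with `p < alpha` and
#' positive bait log2 fold change are called enriched; no multiple-testing
#' correction is applied to the call (a BH column is reported for
#' information).
#'
#' @inheritParams two_group_ttest
#' @param coisolation_threshold Percent interference above which peptides
#'   are excluded (default 25).
#' @return An object of class `ipms_fit` with the result table (sorted by p)
#'   and the normalized matrix.
#' @examples
#' sim <- simulate_tmt(n_proteins = 200, n_true_interactors = 4,
#'                     fold_change = 8, seed = 11)
#' fit <- ipms_test(sim$matrix)
#' head(as.data.frame(fit))
#' @export
ipms_test <- function(x, coisolation_threshold = 25, log2_transform = TRUE,
                      alpha = 0.05) {
  stopifnot(is(x, "abundance_matrix"))
  x <- filter_coisolation(x, coisolation_threshold)
  if (nrow(x$values) == 0L)
    stop("no rows left after co-isolation filtering")
  x <- total_normalize(x)
  if (!is.null(x$protein_group)) x <- aggregate_to_proteins(x)
  x <- median_normalize(x)
  tab <- two_group_ttest(x, log2_transform = log2_transform, alpha = alpha)
  tab <- tab[order(tab$p, -abs(tab$log2fc), tab$protein), ]
  rownames(tab) <- NULL
  structure(list(results = tab, matrix = x, alpha = alpha,
                 log2_transform = log2_transform),
            class = "ipms_fit")
}

#' @export
print.ipms_fit <- function(x, n = 10, ...) {
  tab <- x$results
  cat("IP-MS differential enrichment: ", nrow(tab), " proteins (",
      sum(tab$tested), " tested), ", sum(tab$significant),
      " enriched at p < ", x$alpha, "\n\n", sep = "")
  top <- utils::head(tab[tab$tested, ], n)
  print(data.frame(protein = top$protein, log2fc = signif(top$log2fc, 3),
                   t = signif(top$t, 4), p = signif(top$p, 3),
                   significant = top$significant), row.names = FALSE)
  invisible(x)
}

#' @export
summary.ipms_fit <- function(object, ...) {
  tab <- object$results
  cat("Proteins: ", nrow(tab), "; tested in all channels: ", sum(tab$tested),
      "; enriched (p < ", object$alpha, ", log2fc > 0): ",
      sum(tab$significant), "\n", sep = "")
  invisible(object)
}

#' @export
as.data.frame.ipms_fit <- function(x, row.names = NULL, optional = FALSE,
                                   ...) {
  x$results
}

#' Volcano plot of an IP-MS fit
#'
#' @param x An `ipms_fit`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.ipms_fit <- function(x, ...) {
  tab <- x$results[x$results$tested, ]
  cols <- ifelse(tab$significant, "dodgerblue3", "grey60")
  graphics::plot(tab$log2fc, -log10(tab$p), col = cols, pch = 16,
                 xlab = "log2 fold change (bait / control)",
                 ylab = "-log10 p", ...)
  abline(h = -log10(x$alpha), lty = 2)
  abline(v = 0, lty = 3)
  invisible(x)
}
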