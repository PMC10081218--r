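#' Permutation null distribution of base-pair overlap
#'
#' Core of the co-localization test. The query peak set stays fixed; the
#' annotation set is relocated `n_permutations` times by length-matched
#' random placement in eligible space ([shuffle_intervals()]), with optional
#' probe-density matching for ChIP-chip annotations
#' ([shuffle_probe_matched()]). Each permutation records the base-pair
#' overlap between the query and the shuffled annotation, giving the null
#' distribution against which the observed overlap is judged.
#'
#' Reproducibility: one master `seed` yields per-permutation seeds, so each
#' permutation is independent of execution order and the whole object is
#' bit-identical across runs. When probe matching is requested and a
#' permutation matches fewer than `required_match_fraction` of its peaks, it
#' is regenerated (continuing the same random stream) up to 10 times and the
#' best-matched attempt is kept; such permutations are counted in
#' `n_flagged`.
#'
#' @param query `GRanges`: the fixed query peak set.
#' @param annotation `GRanges`: the annotation peak set to be shuffled.
#' @param space An `eligible_space` from [build_eligible_space()].
#' @param probes Optional `GRanges` probe map; when given, shuffles are
#'   probe-density matched.
#' @param n_permutations Number of permutations (default 1000).
#' @param seed Master random seed (integer).
#' @param probe_tolerance,max_attempts See [shuffle_probe_matched()].
#' @param required_match_fraction Minimum acceptable matched fraction per
#'   permutation before it is flagged and regenerated (default 0.99).
#' @param same_chrom Restrict placement to the chromosome of origin.
#' @return An object of class `null_distribution` with elements `observed`,
#'   `null_values` (length `n_permutations`), `matched_fractions` (all 1 when
#'   no probe constraint), `n_dropped`, `n_flagged`, and a `config` echo.
#' @export
build_null <- function(query, annotation, space, probes = NULL,
                       n_permutations = 1000L, seed = 1L,
                       probe_tolerance = 0.1, max_attempts = 100L,
                       required_match_fraction = 0.99,
                       same_chrom = FALSE) {
  stopifnot(n_permutations >= 1L)
  genome <- space$genome
  q_lin <- .linearize(reduce(query, ignore.strand = TRUE), genome)
  a_lin <- .linearize(annotation, genome)
  lens <- a_lin$e - a_lin$s
  observed <- .overlap_lin(q_lin, .merge_lin(a_lin$s, a_lin$e))

  probe_idx <- if (!is.null(probes)) .probe_index(probes, genome) else NULL
  d0 <- if (!is.null(probes))
    .probe_cov(probe_idx, a_lin$s, a_lin$e) / pmax(lens, 1) else NULL
  pk_chrom <- if (same_chrom) as.character(seqnames(annotation)) else NULL

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  perm_seeds <- sample.int(2147483646L, n_permutations)

  null_values <- numeric(n_permutations)
  matched <- rep(1, n_permutations)
  n_dropped <- 0L
  n_flagged <- 0L
  for (i in seq_len(n_permutations)) {
    set.seed(perm_seeds[i])
    if (is.null(probes)) {
      s <- .shuffle_lin_fast(lens, space, pk_chrom)
    } else {
      best <- .shuffle_probe_lin(lens, d0, space, probe_idx, probe_tolerance,
                                 max_attempts, pk_chrom)
      if (best$matched_fraction < required_match_fraction) {
        n_flagged <- n_flagged + 1L
        for (retry in seq_len(10L)) {
          cand <- .shuffle_probe_lin(lens, d0, space, probe_idx,
                                     probe_tolerance, max_attempts, pk_chrom)
          if (cand$matched_fraction > best$matched_fraction) best <- cand
          if (best$matched_fraction >= required_match_fraction) break
        }
        if (best$matched_fraction < required_match_fraction)
          message("permutation ", i, ": matched fraction ",
                  signif(best$matched_fraction, 3),
                  " below required ", required_match_fraction,
                  " after regeneration; proceeding with best attempt")
      }
      s <- best$s
      matched[i] <- best$matched_fraction
    }
    keep <- !is.na(s)
    n_dropped <- n_dropped + sum(!keep)
    null_values[i] <- .overlap_lin(q_lin,
                                   .merge_lin(s[keep], s[keep] + lens[keep]))
  }
  structure(list(observed = observed,
                 null_values = null_values,
                 matched_fractions = matched,
                 n_permutations = n_permutations,
                 n_dropped = n_dropped,
                 n_flagged = n_flagged,
                 config = list(seed = seed,
                               probe_tolerance = probe_tolerance,
                               max_attempts = max_attempts,
                               required_match_fraction = required_match_fraction,
                               probe_matched = !is.null(probes),
                               same_chrom = same_chrom)),
            class = "null_distribution")
}

# genome-wide (or same-chromosome) vectorized length-matched placement on the
# line; NA for unplaceable lengths
.shuffle_lin_fast <- function(lens, space, pk_chrom = NULL) {
  if (is.null(pk_chrom)) return(.place_lin(lens, space))
  s <- rep(NA_real_, length(lens))
  for (ch in unique(pk_chrom)) {
    pk <- which(pk_chrom == ch)
    sg <- which(space$seg_chrom == ch)
    if (length(sg)) s[pk] <- .place_lin(lens[pk], space, seg_idx = sg)
  }
  s
}

# per-peak sequential accept/reject on probe density (linear coordinates);
# mirrors shuffle_probe_matched() but avoids GRanges in the permutation loop
.shuffle_probe_lin <- function(lens, d0, space, probe_idx, tol, max_attempts,
                               pk_chrom = NULL) {
  n <- length(lens)
  out_s <- rep(NA_real_, n)
  ok <- logical(n)
  for (i in seq_len(n)) {
    sg <- if (!is.null(pk_chrom)) which(space$seg_chrom == pk_chrom[i]) else NULL
    for (a in seq_len(max_attempts)) {
      s <- .place_lin(lens[i], space, seg_idx = sg)
      if (is.na(s)) break
      out_s[i] <- s
      d <- .probe_cov(probe_idx, s, s + lens[i]) / lens[i]
      if (abs(d - d0[i]) <= tol) { ok[i] <- TRUE; break }
    }
  }
  placed <- !is.na(out_s)
  list(s = out_s,
       matched_fraction = if (any(placed)) mean(ok[placed]) else NA_real_)
}

#' @export
print.null_distribution <- function(x, ...) {
  cat("Permutation null distribution (", x$n_permutations, " permutations)\n",
      sep = "")
  cat("  observed overlap: ", format(x$observed, big.mark = ","), " bp\n",
      sep = "")
  cat("  null overlap:     mean ",
      format(round(mean(x$null_values), 1), big.mark = ","), " bp, range [",
      format(min(x$null_values), big.mark = ","), ", ",
      format(max(x$null_values), big.mark = ","), "]\n", sep = "")
  if (x$config$probe_matched)
    cat("  probe matching:   min matched fraction ",
        signif(min(x$matched_fractions), 4),
        " (", x$n_flagged, " flagged permutation(s))\n", sep = "")
  if (x$n_dropped > 0L)
    cat("  dropped placements:", x$n_dropped, "\n")
  invisible(x)
}
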