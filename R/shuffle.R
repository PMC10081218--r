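#' Build the eligible placement space
#'
#' The random-placement null relocates peaks anywhere in the genome except
#' blacklisted or assembly-gap regions. This computes the complement of the
#' (merged) exclusions as a set of contiguous placeable segments, with an
#' index for uniform sampling of start positions.
#'
#' @param genome A `Seqinfo` (see [read_chrom_sizes()]).
#' @param exclusions Optional `GRanges` of regions no shuffled peak may touch
#'   (blacklist, gaps). `NULL` or empty means the whole genome is eligible.
#' @return An object of class `eligible_space`.
#' @export
build_eligible_space <- function(genome, exclusions = NULL) {
  whole <- GRanges(seqlevels(genome),
                   IRanges(1, as.numeric(seqlengths(genome))),
                   seqinfo = genome)
  if (is.null(exclusions) || length(exclusions) == 0L) {
    segs <- whole
  } else {
    segs <- GenomicRanges::setdiff(whole, reduce(exclusions, ignore.strand = TRUE),
                                   ignore.strand = TRUE)
  }
  total <- sum(as.numeric(width(segs)))
  if (total <= 0)
    stop("eligible space is empty: exclusions cover the entire genome")
  lin <- .linearize(segs, genome)
  structure(list(genome = genome,
                 segments = segs,
                 seg_chrom = as.character(seqnames(segs)),
                 lin_s = lin$s, lin_e = lin$e,
                 seg_width = lin$e - lin$s,
                 total = total),
            class = "eligible_space")
}

#' @export
print.eligible_space <- function(x, ...) {
  cat("Eligible placement space:", length(x$lin_s), "segment(s),",
      format(x$total, big.mark = ","), "bp eligible of",
      format(sum(as.numeric(seqlengths(x$genome))), big.mark = ","),
      "bp genome\n")
  invisible(x)
}

# Linear start positions for intervals of the given lengths, drawn uniformly
# over every position (across all segments/chromosomes) where the interval
# fits entirely inside one eligible segment. Lengths that fit nowhere yield
# NA (callers decide whether to drop or error). `seg_idx` optionally
# restricts to a subset of segments (same-chromosome policy).
#
# Sampling is by rejection: a position uniform over all eligible bases is
# uniform over valid starts once draws whose interval does not fit entirely
# inside its segment are rejected, and with peaks much shorter than segments
# almost every draw is accepted. A handful of vectorized redraw rounds
# resolves stragglers; the exhaustive per-segment enumeration is the
# fallback for pathological length/segment combinations.
.place_lin <- function(lengths, space, seg_idx = NULL) {
  w <- if (is.null(seg_idx)) space$seg_width else space$seg_width[seg_idx]
  s0 <- if (is.null(seg_idx)) space$lin_s else space$lin_s[seg_idx]
  n <- length(lengths)
  if (n == 0L) return(numeric(0))
  out <- rep(NA_real_, n)
  placeable <- lengths <= max(w)
  cum <- cumsum(w)
  total <- cum[length(cum)]
  todo <- which(placeable)
  for (round in seq_len(50L)) {
    if (length(todo) == 0L) break
    u <- floor(runif(length(todo)) * total)
    seg <- findInterval(u, cum) + 1L
    pos <- s0[seg] + (u - c(0, cum)[seg])
    fits <- pos + lengths[todo] <= s0[seg] + w[seg]
    out[todo[fits]] <- pos[fits]
    todo <- todo[!fits]
  }
  # exact enumeration for anything still unplaced after 50 rounds
  for (i in todo) {
    valid <- pmax(w - lengths[i] + 1, 0)
    tv <- sum(valid)
    if (tv <= 0) next                    # cannot happen given placeable
    r <- floor(runif(1) * tv)
    cv <- cumsum(valid)
    sg <- findInterval(r, cv) + 1L
    out[i] <- s0[sg] + (r - c(0, cv)[sg])
  }
  out
}

#' Place one interval uniformly in eligible space
#'
#' Draws a start position uniformly over all genome positions at which an
#' interval of the requested length fits entirely within one eligible
#' segment, so it has zero overlap with the exclusions. The number of
#' uniform deviates consumed is itself a deterministic function of the draws,
#' so results are reproducible from the seed.
#'
#' @param length Interval length in bp.
#' @param space An `eligible_space` from [build_eligible_space()].
#' @return A length-1 `GRanges`.
#' @export
place_interval <- function(length, space) {
  stopifnot(length >= 1)
  s <- .place_lin(length, space)
  if (is.na(s))
    stop("placement error: no eligible segment can host an interval of ",
         length, " bp")
  .delinearize(s, s + length, space$genome)
}

#' Length-matched shuffle of a peak set
#'
#' Produces one random relocation of `peaks`: every output interval has the
#' length of an input interval (the length multiset is conserved), lies
#' entirely within eligible space, and its start is uniform over all valid
#' positions. Shuffled intervals may overlap one another. Peaks too long for
#' any eligible segment are dropped with a warning and counted in the
#' `n_dropped` attribute.
#'
#' @param peaks `GRanges` to relocate.
#' @param space An `eligible_space`.
#' @param same_chrom If `TRUE`, each peak is relocated only within its
#'   chromosome of origin; default is genome-wide placement.
#' @return A `GRanges` of shuffled intervals (unsorted, in input order),
#'   with attribute `n_dropped`.
#' @export
shuffle_intervals <- function(peaks, space, same_chrom = FALSE) {
  lens <- width(peaks)
  if (length(lens) == 0L) {
    out <- GRanges(seqinfo = space$genome)
    attr(out, "n_dropped") <- 0L
    return(out)
  }
  if (!same_chrom) {
    s <- .place_lin(lens, space)
  } else {
    s <- rep(NA_real_, length(lens))
    pk_chrom <- as.character(seqnames(peaks))
    for (ch in unique(pk_chrom)) {
      pk <- which(pk_chrom == ch)
      sg <- which(space$seg_chrom == ch)
      if (length(sg)) s[pk] <- .place_lin(lens[pk], space, seg_idx = sg)
    }
  }
  drop <- is.na(s)
  if (any(drop))
    warning(sum(drop), " peak(s) fit in no eligible segment and were dropped")
  out <- .delinearize(s[!drop], s[!drop] + lens[!drop], space$genome)
  attr(out, "n_dropped") <- sum(drop)
  out
}

## ---- probe density ----------------------------------------------------------

# prefix-sum index over merged probes on the linearized genome:
# F(x) = number of probe-covered bases at positions < x
.probe_index <- function(probes, genome) {
  lin <- .linearize(reduce(probes, ignore.strand = TRUE), genome)
  m <- .merge_lin(lin$s, lin$e)
  list(s = m$s, e = m$e, cumw = cumsum(m$e - m$s))
}

# covered bases in [s, e) given a probe index; vectorized over s/e
.probe_cov <- function(idx, s, e) {
  F <- function(x) {
    i <- findInterval(x, idx$s)
    ifelse(i == 0L, 0, idx$cumw[pmax(i, 1L)] - pmax(idx$e[pmax(i, 1L)] - x, 0))
  }
  F(e) - F(s)
}

#' Tiling-probe density of intervals
#'
#' For ChIP-chip-derived annotations the shuffle must respect array design:
#' the probe density of a peak is the fraction of its bases covered by at
#' least one microarray probe (merged probe cover within the peak divided by
#' peak length), a dimensionless value in \[0, 1\].
#'
#' @param x `GRanges` of intervals (peaks).
#' @param probes `GRanges` of array probes.
#' @param genome A `Seqinfo`; required to index the probes.
#' @return Numeric vector of densities, one per interval of `x`.
#' @export
probe_density <- function(x, probes, genome) {
  if (length(x) == 0L) return(numeric(0))
  idx <- .probe_index(probes, genome)
  lin <- .linearize(x, genome)
  unname(.probe_cov(idx, lin$s, lin$e) / (lin$e - lin$s))
}

#' Probe-density-matched shuffle
#'
#' Like [shuffle_intervals()], but each relocated peak must also reproduce
#' the probe density of the original peak to within `probe_tolerance`
#' (absolute difference; exactly `probe_tolerance` passes). Placements are
#' redrawn per peak until matched or `max_attempts` draws are spent;
#' an unmatched peak keeps its last draw. Peaks are processed sequentially
#' in input order, one placement per attempt, so the consumed random stream
#' is fully determined by the seed.
#'
#' @inheritParams shuffle_intervals
#' @param probes `GRanges` of array probes (non-empty).
#' @param probe_tolerance Maximum absolute density difference accepted
#'   (default 0.1).
#' @param max_attempts Placement draws per peak before giving up (default 100).
#' @return A list with `intervals` (`GRanges`, input order, attribute
#'   `n_dropped`) and `matched_fraction` (matched peaks / placed peaks).
#' @export
shuffle_probe_matched <- function(peaks, space, probes,
                                  probe_tolerance = 0.1,
                                  max_attempts = 100L,
                                  same_chrom = FALSE) {
  if (is.null(probes) || length(probes) == 0L)
    stop("probe-matched shuffling requires a non-empty probe map")
  genome <- space$genome
  idx <- .probe_index(probes, genome)
  lin <- .linearize(peaks, genome)
  lens <- lin$e - lin$s
  d0 <- .probe_cov(idx, lin$s, lin$e) / pmax(lens, 1)
  n <- length(lens)
  out_s <- rep(NA_real_, n)
  matched <- logical(n)
  pk_chrom <- as.character(seqnames(peaks))
  for (i in seq_len(n)) {
    sg <- if (same_chrom) which(space$seg_chrom == pk_chrom[i]) else NULL
    for (a in seq_len(max_attempts)) {
      s <- .place_lin(lens[i], space, seg_idx = sg)
      if (is.na(s)) break
      out_s[i] <- s
      d <- .probe_cov(idx, s, s + lens[i]) / lens[i]
      if (abs(d - d0[i]) <= probe_tolerance) {
        matched[i] <- TRUE
        break
      }
    }
  }
  drop <- is.na(out_s)
  if (any(drop))
    warning(sum(drop), " peak(s) fit in no eligible segment and were dropped")
  keep <- !drop
  out <- .delinearize(out_s[keep], out_s[keep] + lens[keep], genome)
  attr(out, "n_dropped") <- sum(drop)
  list(intervals = out,
       matched_fraction = if (any(keep)) mean(matched[keep]) else NA_real_)
}
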