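## Synthetic-data generators. Every generator is a pure function of its
## configuration and seed, and emits ground truth alongside the data so
## downstream recovery tests can score themselves.

.with_seed <- function(seed, expr) {
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  expr
}

#' Simulate a genome and its exclusion regions
#'
#' Builds a multi-chromosome genome and a blacklist-like exclusion set
#' covering a requested fraction of it as disjoint random blocks (one block
#' per equal-width slot, at a random offset inside the slot, so coverage is
#' exact and blocks never touch across slots deterministically given the
#' seed).
#'
#' @param n_chroms Number of chromosomes (default 4).
#' @param chrom_length Length of each chromosome in bp, recycled to
#'   `n_chroms` (default 2.5e6, a Drosophila-like desk scale).
#' @param exclusion_fraction Fraction of the genome covered by exclusions,
#'   in `[0, 0.9]` (default 0.05).
#' @param blocks_per_chrom Exclusion blocks per chromosome (default 5).
#' @param seed Random seed.
#' @return List with `genome` (`Seqinfo`) and `exclusions` (`GRanges`,
#'   empty when `exclusion_fraction = 0`).
#' @export
simulate_genome <- function(n_chroms = 4, chrom_length = 2.5e6,
                            exclusion_fraction = 0.05,
                            blocks_per_chrom = 5, seed = 1) {
  stopifnot(n_chroms >= 1, all(chrom_length >= 1))
  if (exclusion_fraction < 0 || exclusion_fraction > 0.9)
    stop("exclusion_fraction must be in [0, 0.9]")
  lens <- rep_len(round(chrom_length), n_chroms)
  genome <- Seqinfo(paste0("chr", seq_len(n_chroms)), lens)
  if (exclusion_fraction == 0)
    return(list(genome = genome, exclusions = GRanges(seqinfo = genome)))
  .with_seed(seed, {
    chr <- character(0); s <- numeric(0); e <- numeric(0)
    for (i in seq_len(n_chroms)) {
      slot <- floor(lens[i] / blocks_per_chrom)
      block <- round(slot * exclusion_fraction)
      if (block < 1)
        stop("exclusion blocks would be shorter than 1 bp; reduce blocks_per_chrom")
      off <- floor(runif(blocks_per_chrom) * (slot - block + 1))
      s <- c(s, (seq_len(blocks_per_chrom) - 1) * slot + off)
      e <- c(e, (seq_len(blocks_per_chrom) - 1) * slot + off + block)
      chr <- c(chr, rep(paste0("chr", i), blocks_per_chrom))
    }
    list(genome = genome,
         exclusions = sort(GRanges(chr, IRanges(s + 1, e), seqinfo = genome),
                           ignore.strand = TRUE))
  })
}

#' Simulate query and annotation peak sets with planted co-localization
#'
#' Emulates the inputs of the enrichment stage: a query peak set placed
#' uniformly in eligible space and an annotation set in which each peak is,
#' with probability `theta`, planted to overlap a randomly chosen query peak
#' (its start drawn so that at least half of its length lies inside the
#' query peak; planted lengths are truncated at twice the host's width so
#' that guarantee is always satisfiable), and otherwise placed uniformly in
#' eligible space — the same
#' placement law the shuffling null uses, so `theta = 0` data are exactly
#' null. Peak lengths are log-normal with the given median.
#'
#' @param genome A `Seqinfo`.
#' @param exclusions Optional exclusion `GRanges`.
#' @param n_query,n_annotation Numbers of peaks (defaults 2000).
#' @param theta Planting probability in `[0, 1]` (default 0).
#' @param peak_median Median peak length in bp (default 500).
#' @param peak_sigma Log-normal `sdlog` of peak lengths (default 0.5).
#' @param seed Random seed.
#' @param query Optional existing query `GRanges` to plant onto (several
#'   annotation sets with different `theta` can then share one query);
#'   when given, `n_query` is ignored.
#' @return List with `query` and `annotation` (`GRanges`), `theta`, and
#'   `planted` (logical, one per annotation peak).
#' @export
simulate_peaks <- function(genome, exclusions = NULL, n_query = 2000,
                           n_annotation = 2000, theta = 0, peak_median = 500,
                           peak_sigma = 0.5, seed = 1, query = NULL) {
  stopifnot(theta >= 0, theta <= 1, n_query >= 1, n_annotation >= 1,
            peak_median >= 1)
  space <- build_eligible_space(genome, exclusions)
  .with_seed(seed, {
    if (is.null(query)) {
      q_len <- pmax(1, round(rlnorm(n_query, log(peak_median), peak_sigma)))
      q_s <- .place_lin(q_len, space)
      if (anyNA(q_s)) stop("placement infeasible: query peaks exceed segments")
    } else {
      lin <- .linearize(query, genome)
      q_s <- unname(lin$s)
      q_len <- lin$e - lin$s
      n_query <- length(q_s)
    }
    a_len <- pmax(1, round(rlnorm(n_annotation, log(peak_median), peak_sigma)))
    planted <- runif(n_annotation) < theta
    a_s <- rep(NA_real_, n_annotation)
    if (any(!planted)) a_s[!planted] <- .place_lin(a_len[!planted], space)
    if (any(planted)) {
      host <- sample.int(n_query, sum(planted), replace = TRUE)
      a_len[planted] <- pmin(a_len[planted], 2 * q_len[host])
      a_s[planted] <- .plant_lin(a_len[planted], q_s[host], q_len[host],
                                 space$genome)
    }
    if (anyNA(a_s)) stop("placement infeasible: annotation peaks exceed segments")
    list(query = GenomicRanges::sort(
           .delinearize(q_s, q_s + q_len, genome), ignore.strand = TRUE),
         annotation = .delinearize(a_s, a_s + a_len, genome),
         theta = theta,
         planted = planted)
  })
}

# plant annotation peaks of lengths `la` onto host query peaks [qs, qs+ql):
# start uniform over positions giving >= 50% containment. Callers cap la at
# 2 * ql, which makes the position window non-empty even after clipping to
# the host's chromosome (the host itself lies on the chromosome).
.plant_lin <- function(la, qs, ql, genome) {
  off <- .chrom_offsets(genome)
  lens <- as.numeric(seqlengths(genome))
  chrom_i <- findInterval(qs, off)
  lo_chr <- off[chrom_i]
  hi_chr <- off[chrom_i] + lens[chrom_i]
  r <- ceiling(la / 2)
  lo <- pmax(qs + r - la, lo_chr)
  hi <- pmin(qs + ql - r, hi_chr - la)
  lo + floor(runif(length(la)) * (hi - lo + 1))
}

#' Simulate a tiling-array probe map
#'
#' Regularly spaced probes of fixed length across every chromosome,
#' omitting probes that touch optional gap regions — a stand-in for the
#' array designs behind ChIP-chip annotations. Deterministic (no seed).
#'
#' @param genome A `Seqinfo`.
#' @param probe_length Probe length in bp (default 25).
#' @param spacing Start-to-start distance in bp, `>= probe_length`
#'   (default 50).
#' @param gap_regions Optional `GRanges`; probes overlapping them are
#'   removed.
#' @return A `GRanges` probe map.
#' @export
simulate_probe_map <- function(genome, probe_length = 25, spacing = 50,
                               gap_regions = NULL) {
  stopifnot(probe_length >= 1, spacing >= probe_length)
  chr <- character(0); s <- numeric(0)
  for (i in seq_along(seqlevels(genome))) {
    len <- as.numeric(seqlengths(genome))[i]
    if (len < probe_length) next
    st <- seq(0, len - probe_length, by = spacing)
    s <- c(s, st)
    chr <- c(chr, rep(seqlevels(genome)[i], length(st)))
  }
  probes <- GRanges(chr, IRanges(s + 1, s + probe_length), seqinfo = genome)
  if (!is.null(gap_regions) && length(gap_regions) > 0L)
    probes <- probes[!overlapsAny(probes, gap_regions, ignore.strand = TRUE)]
  probes
}

#' Simulate a TMT IP-MS abundance matrix with planted interactors
#'
#' Background protein abundances are log-normal with equal group means;
#' `n_true_interactors` proteins are multiplied by `fold_change` in the bait
#' channels (the first planted protein, named `"bait"`, gets
#' `bait_fold_change`, modelling the immunoprecipitated bait itself).
#' Channel-level systematic scale factors are drawn to exercise the
#' normalization steps, and are returned as part of the truth.
#'
#' @param n_proteins Number of proteins (default 1500).
#' @param n_true_interactors Planted interactors including the bait
#'   (default 10).
#' @param fold_change Linear bait/control fold change of planted interactors
#'   (> 1, default 8).
#' @param bait_fold_change Fold change of the bait protein itself
#'   (default `4 * fold_change`).
#' @param cv Coefficient of variation of the multiplicative measurement
#'   noise (default 0.25).
#' @param bait_cv Coefficient of variation of the bait protein's own
#'   measurement noise (default `cv / 10`). The immunoprecipitated bait is
#'   quantified from many high-intensity peptides, so its relative error is
#'   far smaller than that of background proteins.
#' @param n_channels_per_group Channels per group (default 3, i.e. 3 bait-IP
#'   vs 3 control-IP).
#' @param channel_sdlog Log-scale SD of channel scale factors (default 0.3).
#' @param seed Random seed.
#' @return List with `matrix` (an [abundance_matrix()]), `truth` (planted
#'   protein identifiers, bait first) and `channel_factors`.
#' @export
simulate_tmt <- function(n_proteins = 1500, n_true_interactors = 10,
                         fold_change = 8, bait_fold_change = 4 * fold_change,
                         cv = 0.25, bait_cv = cv / 10,
                         n_channels_per_group = 3,
                         channel_sdlog = 0.3, seed = 1) {
  stopifnot(n_true_interactors < n_proteins, fold_change > 1,
            n_channels_per_group >= 2, cv >= 0, bait_cv >= 0)
  .with_seed(seed, {
    n_chan <- 2L * n_channels_per_group
    groups <- rep(c("bait", "control"), each = n_channels_per_group)
    ids <- c("bait",
             sprintf("interactor%02d", seq_len(n_true_interactors - 1)),
             sprintf("background%04d",
                     seq_len(n_proteins - n_true_interactors)))
    baseline <- rlnorm(n_proteins, meanlog = log(1e6), sdlog = 1.5)
    fc <- rep(1, n_proteins)
    fc[1] <- bait_fold_change
    if (n_true_interactors > 1) fc[2:n_true_interactors] <- fold_change
    sigma_row <- rep(sqrt(log(1 + cv^2)), n_proteins)
    sigma_row[1] <- sqrt(log(1 + bait_cv^2))
    channel_factors <- rlnorm(n_chan, 0, channel_sdlog)
    mu <- outer(baseline, channel_factors)
    mu[, groups == "bait"] <- mu[, groups == "bait"] * fc
    noise <- if (any(sigma_row > 0))
      matrix(rlnorm(n_proteins * n_chan, -sigma_row^2 / 2, sigma_row),
             n_proteins, n_chan) else 1
    vals <- mu * noise
    dimnames(vals) <- list(ids, paste0(groups, rep(seq_len(n_channels_per_group), 2)))
    list(matrix = abundance_matrix(vals, setNames(groups, colnames(vals))),
         truth = ids[seq_len(n_true_interactors)],
         channel_factors = setNames(channel_factors, colnames(vals)))
  })
}
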