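#' Read a UCSC-style chrom.sizes file
#'
#' Parses a two-column whitespace-delimited text file (chromosome name,
#' length in bp) into a [GenomeInfoDb::Seqinfo] object that defines the
#' coordinate universe for all downstream operations. Chromosome order is
#' the file order.
#'
#' @param path Path to the chrom.sizes file.
#' @return A `Seqinfo` with one entry per chromosome.
#' @examples
#' f <- tempfile()
#' writeLines(c("chr1\t1000", "chr2\t500"), f)
#' read_chrom_sizes(f)
#' @export
read_chrom_sizes <- function(path) {
  lines <- readLines(path)
  keep <- which(nzchar(trimws(lines)))
  if (length(keep) == 0L) stop("chrom.sizes file '", path, "' is empty")
  nms <- character(length(keep))
  lens <- numeric(length(keep))
  for (i in seq_along(keep)) {
    fields <- strsplit(trimws(lines[keep[i]]), "[ \t]+")[[1]]
    if (length(fields) < 2L)
      stop("malformed chrom.sizes line ", keep[i], ": '", lines[keep[i]], "'")
    len <- suppressWarnings(as.numeric(fields[2]))
    if (is.na(len) || len != floor(len))
      stop("malformed chrom.sizes line ", keep[i], ": length '", fields[2],
           "' is not an integer")
    if (len <= 0)
      stop("chrom.sizes line ", keep[i], ": chromosome '", fields[1],
           "' has non-positive length ", len)
    nms[i] <- fields[1]
    lens[i] <- len
  }
  if (anyDuplicated(nms))
    stop("duplicate chromosome name(s) in '", path, "': ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "))
  Seqinfo(seqnames = nms, seqlengths = lens)
}

#' Read a BED file of genomic intervals
#'
#' Reads BED3/BED5+ (tab- or space-separated, 0-based half-open) into a
#' [GenomicRanges::GRanges]. `track`, `browser` and `#` comment lines are
#' skipped. Column 4 becomes the `name` metadata column and column 5 the
#' `score` (the BED placeholder `.` is read as `NA` in either); columns
#' beyond 5 are preserved opaquely in an `extra` column so
#' that [write_bed()] round-trips them.
#'
#' @param path Path to the BED file.
#' @param genome Optional `Seqinfo` (see [read_chrom_sizes()]). When given,
#'   intervals on unknown chromosomes or exceeding chromosome bounds are
#'   rejected, and the returned object carries the genome's `seqinfo`.
#' @return A sorted `GRanges` (strand-less).
#' @export
read_bed <- function(path, genome = NULL) {
  lines <- readLines(path)
  is_data <- nzchar(trimws(lines)) &
    !grepl("^(track|browser|#)", lines)
  idx <- which(is_data)
  if (length(idx) == 0L) {
    gr <- GRanges()
    if (!is.null(genome)) seqlevels(gr) <- seqlevels(genome)
    return(gr)
  }
  parts <- strsplit(lines[idx], "\t", fixed = TRUE)
  # permit space-separated files
  one_col <- lengths(parts) == 1L
  if (any(one_col))
    parts[one_col] <- strsplit(lines[idx][one_col], "[ \t]+")
  ncols <- lengths(parts)
  if (any(ncols < 3L))
    stop("BED line ", idx[which(ncols < 3L)[1]], ": fewer than 3 columns")
  chrom <- vapply(parts, `[`, character(1), 1L)
  s <- suppressWarnings(as.numeric(vapply(parts, `[`, character(1), 2L)))
  e <- suppressWarnings(as.numeric(vapply(parts, `[`, character(1), 3L)))
  bad <- which(is.na(s) | is.na(e))
  if (length(bad))
    stop("BED line ", idx[bad[1]], ": non-numeric coordinates")
  bad <- which(s < 0 | s >= e)
  if (length(bad))
    stop("BED line ", idx[bad[1]], ": requires 0 <= start < end, got [",
         s[bad[1]], ", ", e[bad[1]], ")")
  if (!is.null(genome)) {
    known <- chrom %in% seqlevels(genome)
    if (!all(known))
      stop("BED line ", idx[which(!known)[1]], ": unknown chromosome '",
           chrom[which(!known)[1]], "'")
    lens <- seqlengths(genome)[chrom]
    bad <- which(e > lens)
    if (length(bad))
      stop("BED line ", idx[bad[1]], ": interval end ", e[bad[1]],
           " exceeds length of ", chrom[bad[1]], " (", lens[bad[1]], ")")
  }
  gr <- GRanges(chrom, IRanges(start = s + 1, end = e))
  na_dot <- function(v) ifelse(v == ".", NA_character_, v)
  if (any(ncols >= 4L))
    mcols(gr)$name <- na_dot(vapply(parts, function(p)
      if (length(p) >= 4L) p[4L] else NA_character_, character(1)))
  if (any(ncols >= 5L))
    mcols(gr)$score <- suppressWarnings(as.numeric(
      vapply(parts, function(p) if (length(p) >= 5L) p[5L] else NA_character_,
             character(1))))
  if (any(ncols >= 6L))
    mcols(gr)$extra <- na_dot(vapply(parts, function(p)
      if (length(p) >= 6L) paste(p[-(1:5)], collapse = "\t") else NA_character_,
      character(1)))
  if (!is.null(genome)) seqlevels(gr) <- seqlevels(genome)
  if (!is.null(genome)) seqinfo(gr) <- genome
  sort(gr, ignore.strand = TRUE)
}

#' Write genomic intervals as BED
#'
#' Inverse of [read_bed()]: writes tab-separated BED with 0-based half-open
#' coordinates. `name`/`score`/`extra` metadata columns, when present, become
#' columns 4, 5 and 6+ so a read/write cycle is bit-faithful.
#'
#' @param x A `GRanges`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_bed <- function(x, path) {
  m <- mcols(x)
  cols <- list(as.character(seqnames(x)),
               format(start(x) - 1, scientific = FALSE, trim = TRUE),
               format(end(x), scientific = FALSE, trim = TRUE))
  has_name <- "name" %in% names(m)
  has_score <- "score" %in% names(m)
  has_extra <- "extra" %in% names(m)
  if (has_name || has_score || has_extra)
    cols <- c(cols, list(ifelse(is.na(m$name), ".", as.character(m$name))))
  if (has_score || has_extra) {
    sc <- if (has_score) m$score else rep(NA_real_, length(x))
    cols <- c(cols, list(ifelse(is.na(sc), ".",
                                format(sc, scientific = FALSE, trim = TRUE))))
  }
  if (has_extra)
    cols <- c(cols, list(ifelse(is.na(m$extra), ".", m$extra)))
  lines <- do.call(paste, c(cols, sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Merge overlapping and bookended intervals
#'
#' Collapses a set of intervals into its minimal disjoint cover: overlapping
#' intervals and intervals that touch end-to-start are merged, so every base
#' is represented once. Total covered bp is preserved.
#'
#' @param x A `GRanges`.
#' @return A merged `GRanges`.
#' @export
merge_intervals <- function(x) {
  reduce(x, ignore.strand = TRUE)
}

#' Total bases covered by an interval set
#'
#' @param x A `GRanges`; overlapping members are counted once.
#' @return Number of base pairs covered.
#' @export
covered_bp <- function(x) {
  sum(as.numeric(width(reduce(x, ignore.strand = TRUE))))
}

#' Base pairs shared by two interval sets
#'
#' Counts genomic positions covered by both sets. Each set is merged first so
#' bases duplicated within one set count once; the result is symmetric in its
#' arguments.
#'
#' @param a,b `GRanges` on the same genome.
#' @return Shared base-pair count (0 for empty input).
#' @export
overlap_bp <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L) return(0)
  # linearized merge + coverage sweep: orders of magnitude faster than
  # GenomicRanges::intersect and independent of attached seqinfo. Chromosomes
  # are separated by offsets built from the largest end seen in either set.
  ca <- as.character(seqnames(a)); cb <- as.character(seqnames(b))
  chroms <- union(ca, cb)
  hi <- setNames(numeric(length(chroms)), chroms)
  ta <- tapply(end(a), ca, max); tb <- tapply(end(b), cb, max)
  hi[names(ta)] <- pmax(hi[names(ta)], ta)
  hi[names(tb)] <- pmax(hi[names(tb)], tb)
  off <- setNames(c(0, cumsum(hi))[seq_along(chroms)], chroms)
  .overlap_lin(.merge_lin(off[ca] + start(a) - 1, off[ca] + end(a)),
               .merge_lin(off[cb] + start(b) - 1, off[cb] + end(b)))
}

#' Count intervals of one set that touch another
#'
#' @param a,b `GRanges` on the same genome.
#' @return Number of intervals in `a` sharing at least 1 bp with any interval
#'   of `b`; each interval of `a` counts at most once.
#' @export
count_overlapping <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L) return(0L)
  sum(countOverlaps(a, b, ignore.strand = TRUE) > 0L)
}

## ---- internal linearized-coordinate fast path -------------------------------
## The permutation loop runs thousands of shuffle+overlap rounds; S4 container
## overhead dominates there, so internally intervals are 0-based half-open
## [s, e) positions on a single line obtained by concatenating chromosomes.
## Intervals never span a chromosome boundary, so interval algebra on the line
## is exact. All fast-path results are property-tested against the GRanges
## route and a per-base boolean oracle.

.chrom_offsets <- function(genome) {
  lens <- as.numeric(seqlengths(genome))
  setNames(c(0, cumsum(lens))[seq_along(lens)], seqlevels(genome))
}

.linearize <- function(gr, genome) {
  if (length(gr) == 0L) return(list(s = numeric(0), e = numeric(0)))
  off <- .chrom_offsets(genome)[as.character(seqnames(gr))]
  list(s = off + start(gr) - 1, e = off + end(gr))
}

.delinearize <- function(s, e, genome) {
  off <- .chrom_offsets(genome)
  lens <- as.numeric(seqlengths(genome))
  idx <- findInterval(s, off)
  GRanges(seqlevels(genome)[idx],
          IRanges(start = s - off[idx] + 1, end = e - off[idx]),
          seqinfo = genome)
}

# merge [s,e) intervals on the line (bookended intervals coalesce)
.merge_lin <- function(s, e) {
  n <- length(s)
  if (n == 0L) return(list(s = numeric(0), e = numeric(0)))
  o <- order(s, e)
  s <- s[o]; e <- e[o]
  cm <- cummax(e)
  new_grp <- c(TRUE, s[-1] > cm[-n])
  last <- c(which(new_grp[-1]), n)
  list(s = s[new_grp], e = cm[last])
}

# shared bp between two MERGED interval lists, by coverage sweep
.overlap_lin <- function(a, b) {
  na <- length(a$s); nb <- length(b$s)
  if (na == 0L || nb == 0L) return(0)
  pos <- c(a$s, b$s, a$e, b$e)
  delta <- c(rep(1L, na + nb), rep(-1L, na + nb))
  o <- order(pos)
  pos <- pos[o]
  cov <- cumsum(delta[o])
  n <- length(pos)
  sum(diff(pos) * (cov[-n] == 2L))
}
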