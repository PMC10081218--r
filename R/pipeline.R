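## File-to-file orchestration behind the command-line interface: each run_*
## function reads standard-format inputs, executes one analysis stage, writes
## a TSV result plus a JSON run manifest, and returns the fitted object
## invisibly. A YAML config may supply any argument; explicit arguments win.

.read_config <- function(config) {
  if (is.null(config)) return(list())
  if (is.character(config)) yaml::read_yaml(config) else as.list(config)
}

.merge_config <- function(config, args) {
  cfg <- .read_config(config)
  for (nm in names(args)) if (!is.null(args[[nm]])) cfg[[nm]] <- args[[nm]]
  cfg
}

.file_digests <- function(paths) {
  paths <- paths[!vapply(paths, is.null, logical(1))]
  paths <- unlist(paths, use.names = TRUE)
  if (length(paths) == 0L) return(list())
  as.list(tools::md5sum(paths))
}

.write_manifest <- function(path, command, cfg, inputs, outputs) {
  manifest <- list(command = command,
                   tool = "peakperm",
                   version = as.character(packageVersion("peakperm")),
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                   config = cfg,
                   input_md5 = .file_digests(inputs),
                   output_md5 = .file_digests(outputs))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       null = "null")
  invisible(path)
}

.manifest_path <- function(out) paste0(out, ".manifest.json")

#' Run the enrichment stage from files
#'
#' Reads a query BED, one or more annotation BEDs, a chrom.sizes file and
#' optional exclusion/probe BEDs, runs [enrichment_test()], and writes the
#' enrichment table as TSV plus a JSON run manifest (`<out>.manifest.json`).
#'
#' @param query,chrom_sizes,out File paths (query BED, chrom.sizes, output
#'   TSV).
#' @param annotations Named character vector of annotation BED paths (names
#'   become annotation labels; unnamed paths are labelled by file name).
#' @param exclusions Optional exclusion BED path.
#' @param probes Optional named character vector of probe-map BED paths for
#'   the annotations needing probe-density matching.
#' @param config Optional YAML file path or list with defaults for the
#'   remaining arguments.
#' @inheritParams enrichment_test
#' @return Invisibly, the `peak_enrichment` object.
#' @export
run_enrich <- function(query, annotations, chrom_sizes, out,
                       exclusions = NULL, probes = NULL,
                       n_permutations = NULL, seed = NULL,
                       probe_tolerance = NULL, max_attempts = NULL,
                       required_match_fraction = NULL, same_chrom = NULL,
                       config = NULL) {
  cfg <- .merge_config(config, list(
    query = query, annotations = annotations, chrom_sizes = chrom_sizes,
    out = out, exclusions = exclusions, probes = probes,
    n_permutations = n_permutations, seed = seed,
    probe_tolerance = probe_tolerance, max_attempts = max_attempts,
    required_match_fraction = required_match_fraction,
    same_chrom = same_chrom))
  defaults <- list(n_permutations = 1000L, seed = 1L, probe_tolerance = 0.1,
                   max_attempts = 100L, required_match_fraction = 0.99,
                   same_chrom = FALSE)
  for (nm in names(defaults)) if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
  genome <- read_chrom_sizes(cfg$chrom_sizes)
  qry <- read_bed(cfg$query, genome)
  if (length(qry) == 0L) stop("query peak file '", cfg$query, "' is empty")
  ann_paths <- unlist(cfg$annotations)
  ann_names <- names(ann_paths)
  if (is.null(ann_names)) ann_names <- rep("", length(ann_paths))
  blank <- !nzchar(ann_names)
  ann_names[blank] <- sub("\\.bed$", "", basename(ann_paths[blank]))
  names(ann_paths) <- ann_names
  anns <- lapply(ann_paths, read_bed, genome = genome)
  for (nm in names(anns))
    if (length(anns[[nm]]) == 0L)
      stop("annotation file '", ann_paths[[nm]], "' is empty")
  excl <- if (!is.null(cfg$exclusions)) read_bed(cfg$exclusions, genome)
  probe_sets <- if (!is.null(cfg$probes))
    lapply(unlist(cfg$probes), read_bed, genome = genome)
  fit <- enrichment_test(qry, anns, genome, exclusions = excl,
                         probes = probe_sets,
                         n_permutations = as.integer(cfg$n_permutations),
                         seed = as.integer(cfg$seed),
                         probe_tolerance = cfg$probe_tolerance,
                         max_attempts = as.integer(cfg$max_attempts),
                         required_match_fraction = cfg$required_match_fraction,
                         same_chrom = isTRUE(cfg$same_chrom))
  write_enrichment_tsv(fit, cfg$out)
  .write_manifest(.manifest_path(cfg$out), "enrich",
                  cfg[setdiff(names(cfg), c("annotations", "probes"))],
                  c(list(query = cfg$query, chrom_sizes = cfg$chrom_sizes,
                         exclusions = cfg$exclusions),
                    as.list(ann_paths), as.list(unlist(cfg$probes))),
                  list(out = cfg$out))
  invisible(fit)
}

#' Run the co-localization stage from files
#'
#' Reads two peak BEDs and a chrom.sizes file, runs [colocalization_test()],
#' and writes a one-row TSV report (both directed overlap fractions, the
#' binned contingency counts, Fisher p and odds ratio) plus a manifest.
#'
#' @param a,b,chrom_sizes,out File paths.
#' @param bin_width Bin size in bp or `"auto"`.
#' @param config Optional YAML path or list.
#' @return Invisibly, the `peak_coloc` object.
#' @export
run_coloc <- function(a, b, chrom_sizes, out, bin_width = NULL,
                      config = NULL) {
  cfg <- .merge_config(config, list(a = a, b = b, chrom_sizes = chrom_sizes,
                                    out = out, bin_width = bin_width))
  if (is.null(cfg$bin_width)) cfg$bin_width <- "auto"
  genome <- read_chrom_sizes(cfg$chrom_sizes)
  res <- colocalization_test(read_bed(cfg$a, genome), read_bed(cfg$b, genome),
                             genome, bin_width = cfg$bin_width)
  write.table(as.data.frame(res), cfg$out, sep = "\t", quote = FALSE,
              row.names = FALSE)
  .write_manifest(.manifest_path(cfg$out), "coloc", cfg,
                  list(a = cfg$a, b = cfg$b, chrom_sizes = cfg$chrom_sizes),
                  list(out = cfg$out))
  invisible(res)
}

#' Run the IP-MS stage from files
#'
#' Reads a TSV abundance table (see [read_abundance_tsv()]), runs
#' [ipms_test()], and writes the volcano-ready interactor table plus a
#' manifest.
#'
#' @param input,out File paths.
#' @param groups Named character vector mapping channel columns to
#'   `"bait"`/`"control"` (required, possibly via `config`).
#' @param coisolation_threshold,log2_transform,alpha See [ipms_test()].
#' @param config Optional YAML path or list.
#' @return Invisibly, the `ipms_fit` object.
#' @export
run_ipms <- function(input, out, groups = NULL, coisolation_threshold = NULL,
                     log2_transform = NULL, alpha = NULL, config = NULL) {
  cfg <- .merge_config(config, list(input = input, out = out, groups = groups,
                                    coisolation_threshold = coisolation_threshold,
                                    log2_transform = log2_transform,
                                    alpha = alpha))
  if (is.null(cfg$coisolation_threshold)) cfg$coisolation_threshold <- 25
  if (is.null(cfg$log2_transform)) cfg$log2_transform <- TRUE
  if (is.null(cfg$alpha)) cfg$alpha <- 0.05
  if (is.null(cfg$groups))
    stop("channel group labels are required (groups = c(channel = 'bait'|'control'))")
  grp <- unlist(cfg$groups)
  fit <- ipms_test(read_abundance_tsv(cfg$input, grp),
                   coisolation_threshold = cfg$coisolation_threshold,
                   log2_transform = isTRUE(cfg$log2_transform),
                   alpha = cfg$alpha)
  write.table(fit$results, cfg$out, sep = "\t", quote = FALSE,
              row.names = FALSE)
  .write_manifest(.manifest_path(cfg$out), "ipms", cfg,
                  list(input = cfg$input), list(out = cfg$out))
  invisible(fit)
}

#' Generate a complete synthetic input bundle on disk
#'
#' Writes everything the pipeline consumes, with ground truth: chrom.sizes,
#' exclusion BED, query and annotation BEDs (planted co-localization
#' `theta`), a tiling probe BED, a TMT abundance TSV with planted
#' interactors, and a `truth.json`.
#'
#' @param dir Output directory (created if needed).
#' @param theta Planted annotation/query co-localization probability.
#' @param seed Random seed.
#' @param ... Passed on to [simulate_genome()], [simulate_peaks()] and
#'   [simulate_tmt()] (matched by name).
#' @return Invisibly, a named list of the written file paths.
#' @export
run_simulate <- function(dir, theta = 0, seed = 1, ...) {
  dots <- list(...)
  pick <- function(f, extra) {
    nms <- intersect(names(dots), names(formals(f)))
    c(extra, dots[nms])
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  gen <- do.call(simulate_genome, pick(simulate_genome, list(seed = seed)))
  pk <- do.call(simulate_peaks,
                pick(simulate_peaks,
                     list(genome = gen$genome, exclusions = gen$exclusions,
                          theta = theta, seed = seed + 1)))
  probes <- do.call(simulate_probe_map,
                    pick(simulate_probe_map, list(genome = gen$genome)))
  tmt <- do.call(simulate_tmt, pick(simulate_tmt, list(seed = seed + 2)))
  paths <- list(chrom_sizes = file.path(dir, "genome.chrom.sizes"),
                exclusions = file.path(dir, "exclusions.bed"),
                query = file.path(dir, "query.bed"),
                annotation = file.path(dir, "annotation.bed"),
                probes = file.path(dir, "probes.bed"),
                tmt = file.path(dir, "tmt.tsv"),
                truth = file.path(dir, "truth.json"))
  writeLines(paste(seqlevels(gen$genome),
                   format(seqlengths(gen$genome), scientific = FALSE,
                          trim = TRUE), sep = "\t"),
             paths$chrom_sizes)
  write_bed(gen$exclusions, paths$exclusions)
  write_bed(pk$query, paths$query)
  write_bed(pk$annotation, paths$annotation)
  write_bed(probes, paths$probes)
  m <- tmt$matrix
  write.table(data.frame(id = rownames(m$values), m$values,
                         check.names = FALSE),
              paths$tmt, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(theta = theta, seed = seed,
         planted_annotation_peaks = sum(pk$planted),
         tmt_groups = as.list(setNames(m$groups, colnames(m$values))),
         tmt_truth = tmt$truth,
         tmt_channel_factors = as.list(tmt$channel_factors)),
    paths$truth, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  .write_manifest(file.path(dir, "simulate.manifest.json"), "simulate",
                  c(list(theta = theta, seed = seed), dots),
                  list(), paths)
  invisible(paths)
}
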