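#' Catalog-construction run configuration
#'
#' Bundles every threshold of the catalog pipeline with validation. Defaults
#' are the catalog's stated thresholds: sketching at k = 21 with 5000
#' hashes, ANI reported above 0.8 (pre-cluster floor), species delineated at
#' ANI > 0.95, genomes kept when N50 > 5000 and quality score >= 50, high
#' quality above 90, CLR zero replacement at delta = 1/N^2.
#'
#' @param k Odd k-mer length.
#' @param sketch_size MinHash sketch size s.
#' @param precluster_ani ANI reporting floor / pre-cluster threshold.
#' @param species_ani Species ANI threshold; must exceed `precluster_ani`.
#' @param n50_min Minimum N50 (strict).
#' @param score_min Minimum quality score (inclusive).
#' @param hq_score High-quality score threshold (strict).
#' @param seed Integer seed for every stochastic stage.
#' @return A validated list of class `magcat_config`.
#' @export
magcat_config <- function(k = 21L, sketch_size = 5000L, precluster_ani = 0.8,
                          species_ani = 0.95, n50_min = 5000, score_min = 50,
                          hq_score = 90, seed = 42L) {
  stopifnot(k %% 2L == 1L, k >= 3L, k <= 31L, sketch_size >= 1L,
            n50_min >= 0, seed == as.integer(seed))
  if (!(precluster_ani > 0 && precluster_ani < species_ani &&
        species_ani < 1))
    stop("invalid config: need 0 < precluster_ani < species_ani < 1")
  structure(list(k = as.integer(k), sketch_size = as.integer(sketch_size),
                 precluster_ani = precluster_ani, species_ani = species_ani,
                 n50_min = n50_min, score_min = score_min,
                 hq_score = hq_score, seed = as.integer(seed)),
            class = "magcat_config")
}

#' Read a run configuration from a flat JSON file
#'
#' Keys not present fall back to the [magcat_config()] defaults; `overrides`
#' (e.g. parsed command-line flags) take precedence over the file.
#'
#' @param path JSON path, or `NULL` for pure defaults.
#' @param overrides Named list of config values overriding the file.
#' @return A `magcat_config`.
#' @export
read_config <- function(path = NULL, overrides = list()) {
  vals <- if (!is.null(path)) jsonlite::read_json(path, simplifyVector = TRUE)
          else list()
  vals[names(overrides)] <- overrides
  known <- names(formals(magcat_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  do.call(magcat_config, vals)
}

#' Run the full catalog-construction pipeline to an output directory
#'
#' Stages run in order: assembly statistics -> quality filter -> sketching ->
#' all-vs-all ANI -> pre-clustering + average-linkage species clustering ->
#' representative selection. Each output TSV starts with `#` header comments
#' recording the tool version, an md5 hash of the configuration, and the
#' seed, so a run is reproducible from its own artifacts.
#'
#' @param assemblies Named list of [genome_assembly()] objects, or a
#'   character vector of FASTA paths.
#' @param metadata Metadata data.frame or path to a metadata TSV
#'   (see [read_genome_metadata()]).
#' @param out_dir Output directory (created if needed).
#' @param config A [magcat_config()].
#' @return The [dereplicate()] result, invisibly; artifacts are written to
#'   `out_dir` (`config.json`, `stats.tsv`, `qc.tsv`, `ani.tsv`,
#'   `species.tsv`, `assignments.tsv`, `excluded.tsv`).
#' @export
run_pipeline <- function(assemblies, metadata, out_dir,
                         config = magcat_config()) {
  stopifnot(inherits(config, "magcat_config"))
  if (is.character(assemblies))
    assemblies <- lapply(assemblies, read_fasta)
  if (is.character(metadata))
    metadata <- read_genome_metadata(metadata)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  cfg_path <- file.path(out_dir, "config.json")
  jsonlite::write_json(unclass(config), cfg_path, auto_unbox = TRUE,
                       digits = NA)
  header <- c(
    paste0("magcat ", as.character(utils::packageVersion("magcat"))),
    paste0("config_md5 ", unname(tools::md5sum(cfg_path))),
    paste0("seed ", config$seed))

  res <- dereplicate(assemblies, metadata,
                     k = config$k, sketch_size = config$sketch_size,
                     seed = config$seed, ani_threshold = config$species_ani,
                     precluster_ani = config$precluster_ani,
                     n50_min = config$n50_min, score_min = config$score_min)

  write_tsv_file(res$stats, file.path(out_dir, "stats.tsv"), header)
  write_tsv_file(res$qc, file.path(out_dir, "qc.tsv"), header)
  write_tsv_file(res$edges, file.path(out_dir, "ani.tsv"), header)
  write_tsv_file(species_table(res), file.path(out_dir, "species.tsv"),
                 header)
  write_tsv_file(res$assignments, file.path(out_dir, "assignments.tsv"),
                 header)
  write_tsv_file(res$excluded, file.path(out_dir, "excluded.tsv"), header)
  invisible(res)
}
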