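#' Genome quality score
#'
#' The checkM-derived quality score used throughout catalog construction:
#' completeness minus five times contamination. Both arguments are
#' percentages; the score is dimensionless and may be negative (contamination
#' can exceed 100% for multi-strain reference genomes).
#'
#' @param completeness Percent completeness in \[0, 100\].
#' @param contamination Percent contamination, >= 0 (no upper cap).
#' @return Numeric score vector.
#' @export
#' @examples
#' quality_score(95, 1) # 90
quality_score <- function(completeness, contamination) {
  stopifnot(all(completeness >= 0 & completeness <= 100),
            all(contamination >= 0))
  completeness - 5 * contamination
}

#' Assess genomes against the catalog inclusion and high-quality thresholds
#'
#' A genome enters the catalog when its assembly is contiguous enough
#' (N50 strictly greater than `n50_min`) and its quality score is at least
#' `score_min` (a score of exactly 50 is kept: only scores below 50 are
#' excluded). Genomes with a quality score strictly above `hq_score` are
#' additionally flagged high quality ("near complete"); a score of exactly 90
#' is not high quality. When the metadata carries a `passes_chimerism` column
#' (an upstream GUNC-style screen), it is AND-ed into the filter.
#'
#' @param metadata Data.frame with `genome_id`, `completeness`,
#'   `contamination`, `is_isolate` and optionally `passes_chimerism`.
#' @param stats Data.frame with `genome_id` and `n50`
#'   (see [assembly_stats_table()]).
#' @param n50_min N50 must strictly exceed this (default 5000 bp).
#' @param score_min Minimum quality score kept (default 50, inclusive).
#' @param hq_score High-quality threshold (default 90, exclusive).
#' @return Data.frame with `genome_id`, `quality_score`, `passes_filter`,
#'   `is_high_quality`.
#' @export
assess_quality <- function(metadata, stats, n50_min = 5000,
                           score_min = 50, hq_score = 90) {
  validate_genome_metadata(metadata)
  idx <- match(metadata$genome_id, stats$genome_id)
  if (anyNA(idx))
    stop("no assembly stats for genome(s): ",
         paste(metadata$genome_id[is.na(idx)], collapse = ", "))
  score <- quality_score(metadata$completeness, metadata$contamination)
  passes <- stats$n50[idx] > n50_min & score >= score_min
  if ("passes_chimerism" %in% names(metadata))
    passes <- passes & metadata$passes_chimerism
  data.frame(genome_id = metadata$genome_id,
             quality_score = score,
             passes_filter = passes,
             is_high_quality = passes & score > hq_score,
             stringsAsFactors = FALSE)
}
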