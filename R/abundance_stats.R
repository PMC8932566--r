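#' Species-level mapping rate of a sample
#'
#' The fraction of a sample's sequencing reads attributed to catalog species
#' by the read classifier: the sample's row sum of the species count table
#' divided by its total read count.
#'
#' @param counts Samples x taxa matrix of non-negative counts (row names are
#'   sample ids).
#' @param total_reads Named numeric vector of per-sample total reads; must
#'   cover `sample` and be >= the row sum.
#' @param sample Sample id.
#' @return Mapping rate in \[0, 1\].
#' @export
mapping_rate <- function(counts, total_reads, sample) {
  if (!sample %in% rownames(counts)) stop("unknown sample: ", sample)
  if (!sample %in% names(total_reads))
    stop("missing total_reads for sample: ", sample)
  attributed <- sum(counts[sample, ])
  total <- total_reads[[sample]]
  if (total < attributed)
    stop("total_reads below attributed reads for sample: ", sample)
  attributed / total
}

#' Multiplicative zero replacement for a composition
#'
#' Replaces zeros in a closed composition by `delta` and rescales the
#' non-zero parts by (1 - delta * z), where z is the number of zeros, so that
#' the output still sums to one. The default delta is 1/N^2 with N the number
#' of parts (species).
#'
#' @param x Non-negative vector; closure (division by the sum) is applied
#'   first, so counts are accepted.
#' @param delta Replacement value for zeros; default `1/length(x)^2`.
#' @return A strictly positive composition summing to 1.
#' @export
#' @examples
#' multiplicative_replace(c(1, 0), delta = 1/4) # 0.75 0.25
multiplicative_replace <- function(x, delta = NULL) {
  stopifnot(all(x >= 0))
  s <- sum(x)
  if (s <= 0) stop("composition sums to zero; closure impossible")
  x <- x / s
  if (is.null(delta)) delta <- 1 / length(x)^2
  z <- sum(x == 0)
  if (z == 0L) return(x)
  if (delta * z >= 1) stop("delta too large: delta * #zeros >= 1")
  out <- ifelse(x == 0, delta, x * (1 - delta * z))
  out
}

#' Centered log-ratio transform of a count table
#'
#' Per sample (row): closure, multiplicative zero replacement with delta
#' 1/N^2 by default, then natural-log centering
#' `x_i -> ln(x_i) - mean(ln x)`. Rows of the result sum to zero, and the
#' transform is invariant to scaling a row's counts by a positive constant.
#'
#' @param counts Samples x taxa matrix of non-negative values with at least
#'   one positive entry per row.
#' @param delta Zero-replacement delta; default `1/ncol(counts)^2`.
#' @return Matrix of the same shape with CLR values.
#' @export
clr_transform <- function(counts, delta = NULL) {
  counts <- as.matrix(counts)
  if (nrow(counts) == 0L || ncol(counts) == 0L) stop("empty count table")
  if (any(counts < 0)) stop("counts must be non-negative")
  out <- t(apply(counts, 1L, function(row) {
    comp <- multiplicative_replace(row, delta = delta)
    lg <- log(comp)
    lg - mean(lg)
  }))
  dimnames(out) <- dimnames(counts)
  out
}

#' Aggregate a species count table to a higher taxonomic rank
#'
#' Sums counts over species sharing the rank-level name; per-sample totals
#' are conserved.
#'
#' @param counts Samples x species matrix (column names are species ids).
#' @param taxonomy Catalog taxonomy table (see [build_catalog_taxonomy()])
#'   covering every column of `counts`.
#' @param rank Target rank name.
#' @return Samples x taxa matrix at the requested rank.
#' @export
aggregate_by_taxon <- function(counts, taxonomy, rank) {
  rank <- match.arg(rank, GTDB_RANKS)
  counts <- as.matrix(counts)
  idx <- match(colnames(counts), taxonomy$species_id)
  if (anyNA(idx))
    stop("missing lineage for taxon/taxa: ",
         paste(colnames(counts)[is.na(idx)], collapse = ", "))
  group <- taxonomy[[rank]][idx]
  agg <- t(rowsum(t(counts), group = group))
  agg[, unique(group), drop = FALSE]
}

#' Pearson correlation of mean abundances between two hosts
#'
#' Correlates per-taxon mean abundances (typically CLR means) over the union
#' of taxa from both hosts. A taxon absent from one host is imputed at that
#' host's minimum observed value ("lowest value measured").
#'
#' @param mean_a,mean_b Named numeric vectors of per-taxon mean abundances.
#' @return Pearson correlation coefficient.
#' @export
mean_abundance_correlation <- function(mean_a, mean_b) {
  stopifnot(!is.null(names(mean_a)), !is.null(names(mean_b)))
  taxa <- union(names(mean_a), names(mean_b))
  if (length(taxa) < 3L) stop("degenerate correlation: fewer than 3 taxa")
  a <- mean_a[taxa]
  b <- mean_b[taxa]
  a[is.na(a)] <- min(mean_a)
  b[is.na(b)] <- min(mean_b)
  cor(a, b, method = "pearson")
}

#' KEGG-module presence in a genome
#'
#' A module is inferred present when at least three quarters of its steps are
#' annotated in the genome (the 3/4 boundary is inclusive: 6 of 8 steps
#' counts as present).
#'
#' @param steps_present Number of module steps found (vectorized).
#' @param steps_total Total steps of the module (>= 1).
#' @return Logical presence.
#' @export
#' @examples
#' module_present(3, 4) # TRUE
#' module_present(2, 4) # FALSE
module_present <- function(steps_present, steps_total) {
  stopifnot(all(steps_total >= 1), all(steps_present >= 0),
            all(steps_present <= steps_total))
  steps_present / steps_total >= 0.75
}

#' Metagenome-side abundance of a module
#'
#' The sum of the relative abundances of all genomes carrying the module.
#'
#' @param presence Named logical vector: genome carries the module.
#' @param rel_ab Named relative-abundance vector over the same genomes
#'   (sums to <= 1).
#' @return Module abundance fraction.
#' @export
module_abundance <- function(presence, rel_ab) {
  stopifnot(setequal(names(presence), names(rel_ab)),
            sum(rel_ab) <= 1 + 1e-9)
  sum(rel_ab[names(presence)[presence]])
}

#' Per-sample module abundance table from step coverage and counts
#'
#' Derives module presence per genome from a DRAM-style step-coverage table
#' (3/4 rule), converts the count table to per-sample relative abundances,
#' and sums relative abundances over module-carrying genomes.
#'
#' @param coverage Data.frame with `genome_id`, `module_id`, `steps_present`,
#'   `steps_total`.
#' @param counts Samples x genomes count matrix.
#' @return Samples x modules matrix of module relative abundances.
#' @export
module_abundance_table <- function(coverage, counts) {
  required <- c("genome_id", "module_id", "steps_present", "steps_total")
  missing <- setdiff(required, names(coverage))
  if (length(missing))
    stop("coverage table lacks column(s): ", paste(missing, collapse = ", "))
  counts <- as.matrix(counts)
  rel <- counts / rowSums(counts)
  present <- coverage[module_present(coverage$steps_present,
                                     coverage$steps_total), , drop = FALSE]
  modules <- sort(unique(coverage$module_id))
  out <- matrix(0, nrow(counts), length(modules),
                dimnames = list(rownames(counts), modules))
  for (m in modules) {
    genomes <- intersect(present$genome_id[present$module_id == m],
                         colnames(counts))
    if (length(genomes))
      out[, m] <- rowSums(rel[, genomes, drop = FALSE])
  }
  out
}

#' Welch's unequal-variance two-sample t test
#'
#' The t statistic uses per-group variances; degrees of freedom follow the
#' Welch-Satterthwaite approximation; the p value is two-sided. When both
#' groups are constant and equal, t = 0 and p = 1 by convention.
#'
#' @param x,y Numeric vectors with at least two values each.
#' @return List with `t`, `df`, `p`.
#' @export
welch_test <- function(x, y) {
  nx <- length(x); ny <- length(y)
  if (nx < 2L || ny < 2L) stop("each group needs at least 2 values")
  vx <- stats::var(x); vy <- stats::var(y)
  se2 <- vx / nx + vy / ny
  diff <- mean(x) - mean(y)
  if (se2 == 0) {
    if (diff == 0) return(list(t = 0, df = nx + ny - 2, p = 1))
    return(list(t = sign(diff) * Inf, df = nx + ny - 2, p = 0))
  }
  t_stat <- diff / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  list(t = t_stat, df = df, p = 2 * pt(-abs(t_stat), df))
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjustment `p_(i) * n / i` with cumulative-minimum monotone
#' enforcement from the largest p value down, capped at 1; input order is
#' preserved.
#'
#' @param p Vector of p values in \[0, 1\].
#' @return Adjusted p values in the original order.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = FALSE)) stop("p values must lie in [0, 1]")
  n <- length(p)
  if (n == 0L) return(numeric())
  ord <- order(p, decreasing = TRUE)
  ranks <- n:1L
  adj <- pmin(1, cummin(n / ranks * p[ord]))
  out <- numeric(n)
  out[ord] <- adj
  out
}

#' Groupwise differential testing with Welch + BH
#'
#' Runs a Welch test per feature (column) between two sample groups and
#' adjusts p values with Benjamini-Hochberg. For compositional inputs
#' (module or taxon relative abundances), apply [clr_transform()] first;
#' `transform = "clr"` does so internally (the default scale for module
#' abundance testing).
#'
#' @param mat Samples x features matrix.
#' @param groups Vector (length nrow) with exactly two distinct labels.
#' @param transform `"clr"` (default) to CLR-transform rows first, or
#'   `"none"`.
#' @return Data.frame with `feature`, `mean_<group1>`, `mean_<group2>`, `t`,
#'   `df`, `p`, `p_bh`, sorted as the input columns.
#' @export
differential_test <- function(mat, groups, transform = c("clr", "none")) {
  transform <- match.arg(transform)
  mat <- as.matrix(mat)
  stopifnot(length(groups) == nrow(mat))
  lv <- unique(groups)
  if (length(lv) != 2L) stop("groups must have exactly two levels")
  if (transform == "clr") mat <- clr_transform(mat)
  res <- lapply(seq_len(ncol(mat)), function(j) {
    x <- mat[groups == lv[1], j]
    y <- mat[groups == lv[2], j]
    w <- welch_test(x, y)
    data.frame(feature = colnames(mat)[j] %||% as.character(j),
               mean_1 = mean(x), mean_2 = mean(y),
               t = w$t, df = w$df, p = w$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  names(out)[2:3] <- paste0("mean_", lv)
  out$p_bh <- bh_adjust(out$p)
  out
}
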