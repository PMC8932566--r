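#' Pre-cluster genomes into connected components of the ANI graph
#'
#' Genomes joined directly or transitively by a reported ANI edge (>= 0.8 by
#' default upstream) fall into one pre-cluster; genomes without any edge
#' become singleton components. Exact hierarchical clustering then runs per
#' component, never across components.
#'
#' @param edges Data.frame with columns `id_a`, `id_b` (see
#'   [ani_all_vs_all()]); self-loops are not allowed.
#' @param all_ids Character vector of every genome id under consideration.
#' @return List of character vectors (components), each sorted; singletons
#'   included.
#' @export
precluster_components <- function(edges, all_ids) {
  stopifnot(is.character(all_ids), !anyDuplicated(all_ids))
  if (nrow(edges)) {
    unknown <- setdiff(c(edges$id_a, edges$id_b), all_ids)
    if (length(unknown))
      stop("edge references unknown genome id(s): ",
           paste(unknown, collapse = ", "))
    if (any(edges$id_a == edges$id_b)) stop("self-loop in ANI graph")
  }
  g <- igraph::graph_from_data_frame(
    edges[, c("id_a", "id_b")], directed = FALSE,
    vertices = data.frame(name = all_ids, stringsAsFactors = FALSE))
  comp <- igraph::components(g)
  unname(lapply(split(all_ids, comp$membership[all_ids]), sort))
}

#' Group one pre-cluster into species by average-linkage clustering
#'
#' Pairwise distances are d = 1 - ANI. Pairs missing from `ani` (below the
#' 0.8 reporting floor) are imputed at d = 0.3, comfortably above any cut so
#' that sub-floor similarity never drives a merge. The dendrogram is cut so
#' that genomes merged strictly below d = 1 - `ani_threshold` share a species
#' ("ANI > 95%" is a strict inequality; the cut height is 1 - threshold minus
#' a 1e-9 epsilon).
#'
#' @param ids Character vector of genome ids in one pre-cluster.
#' @param ani Data.frame with `id_a`, `id_b`, `ani` restricted to (or a
#'   superset of) pairs among `ids`.
#' @param ani_threshold Species threshold, default 0.95.
#' @return List of character vectors, one per species, each sorted.
#' @export
average_linkage_species <- function(ids, ani, ani_threshold = 0.95) {
  stopifnot(length(ids) >= 1L, !anyDuplicated(ids),
            ani_threshold > 0, ani_threshold < 1)
  if (length(ids) == 1L) return(list(ids))
  d <- matrix(0.3, length(ids), length(ids), dimnames = list(ids, ids))
  diag(d) <- 0
  keep <- ani$id_a %in% ids & ani$id_b %in% ids
  if (any(keep)) {
    sub <- ani[keep, , drop = FALSE]
    d[cbind(sub$id_a, sub$id_b)] <- 1 - sub$ani
    d[cbind(sub$id_b, sub$id_a)] <- 1 - sub$ani
  }
  hc <- hclust(as.dist(d), method = "average")
  cut_h <- (1 - ani_threshold) - 1e-9
  memb <- cutree(hc, h = cut_h)
  unname(lapply(split(ids, memb), sort))
}

#' Representative selection score
#'
#' Score = quality score + 0.5 * log10(N50) + 100 * isIsolate. The +100
#' isolate term guarantees that an isolate is preferred over any MAG whose
#' quality-plus-contiguity advantage is below 100; the log10 term adds 0.5
#' per decade of N50. (The log base is a declared convention; base 10 keeps
#' the contiguity term in the intended small range.)
#'
#' @param metadata Data.frame with `genome_id`, `completeness`,
#'   `contamination`, `is_isolate`.
#' @param stats Data.frame with `genome_id`, `n50` (n50 >= 1).
#' @return Data.frame with `genome_id`, `score`.
#' @export
#' @examples
#' md <- data.frame(genome_id = "g", completeness = 95, contamination = 1,
#'                  is_isolate = TRUE)
#' st <- data.frame(genome_id = "g", n50 = 1e5)
#' representative_score(md, st)$score # 90 + 2.5 + 100
representative_score <- function(metadata, stats) {
  idx <- match(metadata$genome_id, stats$genome_id)
  if (anyNA(idx))
    stop("no assembly stats for genome(s): ",
         paste(metadata$genome_id[is.na(idx)], collapse = ", "))
  n50v <- stats$n50[idx]
  stopifnot(all(n50v >= 1))
  score <- quality_score(metadata$completeness, metadata$contamination) +
    0.5 * log10(n50v) + 100 * as.numeric(metadata$is_isolate)
  data.frame(genome_id = metadata$genome_id, score = score,
             stringsAsFactors = FALSE)
}

#' Select the representative genome of a species cluster
#'
#' The member with the highest representative score wins; ties break to the
#' lexicographically smallest genome id for determinism.
#'
#' @param members Character vector of member genome ids (non-empty).
#' @param scores Named numeric vector or data.frame (`genome_id`, `score`)
#'   covering every member.
#' @return The representative genome id.
#' @export
select_representative <- function(members, scores) {
  if (length(members) == 0L) stop("empty member list")
  if (is.data.frame(scores))
    scores <- setNames(scores$score, scores$genome_id)
  if (!all(members %in% names(scores)))
    stop("missing score for member(s): ",
         paste(setdiff(members, names(scores)), collapse = ", "))
  s <- scores[members]
  best <- members[s == max(s)]
  sort(best)[1L]
}

#' Dereplicate a genome collection into 95%-ANI species clusters
#'
#' Runs the full catalog-construction chain: quality filtering (N50 > 5000,
#' quality score >= 50), k-mer sketching, all-vs-all ANI with a 0.8 reporting
#' floor, graph pre-clustering, per-component average-linkage clustering at
#' the species threshold, and scored representative selection.
#'
#' @param assemblies List of [genome_assembly()] objects.
#' @param metadata Metadata data.frame covering every assembly
#'   (see [read_genome_metadata()]).
#' @param k,sketch_size,seed Sketching parameters (see [build_sketch()]).
#' @param ani_threshold Species threshold, default 0.95.
#' @param precluster_ani ANI reporting floor / pre-cluster threshold,
#'   default 0.8.
#' @param n50_min,score_min Quality-filter thresholds (see
#'   [assess_quality()]).
#' @return An object of class `species_cluster_set`: a list with
#'   `clusters` (list of species, each with `species_id`,
#'   `representative_id`, `members`, `min_ani`), `assignments` (data.frame
#'   genome_id/species_id/representative), `excluded` (data.frame
#'   genome_id/reason), and the run parameters.
#' @export
dereplicate <- function(assemblies, metadata, k = 21L, sketch_size = 5000L,
                        seed = 42L, ani_threshold = 0.95,
                        precluster_ani = 0.8, n50_min = 5000,
                        score_min = 50) {
  stopifnot(precluster_ani > 0, precluster_ani < ani_threshold,
            ani_threshold < 1)
  ids <- vapply(assemblies, function(a) a$genome_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate genome ids among assemblies")
  names(assemblies) <- ids
  if (!setequal(ids, metadata$genome_id))
    stop("assemblies and metadata cover different genome ids")

  stats <- assembly_stats_table(assemblies)
  qc <- assess_quality(metadata, stats, n50_min = n50_min,
                       score_min = score_min)
  excluded <- qc_exclusion_reasons(qc, metadata, stats, n50_min, score_min)
  keep <- qc$genome_id[qc$passes_filter]

  clusters <- list()
  edges <- data.frame(id_a = character(), id_b = character(),
                      jaccard = numeric(), ani = numeric(),
                      n_common = integer(), stringsAsFactors = FALSE)
  if (length(keep) >= 1L) {
    if (length(keep) >= 2L) {
      sketches <- build_sketches(assemblies[keep], k = k,
                                 sketch_size = sketch_size, seed = seed)
      edges <- ani_all_vs_all(sketches, report_min = precluster_ani)
    }
    comps <- precluster_components(edges, keep)
    species <- unlist(lapply(comps, average_linkage_species, ani = edges,
                             ani_threshold = ani_threshold),
                      recursive = FALSE)
    # deterministic ordering: by first member id
    species <- species[order(vapply(species, `[`, character(1), 1L))]
    scores <- representative_score(metadata[metadata$genome_id %in% keep, ,
                                            drop = FALSE], stats)
    clusters <- lapply(seq_along(species), function(i) {
      mem <- species[[i]]
      list(species_id = sprintf("SP%04d", i),
           representative_id = select_representative(mem, scores),
           members = mem,
           min_ani = min_within_ani(mem, edges))
    })
  }

  assignments <- if (length(clusters)) {
    do.call(rbind, lapply(clusters, function(cl) {
      data.frame(genome_id = cl$members, species_id = cl$species_id,
                 representative_id = cl$representative_id,
                 stringsAsFactors = FALSE)
    }))
  } else {
    data.frame(genome_id = character(), species_id = character(),
               representative_id = character(), stringsAsFactors = FALSE)
  }

  structure(
    list(clusters = clusters, assignments = assignments, excluded = excluded,
         edges = edges, qc = qc, stats = stats,
         params = list(k = k, sketch_size = sketch_size, seed = seed,
                       ani_threshold = ani_threshold,
                       precluster_ani = precluster_ani,
                       n50_min = n50_min, score_min = score_min)),
    class = "species_cluster_set"
  )
}

qc_exclusion_reasons <- function(qc, metadata, stats, n50_min, score_min) {
  failed <- qc[!qc$passes_filter, , drop = FALSE]
  if (!nrow(failed))
    return(data.frame(genome_id = character(), reason = character(),
                      stringsAsFactors = FALSE))
  reason <- vapply(failed$genome_id, function(id) {
    r <- character()
    if (stats$n50[match(id, stats$genome_id)] <= n50_min)
      r <- c(r, sprintf("n50<=%g", n50_min))
    if (failed$quality_score[failed$genome_id == id] < score_min)
      r <- c(r, sprintf("quality_score<%g", score_min))
    if ("passes_chimerism" %in% names(metadata) &&
        !metadata$passes_chimerism[match(id, metadata$genome_id)])
      r <- c(r, "chimerism")
    paste(r, collapse = ";")
  }, character(1))
  data.frame(genome_id = failed$genome_id, reason = unname(reason),
             stringsAsFactors = FALSE)
}

min_within_ani <- function(members, edges) {
  if (length(members) < 2L) return(NA_real_)
  keep <- edges$id_a %in% members & edges$id_b %in% members
  n_pairs <- choose(length(members), 2)
  if (sum(keep) < n_pairs) return(NA_real_) # some pairs below the floor
  min(edges$ani[keep])
}

#' @export
print.species_cluster_set <- function(x, ...) {
  cat(sprintf(
    "<species_cluster_set> %d genome(s) in %d species cluster(s); %d excluded by QC\n",
    nrow(x$assignments), length(x$clusters), nrow(x$excluded)))
  cat(sprintf("  ANI threshold %.2f (pre-cluster floor %.2f), k=%d, s=%d\n",
              x$params$ani_threshold, x$params$precluster_ani,
              x$params$k, x$params$sketch_size))
  invisible(x)
}

#' Species table of a cluster set
#'
#' @param x A `species_cluster_set`.
#' @return Data.frame with `species_id`, `representative_id`, `n_members`,
#'   semicolon-joined `members`, and `min_ani` (NA when some within-cluster
#'   pair fell below the reporting floor).
#' @export
species_table <- function(x) {
  stopifnot(inherits(x, "species_cluster_set"))
  if (!length(x$clusters))
    return(data.frame(species_id = character(), representative_id = character(),
                      n_members = integer(), members = character(),
                      min_ani = numeric(), stringsAsFactors = FALSE))
  do.call(rbind, lapply(x$clusters, function(cl) {
    data.frame(species_id = cl$species_id,
               representative_id = cl$representative_id,
               n_members = length(cl$members),
               members = paste(cl$members, collapse = ";"),
               min_ani = cl$min_ani,
               stringsAsFactors = FALSE)
  }))
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between two partitions of the same items;
#' 1 means identical partitions, 0 is the expectation under random labeling.
#' Used to compare recovered species clusters against simulation truth.
#'
#' @param a,b Vectors of cluster labels of equal length.
#' @return The adjusted Rand index.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2L)
  tab <- table(a, b)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  n2 <- choose(length(a), 2)
  expected <- sum_a * sum_b / n2
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1) # both partitions trivial
  (sum_ij - expected) / (max_index - expected)
}
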