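# Independent brute-force oracles used to validate the package's clustering
# and graph code, plus small fixture builders. These deliberately do not call
# the code paths they check.

# naive agglomerative average-linkage clustering on a distance matrix:
# repeatedly merge the closest pair of clusters (average of all original
# pairwise distances; ties broken by smallest cluster indices) while the
# minimum average distance does not exceed `cut`
naive_average_linkage <- function(d, cut) {
  stopifnot(is.matrix(d), !is.null(rownames(d)))
  clusters <- as.list(rownames(d))
  while (length(clusters) > 1L) {
    best <- NULL
    best_d <- Inf
    for (i in seq_len(length(clusters) - 1L)) {
      for (j in seq.int(i + 1L, length(clusters))) {
        avg <- mean(d[clusters[[i]], clusters[[j]]])
        if (avg < best_d - 1e-12) {
          best_d <- avg
          best <- c(i, j)
        }
      }
    }
    if (best_d > cut) break
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  unname(lapply(clusters, sort))
}

# union-find connected components
uf_components <- function(ids, edges) {
  parent <- setNames(ids, ids)
  find <- function(x) {
    while (parent[[x]] != x) {
      parent[[x]] <<- parent[[parent[[x]]]]
      x <- parent[[x]]
    }
    x
  }
  if (nrow(edges)) {
    for (r in seq_len(nrow(edges))) {
      ra <- find(edges$id_a[r])
      rb <- find(edges$id_b[r])
      if (ra != rb) parent[[ra]] <- rb
    }
  }
  roots <- vapply(ids, find, character(1))
  unname(lapply(split(ids, roots), sort))
}

# canonical form of a partition (list of sorted id vectors) for set equality
canonical_partition <- function(p) {
  p <- lapply(p, sort)
  p[order(vapply(p, `[`, character(1), 1L))]
}

# random ANI edge list over n genomes: pairs present with prob p_edge carry
# an ANI uniform in [ani_lo, ani_hi]; others fall below the reporting floor
random_ani_instance <- function(n, p_edge = 0.6, ani_lo = 0.9, ani_hi = 1) {
  ids <- sprintf("g%02d", seq_len(n))
  pairs <- t(combn(ids, 2))
  keep <- runif(nrow(pairs)) < p_edge
  edges <- data.frame(id_a = pairs[keep, 1], id_b = pairs[keep, 2],
                      ani = runif(sum(keep), ani_lo, ani_hi),
                      stringsAsFactors = FALSE)
  list(ids = ids, edges = edges)
}

# distance matrix matching the package's imputation contract
ani_to_dist <- function(ids, edges, missing_d = 0.3) {
  d <- matrix(missing_d, length(ids), length(ids),
              dimnames = list(ids, ids))
  diag(d) <- 0
  if (nrow(edges)) {
    d[cbind(edges$id_a, edges$id_b)] <- 1 - edges$ani
    d[cbind(edges$id_b, edges$id_a)] <- 1 - edges$ani
  }
  d
}

# one-contig assembly from a raw string
asm1 <- function(seq, id = "g", isolate = FALSE) {
  genome_assembly(id, setNames(seq, paste0(id, "_c1")), is_isolate = isolate)
}

# write a small FASTA fixture
write_fasta_text <- function(lines, path = tempfile(fileext = ".fasta")) {
  writeLines(lines, path)
  path
}
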