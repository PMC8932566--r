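test_that("pre-clustering yields connected components with singletons", {
  edges <- data.frame(id_a = c("A", "B"), id_b = c("B", "C"),
                      stringsAsFactors = FALSE)
  comps <- precluster_components(edges, c("A", "B", "C", "D"))
  expect_setequal(vapply(comps, paste, character(1), collapse = ","),
                  c("A,B,C", "D"))
  none <- precluster_components(edges[0, ], c("A", "B"))
  expect_equal(lengths(none), c(1L, 1L))
  expect_error(precluster_components(
    data.frame(id_a = "A", id_b = "Z"), c("A", "B")), "unknown")
  expect_error(precluster_components(
    data.frame(id_a = "A", id_b = "A"), c("A", "B")), "self-loop")
})

test_that("components match a union-find oracle on random graphs", {
  set.seed(101)
  for (rep in 1:5) {
    n <- 50
    ids <- sprintf("n%02d", 1:n)
    m <- sample(20:60, 1)
    edges <- data.frame(id_a = sample(ids, m, TRUE),
                        id_b = sample(ids, m, TRUE),
                        stringsAsFactors = FALSE)
    edges <- edges[edges$id_a != edges$id_b, ]
    got <- canonical_partition(precluster_components(edges, ids))
    want <- canonical_partition(uf_components(ids, edges))
    expect_identical(got, want)
  }
})

test_that("average linkage reproduces hand-executed merges at the 0.95 cut", {
  # all pairwise ANI 0.97: one cluster
  e <- data.frame(id_a = c("A", "A", "B"), id_b = c("B", "C", "C"),
                  ani = rep(0.97, 3), stringsAsFactors = FALSE)
  expect_equal(average_linkage_species(c("A", "B", "C"), e), list(c("A", "B", "C")))
  # A,B merge at d 0.02; d({A,B},C) = mean(0.06, 0.06) = 0.06 > 0.05: split
  e <- data.frame(id_a = c("A", "A", "B"), id_b = c("B", "C", "C"),
                  ani = c(0.98, 0.94, 0.94), stringsAsFactors = FALSE)
  expect_equal(canonical_partition(average_linkage_species(c("A", "B", "C"), e)),
               list(c("A", "B"), "C"))
  # A,B merge at 0.04; d({A,B},C) = 0.045 <= 0.05: one species
  e <- data.frame(id_a = c("A", "A", "B"), id_b = c("B", "C", "C"),
                  ani = c(0.96, 0.955, 0.955), stringsAsFactors = FALSE)
  expect_equal(average_linkage_species(c("A", "B", "C"), e),
               list(c("A", "B", "C")))
  # singleton input stays a singleton cluster
  expect_equal(average_linkage_species("A", e[0, ]), list("A"))
})

test_that("missing pairs are imputed at distance 0.3 and never merge", {
  # A-B reported at 0.99; A-C and B-C below the floor (absent)
  e <- data.frame(id_a = "A", id_b = "B", ani = 0.99, stringsAsFactors = FALSE)
  got <- canonical_partition(average_linkage_species(c("A", "B", "C"), e))
  expect_equal(got, list(c("A", "B"), "C"))
})

test_that("average linkage equals brute-force agglomeration up to 12 genomes", {
  set.seed(202)
  for (rep in 1:25) {
    n <- sample(3:12, 1)
    inst <- random_ani_instance(n)
    got <- canonical_partition(
      average_linkage_species(inst$ids, inst$edges, ani_threshold = 0.95))
    d <- ani_to_dist(inst$ids, inst$edges)
    want <- canonical_partition(naive_average_linkage(d, 0.05 - 1e-9))
    expect_identical(got, want)
  }
})

test_that("raising the ANI threshold never decreases the cluster count", {
  set.seed(303)
  for (rep in 1:10) {
    inst <- random_ani_instance(10, ani_lo = 0.9, ani_hi = 1)
    sizes <- vapply(c(0.93, 0.95, 0.97, 0.99), function(th)
      length(average_linkage_species(inst$ids, inst$edges,
                                     ani_threshold = th)), numeric(1))
    expect_true(all(diff(sizes) >= 0))
  }
})

test_that("representative score follows quality + 0.5 log10(N50) + 100 isolate", {
  md <- data.frame(genome_id = c("iso", "mag1", "mag10x"),
                   completeness = c(90, 90, 90), contamination = 0,
                   is_isolate = c(TRUE, FALSE, FALSE))
  st <- data.frame(genome_id = c("iso", "mag1", "mag10x"),
                   n50 = c(1e5, 1, 10))
  sc <- representative_score(md, st)
  expect_equal(sc$score[sc$genome_id == "iso"], 90 + 2.5 + 100)
  expect_equal(sc$score[sc$genome_id == "mag1"], 90) # log10(1) = 0
  # one decade of N50 adds exactly 0.5
  expect_equal(sc$score[sc$genome_id == "mag10x"] -
                 sc$score[sc$genome_id == "mag1"], 0.5)
})

test_that("representative selection prefers isolates and breaks ties by id", {
  md <- data.frame(genome_id = c("iso", "mag"),
                   completeness = c(60, 95), contamination = 0,
                   is_isolate = c(TRUE, FALSE))
  st <- data.frame(genome_id = c("iso", "mag"), n50 = c(5000, 1e7))
  sc <- representative_score(md, st)
  expect_identical(select_representative(c("iso", "mag"), sc), "iso")
  expect_identical(select_representative("mag", sc), "mag")
  expect_identical(select_representative(c("b", "a"), c(a = 1, b = 1)), "a")
  expect_error(select_representative(character(), sc), "empty")
  expect_error(select_representative(c("iso", "unknown"), sc), "missing score")
})

test_that("dereplicate handles the trivial and degenerate worlds", {
  set.seed(7)
  s <- paste(sample(c("A", "C", "G", "T"), 3e4, TRUE), collapse = "")
  asm <- asm1(s, "only")
  md <- data.frame(genome_id = "only", completeness = 95, contamination = 0,
                   is_isolate = FALSE)
  res <- dereplicate(list(asm), md)
  expect_equal(length(res$clusters), 1L)
  expect_identical(res$clusters[[1]]$representative_id, "only")
  expect_identical(res$clusters[[1]]$members, "only")

  # all genomes failing QC: empty cluster set, all excluded
  md_bad <- md; md_bad$completeness <- 20
  res <- dereplicate(list(asm), md_bad)
  expect_equal(length(res$clusters), 0L)
  expect_equal(nrow(res$assignments), 0L)
  expect_identical(res$excluded$genome_id, "only")
})

test_that("dereplicate recovers simulated species exactly (5 species x 3 strains)", {
  sim <- simulate_catalog(n_species = 5, strains_per_species = 3,
                          within_species_ani = 0.98,
                          between_species_ani = 0.85, seed = 11)
  expect_equal(length(sim$assemblies), 15L)
  res <- dereplicate(sim$assemblies, sim$metadata, seed = 11)
  kept <- res$assignments$genome_id
  truth <- sim$truth$species[match(kept, sim$truth$genome_id)]
  # partition property: disjoint cover, representative is a member
  expect_false(anyDuplicated(kept) > 0)
  expect_setequal(kept, res$qc$genome_id[res$qc$passes_filter])
  for (cl in res$clusters)
    expect_true(cl$representative_id %in% cl$members)
  # one cluster per simulated species among QC-passing genomes
  expect_equal(length(res$clusters), length(unique(truth)))
  expect_equal(adjusted_rand_index(res$assignments$species_id, truth), 1)
  # excluded + assigned = all inputs
  expect_setequal(c(kept, res$excluded$genome_id), names(sim$assemblies))
})

test_that("adjusted Rand index behaves at its reference points", {
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c("a", "a", "b", "b")), 1)
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(1, 2, 1, 2)), -0.5)
  expect_lt(abs(adjusted_rand_index(rep(1:2, 50), rep(1:2, each = 50))), 0.2)
})
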