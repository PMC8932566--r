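test_that("mapping rate is attributed reads over total reads", {
  counts <- matrix(c(60, 30, 0, 0, 50, 50), nrow = 3, byrow = TRUE,
                   dimnames = list(c("s1", "s2", "s3"), c("t1", "t2")))
  totals <- c(s1 = 100, s2 = 80, s3 = 100)
  expect_equal(mapping_rate(counts, totals, "s1"), 0.9)
  expect_equal(mapping_rate(counts, totals, "s2"), 0)
  expect_equal(mapping_rate(counts, totals, "s3"), 1)
  expect_error(mapping_rate(counts, totals[1:2], "s3"), "missing total_reads")
  expect_error(mapping_rate(counts, c(s1 = 50), "s1"), "below attributed")
})

test_that("multiplicative replacement preserves closure", {
  expect_equal(multiplicative_replace(c(0.5, 0.5)), c(0.5, 0.5))
  expect_equal(multiplicative_replace(c(1, 0), delta = 1 / 4), c(0.75, 0.25))
  # default delta is 1/N^2
  out <- multiplicative_replace(c(1, 0, 0, 0))
  expect_equal(out[2], 1 / 16)
  expect_equal(sum(out), 1)
  expect_true(all(out > 0))
  expect_error(multiplicative_replace(c(0, 0)), "closure impossible")
  expect_error(multiplicative_replace(c(1, 0, 0), delta = 0.6), "delta too large")
})

test_that("CLR transform: uniform rows, two-part closed form, zero row sums", {
  expect_equal(unname(clr_transform(matrix(c(1, 1, 1, 1), 1))[1, ]),
               rep(0, 4))
  expect_equal(unname(clr_transform(matrix(c(4, 1), 1))[1, ]),
               c(log(2), -log(2)))
  set.seed(31)
  counts <- matrix(rpois(60, 40), nrow = 6,
                   dimnames = list(paste0("s", 1:6), paste0("t", 1:10)))
  counts[sample(60, 8)] <- 0
  clr <- clr_transform(counts)
  expect_true(all(abs(rowSums(clr)) < 1e-9))
  # invariance to scaling a row's counts by a positive constant
  expect_equal(clr_transform(counts * 7), clr)
  expect_error(clr_transform(counts[0, , drop = FALSE]), "empty")
})

test_that("aggregation sums counts within rank names and conserves totals", {
  tab <- simulate_taxonomy(n_ref_families = 2, n_shared_families = 1,
                           n_ref_genera = 2, n_shared_genera = 1,
                           n_ref_species = 4, n_shared_species = 1,
                           n_other_extra_families = 1, n_other_extra_genera = 1)
  tax <- build_catalog_taxonomy(tab[tab$host == "mouse", ])
  counts <- matrix(c(3, 4, 5, 6, 1, 2, 3, 4), nrow = 2, byrow = TRUE,
                   dimnames = list(c("s1", "s2"), tax$species_id))
  gen <- aggregate_by_taxon(counts, tax, "genus")
  expect_equal(rowSums(gen), rowSums(counts)) # conservation
  # two species share genus 1 and genus 2 alternately (round-robin)
  g1 <- tax$genus[1]
  expect_equal(unname(gen[, g1]), unname(counts[, 1] + counts[, 3]))
  # identity at species rank
  sp <- aggregate_by_taxon(counts, tax, "species")
  expect_equal(unname(sp), unname(counts))
  bad <- counts; colnames(bad)[1] <- "mystery"
  expect_error(aggregate_by_taxon(bad, tax, "genus"), "missing lineage")
})

test_that("mean-abundance correlation imputes the host minimum for absences", {
  a <- c(t1 = 1, t2 = 2, t3 = 3)
  expect_equal(mean_abundance_correlation(a, a), 1)
  b <- c(t1 = 3, t2 = 2, t3 = 1)
  expect_equal(mean_abundance_correlation(a, b), -1)
  # t4 absent from a: imputed at min(a) = 1
  b4 <- c(t1 = 1, t2 = 2, t3 = 3, t4 = 4)
  r <- mean_abundance_correlation(a, b4)
  expect_equal(r, cor(c(1, 2, 3, 1), c(1, 2, 3, 4)))
  expect_error(mean_abundance_correlation(c(t1 = 1, t2 = 2), c(t1 = 1, t2 = 2)),
               "degenerate")
  # recovers a known correlation from sampled data
  set.seed(47)
  n <- 200
  x <- rnorm(n)
  y <- 0.5 * x + sqrt(1 - 0.25) * rnorm(n)
  names(x) <- names(y) <- paste0("t", 1:n)
  expect_lt(abs(mean_abundance_correlation(x, y) - 0.5), 0.15)
})

test_that("module presence uses the inclusive three-quarters rule", {
  expect_true(module_present(3, 4))
  expect_false(module_present(2, 4))
  expect_true(module_present(6, 8)) # exactly 0.75 counts as present
  expect_true(module_present(5, 5))
  expect_error(module_present(5, 4))
})

test_that("module abundance sums relative abundances of carrying genomes", {
  rel <- c(g1 = 0.2, g2 = 0.3, g3 = 0.5)
  expect_equal(module_abundance(c(g1 = TRUE, g2 = FALSE, g3 = TRUE), rel), 0.7)
  expect_equal(module_abundance(c(g1 = FALSE, g2 = FALSE, g3 = FALSE), rel), 0)
  expect_equal(module_abundance(c(g1 = TRUE, g2 = TRUE, g3 = TRUE), rel), 1)
  # additive over disjoint genome sets
  p1 <- c(g1 = TRUE, g2 = FALSE, g3 = FALSE)
  p2 <- c(g1 = FALSE, g2 = FALSE, g3 = TRUE)
  expect_equal(module_abundance(p1 | p2, rel),
               module_abundance(p1, rel) + module_abundance(p2, rel))
})

test_that("module abundance table combines step coverage with counts", {
  cov <- data.frame(genome_id = c("g1", "g2", "g1", "g2"),
                    module_id = c("M1", "M1", "M2", "M2"),
                    steps_present = c(4, 1, 0, 3),
                    steps_total = c(4, 4, 3, 3))
  counts <- matrix(c(80, 20, 50, 50), nrow = 2, byrow = TRUE,
                   dimnames = list(c("s1", "s2"), c("g1", "g2")))
  ab <- module_abundance_table(cov, counts)
  expect_equal(unname(ab[, "M1"]), c(0.8, 0.5)) # only g1 carries M1
  expect_equal(unname(ab[, "M2"]), c(0.2, 0.5)) # only g2 carries M2
  expect_error(module_abundance_table(cov[, -1], counts), "lacks column")
})

test_that("Welch test matches the textbook formula and its oracle", {
  w <- welch_test(c(1, 2, 3, 4), c(2, 3, 4, 5))
  # frozen from an independent evaluation of the Welch formulas
  expect_equal(w$t, -1.095445, tolerance = 1e-6)
  expect_equal(w$df, 6, tolerance = 1e-6)
  expect_equal(w$p, 0.315334, tolerance = 1e-5)
  # cross-check against stats::t.test on random draws
  set.seed(53)
  for (i in 1:10) {
    x <- rnorm(sample(3:12, 1), sd = runif(1, 0.5, 2))
    y <- rnorm(sample(3:12, 1), mean = runif(1, -1, 1))
    tt <- stats::t.test(x, y)
    w <- welch_test(x, y)
    expect_equal(w$t, unname(tt$statistic))
    expect_equal(w$df, unname(tt$parameter))
    expect_equal(w$p, tt$p.value)
  }
  # identical groups: zero statistic, p = 1
  expect_equal(welch_test(c(1, 2, 3), c(1, 2, 3))[c("t", "p")],
               list(t = 0, p = 1))
  expect_equal(welch_test(c(2, 2), c(2, 2))$p, 1) # constant equal groups
  expect_error(welch_test(1, c(1, 2)), "at least 2")
})

test_that("BH adjustment is step-up with monotone enforcement", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(59)
  for (i in 1:10) {
    p <- runif(sample(1:40, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, p.adjust(p, method = "BH"))
    expect_true(all(adj >= p))
    # permutation equivariance
    perm <- sample(length(p))
    expect_equal(bh_adjust(p[perm]), adj[perm])
  }
})

test_that("differential testing finds a planted 2-fold shift via CLR + Welch + BH", {
  hits <- vapply(1:10, function(s) {
    set.seed(s)
    base <- rep(1 / 20, 20)
    shifted <- base; shifted[5] <- 2 * shifted[5]
    shifted <- shifted / sum(shifted)
    sim <- simulate_counts(rbind(ctrl = base, treat = shifted),
                           depth = 1e5, n_samples = 10)
    res <- differential_test(sim$counts, sim$groups)
    which.min(res$p_bh) == 5L
  }, logical(1))
  expect_gte(sum(hits), 9L)
})
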