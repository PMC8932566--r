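#' Simulate an ancestral genome sequence
#'
#' Draws i.i.d. bases with the requested GC content. Deterministic for a
#' given seed; with `seed = NULL` the current RNG state is used (so callers
#' like [simulate_catalog()] control determinism with one outer seed).
#'
#' @param length Sequence length in bp (>= 1000).
#' @param gc GC fraction, strictly between 0 and 1.
#' @param seed Integer seed or `NULL`.
#' @return A [genome_assembly()] with a single contig.
#' @export
simulate_ancestor <- function(length, gc = 0.5, seed = NULL) {
  stopifnot(length >= 1000, gc > 0, gc < 1)
  if (!is.null(seed)) set.seed(seed)
  probs <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  seq <- paste(sample(c("A", "C", "G", "T"), length, replace = TRUE,
                      prob = probs), collapse = "")
  genome_assembly(sprintf("ancestor_%dbp", length), c(anc_c1 = seq),
                  source_label = "simulated")
}

#' Mutate a sequence to a target per-site identity
#'
#' Substitutes each ACGT position independently with probability
#' 1 - `target_ani` to a uniformly chosen different base (no indels, no back
#' mutation at a site; N positions are left untouched). The expected identity
#' to the input is exactly `target_ani`.
#'
#' @param seq A DNA string (single contig).
#' @param target_ani Target identity in \[0.7, 1).
#' @param seed Integer seed or `NULL`.
#' @return The mutated DNA string, same length.
#' @export
mutate_to_ani <- function(seq, target_ani, seed = NULL) {
  stopifnot(is.character(seq), length(seq) == 1L,
            target_ani >= 0.7, target_ani < 1)
  if (!is.null(seed)) set.seed(seed)
  bases <- c("A", "C", "G", "T")
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  code <- match(chars, bases) # NA for N
  hit <- which(!is.na(code) & runif(length(chars)) < 1 - target_ani)
  if (length(hit)) {
    code[hit] <- (code[hit] - 1L + sample(1:3, length(hit),
                                          replace = TRUE)) %% 4L + 1L
    chars[hit] <- bases[code[hit]]
  }
  paste(chars, collapse = "")
}

#' Per-branch identity giving a target pairwise identity between two mutants
#'
#' Two sequences independently mutated from one ancestor with per-site
#' retention a agree at a site with probability a^2 + (1 - a)^2 / 3 (both
#' kept, or both mutated to the same of three bases). Inverting gives
#' a = (1 + sqrt(12 p - 3)) / 4 for a target pairwise identity p.
#'
#' @param pairwise Target pairwise identity (> 0.25).
#' @return The per-branch retention to pass to [mutate_to_ani()].
#' @export
branch_identity <- function(pairwise) {
  stopifnot(pairwise > 0.25, pairwise <= 1)
  (1 + sqrt(12 * pairwise - 3)) / 4
}

#' Fragment a sequence into contigs with a target N50
#'
#' Cuts the sequence at random positions (exponential fragment lengths whose
#' mean is calibrated so that the length-weighted median ~ target) and
#' retries until the realized N50 falls within \[0.5, 2\] x target. No bases
#' are lost or duplicated: the contigs concatenate back to the input. A
#' target above half the sequence length returns the sequence as a single
#' contig; a target above the sequence length is infeasible.
#'
#' @param seq A DNA string.
#' @param target_n50 Target N50 in bp.
#' @param genome_id Id for the resulting assembly.
#' @param seed Integer seed or `NULL`.
#' @param max_tries Resampling attempts before giving up.
#' @return A [genome_assembly()].
#' @export
fragment_to_n50 <- function(seq, target_n50, genome_id = "fragmented",
                            seed = NULL, max_tries = 100L) {
  stopifnot(is.character(seq), length(seq) == 1L)
  len <- nchar(seq)
  if (target_n50 <= 0 || target_n50 > len)
    stop("infeasible target N50 (", target_n50, ") for length ", len)
  if (!is.null(seed)) set.seed(seed)
  if (target_n50 > len / 2)
    return(genome_assembly(genome_id, c(c1 = seq),
                           source_label = "simulated"))
  # length-biased median of Exp(mean m) fragments is ~1.678 m
  mean_frag <- target_n50 / 1.678
  for (i in seq_len(max_tries)) {
    lens <- numeric()
    while (sum(lens) < len)
      lens <- c(lens, pmax(1, round(stats::rexp(64, 1 / mean_frag))))
    over <- cumsum(lens) >= len
    lens <- lens[seq_len(which(over)[1])]
    lens[length(lens)] <- len - sum(lens[-length(lens)])
    lens <- lens[lens >= 1]
    realized <- n50(lens)
    if (realized >= 0.5 * target_n50 && realized <= 2 * target_n50) {
      ends <- cumsum(lens)
      starts <- c(1, head(ends, -1) + 1)
      contigs <- substring(seq, starts, ends)
      names(contigs) <- sprintf("%s_c%03d", genome_id, seq_along(contigs))
      return(genome_assembly(genome_id, contigs, source_label = "simulated"))
    }
  }
  stop("could not realize N50 within [0.5, 2] x ", target_n50,
       " after ", max_tries, " tries")
}

#' Simulate a genome catalog with known species truth labels
#'
#' Generates `n_species` ancestor genomes whose pairwise identity is at most
#' `between_species_ani` (derived from a shared root when the bound is >=
#' 0.75, so that pre-clustering is exercised; independent otherwise, and
#' rejection-checked with the exact k-mer Jaccard oracle on a subsample of
#' pairs). Each species contributes 2-5 strains (uniform in
#' `strains_per_species`) mutated so that within-species pairwise identity
#' equals `within_species_ani`, then fragmented to `target_n50`. Metadata
#' draws completeness uniformly in `completeness_range` and contamination in
#' `contamination_range`; with probability `isolate_prob` one strain per
#' species is flagged as an isolate. Fully deterministic under `seed`.
#'
#' @param n_species Number of species.
#' @param strains_per_species Length-2 integer range (or single count).
#' @param genome_length Ancestor length in bp.
#' @param within_species_ani Target pairwise identity among strains of one
#'   species (> 0.95).
#' @param between_species_ani Upper bound on pairwise identity between
#'   species (< 0.95).
#' @param target_n50 Fragmentation target (default 20000 so that simulated
#'   genomes pass the N50 > 5000 filter).
#' @param gc GC fraction of the root sequence.
#' @param isolate_prob Probability that a species has one isolate strain.
#' @param completeness_range,contamination_range Uniform metadata ranges
#'   (percent).
#' @param seed Integer seed.
#' @param max_retries Ancestor-set rejection retries.
#' @return List with `assemblies` (named list of [genome_assembly()]),
#'   `metadata` (data.frame), `truth` (data.frame genome_id/species), and
#'   `params`.
#' @export
simulate_catalog <- function(n_species = 20L, strains_per_species = c(2L, 5L),
                             genome_length = 1e5, within_species_ani = 0.97,
                             between_species_ani = 0.90, target_n50 = 20000,
                             gc = 0.5, isolate_prob = 0.3,
                             completeness_range = c(60, 100),
                             contamination_range = c(0, 8),
                             seed = 1L, max_retries = 5L) {
  stopifnot(n_species >= 1L, within_species_ani > 0.95,
            between_species_ani < 0.95,
            genome_length >= 1000)
  if (length(strains_per_species) == 1L)
    strains_per_species <- rep(strains_per_species, 2L)
  set.seed(seed)

  ancestors <- simulate_species_ancestors(n_species, genome_length, gc,
                                          between_species_ani, max_retries)
  a_within <- branch_identity(within_species_ani)

  assemblies <- list()
  md_rows <- list()
  truth_rows <- list()
  for (sp in seq_len(n_species)) {
    n_str <- if (strains_per_species[1] == strains_per_species[2])
               strains_per_species[1]
             else sample(strains_per_species[1]:strains_per_species[2], 1L)
    iso_strain <- if (runif(1) < isolate_prob) sample(n_str, 1L) else 0L
    for (j in seq_len(n_str)) {
      gid <- sprintf("sp%02d_g%02d", sp, j)
      seq <- mutate_to_ani(ancestors[[sp]], a_within)
      asm <- fragment_to_n50(seq, target_n50, genome_id = gid)
      asm$is_isolate <- (j == iso_strain)
      assemblies[[gid]] <- asm
      md_rows[[gid]] <- data.frame(
        genome_id = gid,
        completeness = runif(1, completeness_range[1], completeness_range[2]),
        contamination = runif(1, contamination_range[1],
                              contamination_range[2]),
        is_isolate = (j == iso_strain),
        stringsAsFactors = FALSE)
      truth_rows[[gid]] <- data.frame(genome_id = gid,
                                      species = sprintf("species%02d", sp),
                                      stringsAsFactors = FALSE)
    }
  }
  list(assemblies = assemblies,
       metadata = do.call(rbind, c(md_rows, list(make.row.names = FALSE))),
       truth = do.call(rbind, c(truth_rows, list(make.row.names = FALSE))),
       params = list(n_species = n_species,
                     strains_per_species = strains_per_species,
                     genome_length = genome_length,
                     within_species_ani = within_species_ani,
                     between_species_ani = between_species_ani,
                     target_n50 = target_n50, seed = seed))
}

# ancestors at pairwise identity <= bound; derived from a shared root when
# the bound is high enough to matter for the 0.8 pre-clustering floor
simulate_species_ancestors <- function(n_species, genome_length, gc,
                                       between_bound, max_retries) {
  for (attempt in seq_len(max_retries)) {
    if (between_bound >= 0.75 && n_species > 1L) {
      root <- simulate_ancestor(genome_length, gc)$contigs[[1]]
      a_between <- branch_identity(between_bound)
      anc <- replicate(n_species, mutate_to_ani(root, a_between))
    } else {
      anc <- replicate(n_species,
                       simulate_ancestor(genome_length, gc)$contigs[[1]])
    }
    if (check_between_bound(anc, between_bound)) return(anc)
  }
  stop("could not generate ancestors below the between-species ANI bound")
}

# exact-oracle spot check on up to 3 ancestor pairs (0.01 measurement margin)
check_between_bound <- function(anc, bound) {
  n <- length(anc)
  if (n < 2L) return(TRUE)
  pairs <- utils::combn(n, 2)
  take <- pairs[, seq_len(min(3L, ncol(pairs))), drop = FALSE]
  for (m in seq_len(ncol(take))) {
    i <- take[1, m]; j <- take[2, m]
    ai <- genome_assembly("a", c(c1 = anc[[i]]))
    aj <- genome_assembly("b", c(c1 = anc[[j]]))
    ani <- ani_from_jaccard(exact_jaccard(ai, aj, k = 21L), 21L)
    if (ani > bound + 0.01) return(FALSE)
  }
  TRUE
}

#' Simulate a multi-sample count table by multinomial sampling
#'
#' @param compositions Either a named numeric vector (one group) or a
#'   groups x taxa matrix with group labels as row names; each composition
#'   must sum to 1.
#' @param depth Reads per sample.
#' @param n_samples Samples per group.
#' @param seed Integer seed or `NULL`.
#' @return List with `counts` (samples x taxa matrix) and `groups`
#'   (character vector of group labels per sample).
#' @export
simulate_counts <- function(compositions, depth = 1e5, n_samples = 10L,
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(dim(compositions)))
    compositions <- matrix(compositions, nrow = 1,
                           dimnames = list("group1", names(compositions)))
  stopifnot(all(abs(rowSums(compositions) - 1) < 1e-8))
  if (is.null(rownames(compositions)))
    rownames(compositions) <- paste0("group", seq_len(nrow(compositions)))
  if (is.null(colnames(compositions)))
    colnames(compositions) <- paste0("taxon", seq_len(ncol(compositions)))
  counts <- NULL
  groups <- character()
  for (g in rownames(compositions)) {
    draws <- t(rmultinom(n_samples, size = depth, prob = compositions[g, ]))
    rownames(draws) <- sprintf("%s_s%02d", g, seq_len(n_samples))
    counts <- rbind(counts, draws)
    groups <- c(groups, rep(g, n_samples))
  }
  colnames(counts) <- colnames(compositions)
  list(counts = counts, groups = groups)
}

#' Synthetic two-host taxonomy table with controlled overlap margins
#'
#' Builds a GTDB-style lineage table for a reference ("mouse") and another
#' ("human") catalog whose rank-level overlap margins are exactly the
#' requested counts: `n_ref_*` taxa exist in the reference host, of which
#' `n_shared_*` also occur in the other host (shared species are both
#' name-matched and flagged). This is a synthetic stand-in, generated in
#' code, for a curated cross-host taxonomy table; it reproduces marginal
#' counts only, not real taxon names. Nesting is consistent: shared genera
#' lie in shared families and shared species in shared genera.
#'
#' @param n_ref_families,n_shared_families Family margin (default 109/88).
#' @param n_ref_genera,n_shared_genera Genus margin (default 412/255).
#' @param n_ref_species,n_shared_species Species margin (default 1573/170).
#' @param n_other_extra_families,n_other_extra_genera Other-host-only taxa.
#' @return Data.frame with `species_id`, `host`, `lineage`, `shared`,
#'   suitable for [build_catalog_taxonomy()] after splitting by host.
#' @export
simulate_taxonomy <- function(n_ref_families = 109L, n_shared_families = 88L,
                              n_ref_genera = 412L, n_shared_genera = 255L,
                              n_ref_species = 1573L, n_shared_species = 170L,
                              n_other_extra_families = 21L,
                              n_other_extra_genera = 157L) {
  stopifnot(n_shared_families <= n_ref_families,
            n_shared_genera <= n_ref_genera,
            n_shared_species <= n_ref_species,
            n_shared_genera >= n_shared_families,
            n_shared_species <= n_shared_genera * 100L)

  fam <- sprintf("Family%03d", seq_len(n_ref_families)) # first n_shared shared
  fam_phylum <- sprintf("Phylum%02d", (seq_len(n_ref_families) - 1L) %% 16L + 1L)

  # genera: shared ones round-robin over shared families, reference-only over all
  gen_fam_idx <- integer(n_ref_genera)
  gen_fam_idx[seq_len(n_shared_genera)] <-
    (seq_len(n_shared_genera) - 1L) %% n_shared_families + 1L
  if (n_ref_genera > n_shared_genera) {
    rest <- seq.int(n_shared_genera + 1L, n_ref_genera)
    gen_fam_idx[rest] <- (rest - 1L) %% n_ref_families + 1L
  }
  gen <- sprintf("Genus%04d", seq_len(n_ref_genera))

  # species: shared ones round-robin over shared genera, rest over all genera
  sp_gen_idx <- integer(n_ref_species)
  sp_gen_idx[seq_len(n_shared_species)] <-
    (seq_len(n_shared_species) - 1L) %% n_shared_genera + 1L
  if (n_ref_species > n_shared_species) {
    rest <- seq.int(n_shared_species + 1L, n_ref_species)
    sp_gen_idx[rest] <- (rest - 1L) %% n_ref_genera + 1L
  }
  sp_name <- c(sprintf("shared_species_%04d", seq_len(n_shared_species)),
               sprintf("mouse_species_%04d",
                       seq_len(n_ref_species - n_shared_species)))

  lineage_of <- function(fam_i, gen_name, sp_label) {
    ph <- fam_phylum[fam_i]
    paste0("d__Bacteria;p__", ph, ";c__Class_", ph, ";o__Order_", ph,
           ";f__", fam[fam_i], ";g__", gen_name, ";s__", gen_name, " ",
           sp_label)
  }

  ref <- data.frame(
    species_id = sprintf("MSP%04d", seq_len(n_ref_species)),
    host = "mouse",
    lineage = vapply(seq_len(n_ref_species), function(i)
      lineage_of(gen_fam_idx[sp_gen_idx[i]], gen[sp_gen_idx[i]], sp_name[i]),
      character(1)),
    shared = seq_len(n_ref_species) <= n_shared_species,
    stringsAsFactors = FALSE)

  # other host: the shared species by name, one filler species per shared
  # genus, and extra host-only families/genera/species
  other_rows <- list()
  for (i in seq_len(n_shared_species)) {
    other_rows[[length(other_rows) + 1L]] <- c(
      lineage_of(gen_fam_idx[sp_gen_idx[i]], gen[sp_gen_idx[i]], sp_name[i]))
  }
  for (gidx in seq_len(n_shared_genera)) {
    other_rows[[length(other_rows) + 1L]] <- c(
      lineage_of(gen_fam_idx[gidx], gen[gidx],
                 sprintf("human_filler_%04d", gidx)))
  }
  hfam <- sprintf("HumanFamily%03d", seq_len(n_other_extra_families))
  hfam_phylum <- c(sprintf("HumanPhylum%d", seq_len(min(5L, n_other_extra_families))),
                   sprintf("Phylum%02d",
                           seq_len(max(0L, n_other_extra_families - 5L)) %% 16L + 1L))
  for (gidx in seq_len(n_other_extra_genera)) {
    fi <- (gidx - 1L) %% n_other_extra_families + 1L
    ph <- hfam_phylum[fi]
    other_rows[[length(other_rows) + 1L]] <- paste0(
      "d__Bacteria;p__", ph, ";c__Class_", ph, ";o__Order_", ph,
      ";f__", hfam[fi], ";g__HumanGenus", sprintf("%04d", gidx),
      ";s__HumanGenus", sprintf("%04d", gidx), " human_species_",
      sprintf("%04d", gidx))
  }
  other <- data.frame(
    species_id = sprintf("HSP%04d", seq_along(other_rows)),
    host = "human",
    lineage = unlist(other_rows),
    shared = c(rep(TRUE, n_shared_species),
               rep(FALSE, length(other_rows) - n_shared_species)),
    stringsAsFactors = FALSE)

  rbind(ref, other)
}
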