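GTDB_RANKS <- c("domain", "phylum", "class", "order", "family", "genus",
                "species")
GTDB_PREFIXES <- setNames(c("d__", "p__", "c__", "o__", "f__", "g__", "s__"),
                          GTDB_RANKS)
RANK_LETTERS <- setNames(c("d", "p", "c", "o", "f", "g", "s"), GTDB_RANKS)

#' Parse a GTDB-style lineage string
#'
#' A lineage is a semicolon-separated list of rank-prefixed names
#' (`d__`/`p__`/`c__`/`o__`/`f__`/`g__`/`s__`) in fixed rank order. Bare
#' prefixes and missing trailing ranks are recorded as empty. Unknown
#' prefixes and out-of-order ranks are errors.
#'
#' @param s Lineage string, e.g.
#'   `"d__Bacteria;p__Firmicutes_A;c__Clostridia;..."`.
#' @return An object of class `gtdb_lineage`: a list with `ranks` (named
#'   7-vector of names, prefix included, empty string for unnamed) and
#'   `placeholder` (named logical 7-vector).
#' @export
parse_lineage <- function(s) {
  stopifnot(is.character(s), length(s) == 1L)
  fields <- trimws(strsplit(s, ";", fixed = TRUE)[[1]])
  fields <- fields[nzchar(fields) | seq_along(fields) <= length(fields)]
  if (length(fields) > 7L)
    stop("lineage has more than 7 fields: ", s)
  ranks <- setNames(rep("", 7L), GTDB_RANKS)
  last_pos <- 0L
  for (f in fields) {
    prefix <- substring(f, 1, 3)
    pos <- match(prefix, GTDB_PREFIXES)
    if (is.na(pos))
      stop("unknown rank prefix '", prefix, "' in lineage: ", s)
    if (pos <= last_pos)
      stop("ranks out of order in lineage: ", s)
    last_pos <- pos
    if (nchar(f) > 3L) ranks[pos] <- f
  }
  if (!nzchar(ranks["domain"]))
    stop("lineage lacks a domain: ", s)
  structure(list(ranks = ranks,
                 placeholder = setNames(rep(FALSE, 7L), GTDB_RANKS)),
            class = "gtdb_lineage")
}

#' @export
print.gtdb_lineage <- function(x, ...) {
  cat("<gtdb_lineage>", lineage_string(x), "\n")
  invisible(x)
}

#' Render a lineage back to its semicolon-separated string
#'
#' @param lin A `gtdb_lineage`.
#' @return The lineage string (empty ranks rendered as bare prefixes).
#' @export
lineage_string <- function(lin) {
  stopifnot(inherits(lin, "gtdb_lineage"))
  out <- ifelse(nzchar(lin$ranks), lin$ranks, GTDB_PREFIXES)
  paste(out, collapse = ";")
}

#' Fill unnamed ranks with deterministic placeholder names
#'
#' Stands in for manual curation of novel taxa: every empty rank receives the
#' name `<prefix><deepest named ancestor>-<anchor>-<rank letter>` (ancestor
#' name without its own prefix), is flagged as a placeholder, and becomes a
#' taxon private to its catalog — distinct anchors never collide and
#' placeholders never match between catalogs. Filling is idempotent.
#'
#' @param lin A `gtdb_lineage` with non-empty domain.
#' @param anchor_id Identifier (typically the species/representative id) that
#'   makes placeholders unique.
#' @return The filled `gtdb_lineage`.
#' @export
#' @examples
#' lin <- parse_lineage("d__Bacteria;p__Bacteroidota;c__Bacteroidia;o__Bacteroidales;f__Muribaculaceae;g__;s__")
#' fill_placeholders(lin, "SP001")$ranks[["genus"]] # g__Muribaculaceae-SP001-g
fill_placeholders <- function(lin, anchor_id) {
  stopifnot(inherits(lin, "gtdb_lineage"), nzchar(lin$ranks["domain"]),
            is.character(anchor_id), nzchar(anchor_id))
  for (i in seq_along(GTDB_RANKS)) {
    if (nzchar(lin$ranks[i])) next
    # deepest genuinely named ancestor: placeholders do not anchor deeper ones
    named <- seq_len(i - 1L)
    named <- named[nzchar(lin$ranks[named]) & !lin$placeholder[named]]
    anc_name <- sub("^[a-z]__", "", lin$ranks[named[length(named)]])
    lin$ranks[i] <- paste0(GTDB_PREFIXES[i], anc_name, "-", anchor_id, "-",
                           RANK_LETTERS[i])
    lin$placeholder[i] <- TRUE
  }
  lin
}

#' Build a catalog taxonomy table from lineage strings
#'
#' Parses each lineage, fills placeholders anchored at the species id, and
#' returns a flat table suitable for [rank_overlap()] and
#' [host_specific_taxa()].
#'
#' @param df Data.frame with columns `species_id`, `host` (e.g. "mouse" or
#'   "human"), `lineage`, and optionally `shared` (logical/0-1: the species
#'   is known to occur in the other host's catalog).
#' @return Data.frame with `species_id`, `host`, one column per rank, one
#'   logical `<rank>_placeholder` column per rank, and `shared`.
#' @export
build_catalog_taxonomy <- function(df) {
  required <- c("species_id", "host", "lineage")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("taxonomy table lacks column(s): ", paste(missing, collapse = ", "))
  if (anyDuplicated(df$species_id)) stop("duplicate species_id")
  lins <- lapply(seq_len(nrow(df)), function(i)
    fill_placeholders(parse_lineage(df$lineage[i]), df$species_id[i]))
  ranks <- do.call(rbind, lapply(lins, function(l)
    as.data.frame(as.list(l$ranks), stringsAsFactors = FALSE)))
  flags <- do.call(rbind, lapply(lins, function(l)
    as.data.frame(as.list(l$placeholder))))
  names(flags) <- paste0(GTDB_RANKS, "_placeholder")
  out <- cbind(df[, c("species_id", "host")], ranks, flags)
  out$shared <- if ("shared" %in% names(df)) as.logical(df$shared) else FALSE
  out
}

#' Read a lineage TSV into a catalog taxonomy table
#'
#' Expects tab-separated columns `species_id`, `host`, `lineage`, optional
#' `shared` (0/1).
#'
#' @param path TSV path.
#' @return See [build_catalog_taxonomy()].
#' @export
read_taxonomy <- function(path) {
  build_catalog_taxonomy(read_tsv_file(path))
}

#' Shared-taxon overlap at one taxonomic rank
#'
#' Counts the distinct taxa of the reference catalog at `rank` (placeholder
#' taxa count as genuine, catalog-private taxa) and how many of them are also
#' present in the other catalog. A taxon is shared when its non-placeholder
#' name occurs in the other catalog at the same rank, or — at species rank —
#' when any of its entries carries the `shared` flag (which encodes an
#' upstream cross-catalog ANI > 95% match). Placeholder names never match
#' across catalogs.
#'
#' @param reference Catalog taxonomy of the reference host
#'   (see [build_catalog_taxonomy()]).
#' @param other Catalog taxonomy of the other host.
#' @param rank One of `"domain"`, `"phylum"`, `"class"`, `"order"`,
#'   `"family"`, `"genus"`, `"species"`.
#' @return One-row data.frame with `rank`, `n_reference_taxa`, `n_shared`,
#'   `pct_shared` (exact), and `pct_display` (nearest integer above species
#'   rank, one decimal at species rank).
#' @export
rank_overlap <- function(reference, other, rank) {
  rank <- match.arg(rank, GTDB_RANKS)
  ph <- paste0(rank, "_placeholder")
  ref_names <- unique(reference[[rank]])
  other_real <- unique(other[[rank]][!other[[ph]]])
  shared_names <- character()
  # name matches between non-placeholder taxa
  ref_real <- unique(reference[[rank]][!reference[[ph]]])
  shared_names <- intersect(ref_real, other_real)
  if (rank == "species") {
    flagged <- unique(reference[[rank]][reference$shared])
    shared_names <- union(shared_names, flagged)
  }
  n_ref <- length(ref_names)
  n_shared <- length(shared_names)
  pct <- 100 * n_shared / n_ref
  data.frame(rank = rank, n_reference_taxa = n_ref, n_shared = n_shared,
             pct_shared = pct,
             pct_display = if (rank == "species") round(pct, 1)
                           else round(pct),
             stringsAsFactors = FALSE)
}

#' Overlap report across all seven ranks
#'
#' @inheritParams rank_overlap
#' @return Data.frame with one row per rank (see [rank_overlap()]).
#' @export
overlap_report <- function(reference, other) {
  do.call(rbind, lapply(GTDB_RANKS, function(r)
    rank_overlap(reference, other, r)))
}

#' Host-specific taxa at one rank
#'
#' Set differences of rank-level name sets between two catalogs. Placeholder
#' taxa are catalog-private and therefore always host-specific; at species
#' rank, reference species carrying the `shared` flag are removed from the
#' reference-specific set.
#'
#' @inheritParams rank_overlap
#' @return List with `reference_only` and `other_only` character vectors.
#' @export
host_specific_taxa <- function(reference, other, rank) {
  rank <- match.arg(rank, GTDB_RANKS)
  ph <- paste0(rank, "_placeholder")
  ref_names <- unique(reference[[rank]])
  other_names <- unique(other[[rank]])
  ref_real <- unique(reference[[rank]][!reference[[ph]]])
  other_real <- unique(other[[rank]][!other[[ph]]])
  shared <- intersect(ref_real, other_real)
  if (rank == "species")
    shared <- union(shared, unique(reference[[rank]][reference$shared]))
  list(reference_only = sort(setdiff(ref_names, shared)),
       other_only = sort(setdiff(other_names, shared)))
}
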