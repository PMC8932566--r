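#' Construct a genome assembly object
#'
#' A genome assembly is a set of contig sequences together with its identity
#' and provenance: whether it comes from a cultured isolate or is a
#' metagenome-assembled genome (MAG), and a free-text source label.
#'
#' @param genome_id Character scalar, unique within a collection.
#' @param contigs Character vector of DNA sequences (alphabet ACGTN). Sequences
#'   are uppercased and characters outside ACGTN are mapped to N.
#' @param is_isolate Logical; `TRUE` for isolate genomes, `FALSE` for MAGs.
#' @param source_label Free-text provenance string.
#' @return An object of class `genome_assembly`.
#' @export
genome_assembly <- function(genome_id, contigs, is_isolate = FALSE,
                            source_label = "") {
  stopifnot(is.character(genome_id), length(genome_id) == 1L, nzchar(genome_id),
            is.character(contigs), length(contigs) >= 1L,
            is.logical(is_isolate), length(is_isolate) == 1L)
  contigs <- normalize_dna(contigs)
  if (any(nchar(contigs) < 1L))
    stop("every contig must have length >= 1")
  if (is.null(names(contigs)))
    names(contigs) <- paste0(genome_id, "_c", seq_along(contigs))
  structure(
    list(genome_id = genome_id, contigs = contigs,
         is_isolate = is_isolate, source_label = source_label),
    class = "genome_assembly"
  )
}

#' @export
print.genome_assembly <- function(x, ...) {
  st <- assembly_stats(x)
  cat(sprintf("<genome_assembly> %s: %d contig(s), %s bp, N50 %s, %s\n",
              x$genome_id, st$n_contigs, format(st$total_length, big.mark = ","),
              format(st$n50, big.mark = ","),
              if (x$is_isolate) "isolate" else "MAG"))
  invisible(x)
}

# uppercase and map non-ACGTN characters (IUPAC ambiguity codes etc.) to N;
# downstream k-mer operations skip N-containing k-mers
normalize_dna <- function(x) {
  x <- toupper(x)
  gsub("[^ACGTN]", "N", x)
}

#' Read a genome assembly from a FASTA file
#'
#' Sequences are uppercased and any character outside ACGTN (e.g. IUPAC
#' ambiguity codes) is mapped to N. Plain and gzip-compressed files are
#' supported.
#'
#' @param path Path to a (possibly gzipped) FASTA file.
#' @param genome_id Genome identifier; defaults to the file name without
#'   extension.
#' @param is_isolate Logical isolate flag attached to the assembly.
#' @param source_label Provenance label; defaults to the file path.
#' @return A [genome_assembly()].
#' @export
read_fasta <- function(path, genome_id = NULL, is_isolate = FALSE,
                       source_label = path) {
  if (!file.exists(path)) stop("file not found: ", path)
  validate_fasta_headers(path)
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0L) stop("no sequences in ", path)
  if (is.null(genome_id))
    genome_id <- sub("\\.(fa|fasta|fna)(\\.gz)?$", "", basename(path))
  contigs <- as.character(seqs)
  names(contigs) <- sub("\\s.*$", "", names(seqs))
  genome_assembly(genome_id, contigs, is_isolate = is_isolate,
                  source_label = source_label)
}

# report the first malformed line (sequence characters before any header)
validate_fasta_headers <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "r") else file(path, "r")
  on.exit(close(con))
  seen_header <- FALSE
  i <- 0L
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) break
    i <- i + 1L
    if (!nzchar(trimws(line))) next
    if (startsWith(line, ">")) {
      if (!nzchar(trimws(substring(line, 2))))
        stop("malformed FASTA header at line ", i, " of ", path)
      seen_header <- TRUE
    } else if (!seen_header) {
      stop("malformed FASTA: sequence before header at line ", i, " of ", path)
    }
  }
  invisible(TRUE)
}

#' Write a genome assembly to a FASTA file
#'
#' @param asm A [genome_assembly()].
#' @param path Output path (`.gz` suffix triggers compression).
#' @param width Line width for wrapping sequences.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(asm, path, width = 80L) {
  stopifnot(inherits(asm, "genome_assembly"))
  seqs <- Biostrings::DNAStringSet(asm$contigs)
  Biostrings::writeXStringSet(seqs, path, width = width,
                              compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Contig N50 of a set of contig lengths
#'
#' N50 is the largest length L such that contigs of length at least L hold at
#' least half of the total assembly length (descending sort, cumulative sum —
#' the community-standard convention).
#'
#' @param lengths Positive integer vector of contig lengths.
#' @return The N50 in bp.
#' @export
#' @examples
#' n50(c(8, 7, 6, 5, 4)) # 7
n50 <- function(lengths) {
  stopifnot(length(lengths) >= 1L, all(lengths >= 1))
  lens <- sort(as.numeric(lengths), decreasing = TRUE)
  csum <- cumsum(lens)
  lens[which(csum >= csum[length(csum)] / 2)[1L]]
}

#' Assembly statistics (total length, contig count, N50)
#'
#' @param asm A [genome_assembly()].
#' @return A one-row data.frame with columns `genome_id`, `total_length`,
#'   `n_contigs`, `n50`.
#' @export
assembly_stats <- function(asm) {
  stopifnot(inherits(asm, "genome_assembly"))
  lens <- nchar(asm$contigs)
  data.frame(genome_id = asm$genome_id,
             total_length = sum(lens),
             n_contigs = length(lens),
             n50 = n50(lens),
             stringsAsFactors = FALSE)
}

#' Assembly statistics for a collection of assemblies
#'
#' @param assemblies A list of [genome_assembly()] objects.
#' @return A data.frame with one row per genome.
#' @export
assembly_stats_table <- function(assemblies) {
  do.call(rbind, lapply(assemblies, assembly_stats))
}

#' Read a genome metadata table
#'
#' Tab-separated with a header row and columns `genome_id`, `completeness`,
#' `contamination`, `is_isolate` (0/1), mirroring checkM-style output.
#' Completeness is a percentage in \[0, 100\]; contamination is a percentage
#' that may exceed 100 (multi-strain reference genomes do occur). An optional
#' `passes_chimerism` column (0/1) carries an upstream chimerism screen.
#'
#' @param path Path to the TSV file.
#' @return A data.frame with logical `is_isolate` (and `passes_chimerism` if
#'   present).
#' @export
read_genome_metadata <- function(path) {
  md <- read_tsv_file(path)
  required <- c("genome_id", "completeness", "contamination", "is_isolate")
  missing <- setdiff(required, names(md))
  if (length(missing))
    stop("metadata table lacks column(s): ", paste(missing, collapse = ", "))
  md$is_isolate <- as.logical(as.integer(md$is_isolate))
  if ("passes_chimerism" %in% names(md))
    md$passes_chimerism <- as.logical(as.integer(md$passes_chimerism))
  validate_genome_metadata(md)
  md
}

validate_genome_metadata <- function(md) {
  if (anyDuplicated(md$genome_id))
    stop("duplicate genome_id in metadata")
  if (any(md$completeness < 0 | md$completeness > 100))
    stop("completeness must lie in [0, 100]")
  if (any(md$contamination < 0))
    stop("contamination must be >= 0")
  invisible(md)
}

#' Write a genome metadata table
#'
#' @param md Metadata data.frame (see [read_genome_metadata()]).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_genome_metadata <- function(md, path) {
  out <- md
  out$is_isolate <- as.integer(out$is_isolate)
  if ("passes_chimerism" %in% names(out))
    out$passes_chimerism <- as.integer(out$passes_chimerism)
  write_tsv_file(out, path)
}
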