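#' Taxonomic ranks used throughout the package
#'
#' Fixed rank order from superkingdom down to strain; every genome's
#' metadata row must carry all eight (placeholders such as
#' `unclassified_genus` are allowed).
#'
#' @export
TAXONOMY_RANKS <- c("superkingdom", "phylum", "class", "order",
                    "family", "genus", "species", "strain")

#' Read genome FASTA records together with their taxonomy metadata
#'
#' FASTA record identifiers (the first whitespace-delimited token of each
#' header) are matched against the `accession` column of a metadata TSV
#' that carries the eight ranks of [TAXONOMY_RANKS]. Sequences are
#' uppercased on ingest. FASTA records without a metadata row are skipped
#' with a warning. Species identifiers (`SPn`) are assigned by first
#' appearance order of the species label in the metadata table, so they
#' are deterministic for a given metadata file.
#'
#' @param fasta_path path to a (multi-record) genome FASTA file.
#' @param metadata_path path to the taxonomy TSV
#'   (`accession` + the eight rank columns).
#' @return A `data.frame` with one row per genome record: `accession`,
#'   `species_id` (integer `n` of `SPn`), the eight rank columns and
#'   `sequence`.
#' @export
read_genomes <- function(fasta_path, metadata_path) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  if (length(seqs) == 0L) stop("empty FASTA: ", fasta_path, call. = FALSE)
  ids <- vapply(strsplit(names(seqs), "\\s+"), `[[`, character(1L), 1L)

  meta <- read.delim(metadata_path, stringsAsFactors = FALSE,
                     colClasses = "character")
  missing <- setdiff(c("accession", TAXONOMY_RANKS), names(meta))
  if (length(missing)) {
    stop("metadata is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(meta$accession)) {
    stop("duplicate accession in metadata: ",
         paste(unique(meta$accession[duplicated(meta$accession)]),
               collapse = ", "), call. = FALSE)
  }
  blank <- vapply(c("accession", TAXONOMY_RANKS),
                  function(col) any(!nzchar(trimws(meta[[col]]))), logical(1L))
  if (any(blank)) {
    stop("metadata has empty values in column(s): ",
         paste(names(blank)[blank], collapse = ", "), call. = FALSE)
  }

  known <- ids %in% meta$accession
  if (any(!known)) {
    warning("skipping FASTA record(s) absent from metadata: ",
            paste(ids[!known], collapse = ", "), call. = FALSE)
  }
  if (!any(known)) stop("no FASTA record has metadata", call. = FALSE)

  sp_levels <- unique(meta$species)
  idx <- match(ids[known], meta$accession)
  out <- data.frame(
    accession = ids[known],
    species_id = match(meta$species[idx], sp_levels),
    meta[idx, TAXONOMY_RANKS, drop = FALSE],
    sequence = toupper(as.character(seqs[known])),
    stringsAsFactors = FALSE, row.names = NULL
  )
  out
}

#' Quality-filter genomes on runs of ambiguous positions
#'
#' Complete-genome assemblies mark low-coverage stretches with non-ACGT
#' characters; a genome is discarded when it contains a run of strictly
#' more than `max_ambiguous_run` consecutive non-ACGT characters.
#'
#' @param genomes genome `data.frame` from [read_genomes()].
#' @param max_ambiguous_run longest tolerated run (default 20).
#' @return `list(kept = , discarded = )`, an exhaustive disjoint partition
#'   of the input rows.
#' @export
qc_filter_genomes <- function(genomes, max_ambiguous_run = 20L) {
  stopifnot(is.data.frame(genomes), nrow(genomes) >= 1L)
  if (!is.numeric(max_ambiguous_run) || max_ambiguous_run < 1) {
    stop("max_ambiguous_run must be >= 1", call. = FALSE)
  }
  rx <- sprintf("[^ACGT]{%d,}", as.integer(max_ambiguous_run) + 1L)
  bad <- grepl(rx, genomes$sequence, perl = TRUE)
  list(kept = genomes[!bad, , drop = FALSE],
       discarded = genomes[bad, , drop = FALSE])
}

.amplicon_header <- function(a) {
  lineage <- paste(unlist(a[TAXONOMY_RANKS[1:7]]), collapse = ";")
  sprintf("SP%d.V%d|%s|pair=%s|src=%s:%d-%d:%s",
          a$species_id, a$variant_id, lineage, a$pair_id,
          a$accession, a$start, a$end, a$strand)
}

#' Write amplicons of one primer pair to FASTA
#'
#' Headers follow the grammar
#' `SP<i>.V<j>|<superkingdom>;...;<species>|pair=<pair_id>|src=<accession>:<start>-<end>:<strand>`
#' (1-based inclusive coordinates on the forward strand of the source
#' record), so the file is parseable without the metadata table and
#' round-trips losslessly through [read_amplicon_fasta()].
#'
#' @param amplicons amplicon `data.frame` (one primer pair) as produced by
#'   [collapse_species_variants()].
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
write_amplicon_fasta <- function(amplicons, path) {
  if (nrow(amplicons) == 0L) {
    file.create(path)
    return(invisible(path))
  }
  if (length(unique(amplicons$pair_id)) != 1L) {
    stop("amplicons must all belong to one primer pair", call. = FALSE)
  }
  key <- paste0("SP", amplicons$species_id, ".V", amplicons$variant_id)
  if (anyDuplicated(key)) {
    stop("duplicate (SPn, Vn) in amplicon set: ",
         paste(unique(key[duplicated(key)]), collapse = ", "), call. = FALSE)
  }
  headers <- vapply(seq_len(nrow(amplicons)),
                    function(i) .amplicon_header(amplicons[i, ]),
                    character(1L))
  out <- Biostrings::DNAStringSet(amplicons$sequence)
  names(out) <- headers
  Biostrings::writeXStringSet(out, path)
  invisible(path)
}

#' Read an amplicon FASTA written by [write_amplicon_fasta()]
#'
#' @param path FASTA path.
#' @return Amplicon `data.frame` (empty for an empty file).
#' @export
read_amplicon_fasta <- function(path) {
  empty <- data.frame(species_id = integer(), variant_id = integer(),
                      pair_id = character(), accession = character(),
                      start = integer(), end = integer(), strand = character(),
                      reported_length = integer(), sequence = character(),
                      stringsAsFactors = FALSE)
  for (r in TAXONOMY_RANKS[1:7]) empty[[r]] <- character()
  if (file.size(path) == 0) return(empty)
  seqs <- Biostrings::readDNAStringSet(path)
  rx <- paste0("^SP(\\d+)\\.V(\\d+)\\|([^|]*)\\|pair=([^|]*)\\|",
               "src=(.+):(\\d+)-(\\d+):([+-])$")
  m <- regmatches(names(seqs), regexec(rx, names(seqs)))
  bad <- vapply(m, length, integer(1L)) != 9L
  if (any(bad)) {
    stop("malformed amplicon header: ", names(seqs)[bad][1L], call. = FALSE)
  }
  f <- function(i) vapply(m, `[[`, character(1L), i)
  lin <- strsplit(f(4L), ";", fixed = TRUE)
  if (any(vapply(lin, length, integer(1L)) != 7L)) {
    stop("amplicon header lineage must have 7 ranks", call. = FALSE)
  }
  out <- data.frame(
    species_id = as.integer(f(2L)), variant_id = as.integer(f(3L)),
    pair_id = f(5L), accession = f(6L),
    start = as.integer(f(7L)), end = as.integer(f(8L)), strand = f(9L),
    stringsAsFactors = FALSE
  )
  out$reported_length <- out$end - out$start
  out$sequence <- as.character(seqs)
  for (i in 1:7) {
    out[[TAXONOMY_RANKS[i]]] <- vapply(lin, `[[`, character(1L), i)
  }
  out
}
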