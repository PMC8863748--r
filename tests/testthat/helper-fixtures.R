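# Shared fixtures, built in code at test time.

CATALOG <- load_primer_catalog()

catalog_pair <- function(pair_id) {
  CATALOG[CATALOG$pair_id == pair_id, , drop = FALSE]
}

# minimal genome data.frame with a complete, hierarchy-consistent lineage
make_genomes <- function(sequences, species = seq_along(sequences),
                         genus = NULL, superkingdom = "Bacteria") {
  n <- length(sequences)
  species <- as.integer(species)
  genus <- genus %||% ceiling(species / 2)
  family <- ceiling(genus / 2)
  data.frame(
    accession = sprintf("ACC%03d", seq_len(n)),
    species_id = species,
    superkingdom = superkingdom,
    phylum = "Phy",
    class = sprintf("Class_%d", ceiling(family / 2)),
    order = sprintf("Order_%d", family),
    family = sprintf("Family_%d", family),
    genus = sprintf("Genus_%d", genus),
    species = sprintf("Genus_%d sp%d", genus, species),
    strain = sprintf("strain_%d", seq_len(n)),
    sequence = toupper(sequences),
    stringsAsFactors = FALSE
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# a genome string with a plus-strand amplicon of the given pair planted at
# `at` (forward-primer first base lands at position at + 1)
plant_amplicon <- function(pair, core, at = 9L, tail = 40L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  f <- sample(expand_degenerate(pair$f_seq), 1L)
  r <- sample(expand_degenerate(pair$r_seq), 1L)
  seg <- paste0(f, core, reverse_complement(r))
  list(genome = paste0(random_dna(at), seg, random_dna(tail)),
       segment = seg, f_site = at + 1L,
       r_end = at + nchar(seg))
}

# small relation data.frame in filter_asi97's output shape
make_relations <- function(pairs, pair_id = "P1", pident = 98) {
  if (!length(pairs)) {
    return(data.frame(pair_id = character(), species_a = character(),
                      species_b = character(), pident = numeric(),
                      stringsAsFactors = FALSE))
  }
  data.frame(
    pair_id = pair_id,
    species_a = vapply(pairs, `[[`, character(1L), 1L),
    species_b = vapply(pairs, `[[`, character(1L), 2L),
    pident = pident,
    stringsAsFactors = FALSE
  )
}

# lineage table for species labels, with a consistent hierarchy derived
# from the genus index
make_lineages <- function(labels, genus) {
  family <- ceiling(genus / 2)
  data.frame(
    species_label = labels,
    superkingdom = "Bacteria", phylum = "Phy",
    class = sprintf("Class_%d", ceiling(family / 2)),
    order = sprintf("Order_%d", family),
    family = sprintf("Family_%d", family),
    genus = sprintf("Genus_%d", genus),
    species = labels, strain = labels,
    stringsAsFactors = FALSE
  )
}

write_genome_files <- function(genomes, dir = tempfile("community")) {
  dir.create(dir, showWarnings = FALSE)
  fasta <- file.path(dir, "genomes.fasta")
  meta <- file.path(dir, "metadata.tsv")
  writeLines(paste0(">", genomes$accession, "\n", genomes$sequence), fasta)
  write.table(genomes[, c("accession", TAXONOMY_RANKS)], meta, sep = "\t",
              quote = FALSE, row.names = FALSE)
  list(fasta = fasta, metadata = meta)
}
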