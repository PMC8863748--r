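#' Build the binary species-similarity matrix for one primer pair
#'
#' Rows and columns are the detected species; a cell holds 1 when a
#' similarity relation (>=97% identity at full query coverage) exists
#' between the two species. The matrix is symmetric with a zero diagonal.
#'
#' @param relations `data.frame` from [filter_asi97()].
#' @param detected_species character vector of detected species labels
#'   (`"SPn"`); every relation endpoint must be among them.
#' @return Symmetric 0/1 integer matrix with `detected_species` dimnames.
#' @export
build_matrix <- function(relations, detected_species) {
  detected_species <- as.character(detected_species)
  m <- matrix(0L, length(detected_species), length(detected_species),
              dimnames = list(detected_species, detected_species))
  if (nrow(relations)) {
    unknown <- setdiff(c(relations$species_a, relations$species_b),
                       detected_species)
    if (length(unknown)) {
      stop("relation references species not in detected set: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    m[cbind(relations$species_a, relations$species_b)] <- 1L
    m[cbind(relations$species_b, relations$species_a)] <- 1L
  }
  m
}

#' Per-primer coverage and similarity statistics
#'
#' From the binary similarity matrix of one primer pair and the number of
#' species evaluated in the domain, computes the descriptive estimators:
#' number of detected species, number of species with at least one
#' similarity relation, total relation count, mean and maximum relations
#' per species, and the coverage percentages SC (detected/total),
#' SC-ASI97 (detected with >=1 relation), SC-NASI97 (detected with none)
#' and non-SC (not detected). `SC_ASI97 + SC_NASI97 == SC` and
#' `SC + non_SC == 100` exactly (before any rounding).
#'
#' @param matrix 0/1 matrix from [build_matrix()].
#' @param n_total_species evaluated-species denominator (e.g. 186
#'   bacteria or 135 archaea).
#' @param pair_id identifier copied into the output row.
#' @param mean_denominator `"species_with_asi97"` (default) divides the
#'   relation-endpoint total by the species having at least one relation;
#'   `"detected"` divides by all detected species.
#' @return One-row `data.frame` (a `PrimerSummary`).
#' @export
summarize_primer <- function(matrix, n_total_species, pair_id = NA_character_,
                             mean_denominator = c("species_with_asi97",
                                                  "detected")) {
  mean_denominator <- match.arg(mean_denominator)
  if (!is.numeric(n_total_species) || n_total_species < 1) {
    stop("n_total_species must be a positive count", call. = FALSE)
  }
  n_detected <- ncol(matrix)
  if (n_total_species < n_detected) {
    stop("n_total_species (", n_total_species,
         ") smaller than number of detected species (", n_detected, ")",
         call. = FALSE)
  }
  degree <- if (n_detected) rowSums(matrix) else numeric()
  n_with <- sum(degree > 0)
  n_edges <- sum(matrix) / 2
  denom <- if (mean_denominator == "species_with_asi97") n_with else n_detected
  data.frame(
    pair_id = pair_id,
    n_total_species = as.integer(n_total_species),
    n_detected = as.integer(n_detected),
    n_species_with_asi97 = as.integer(n_with),
    n_asi97 = as.integer(n_edges),
    mean_asi97_per_species = if (denom > 0) 2 * n_edges / denom else 0,
    max_asi97_per_species = if (n_detected) as.integer(max(degree)) else 0L,
    SC = 100 * n_detected / n_total_species,
    SC_ASI97 = 100 * n_with / n_total_species,
    SC_NASI97 = 100 * (n_detected - n_with) / n_total_species,
    non_SC = 100 * (n_total_species - n_detected) / n_total_species,
    stringsAsFactors = FALSE
  )
}

#' Species-pair frequency across primer pairs
#'
#' The frequency of an unordered species pair is the number of primer
#' pairs in which that pair had a similarity relation.
#'
#' @param relations_by_primer named list of relation `data.frame`s
#'   (one per primer pair).
#' @return `list(frequency = , long = )`: `frequency` has one row per
#'   species pair (`species_a`, `species_b`, `frequency`); `long` is the
#'   heat-map-ready long format with one row per (primer pair, species
#'   pair) occurrence.
#' @export
pair_frequency <- function(relations_by_primer) {
  long <- do.call(rbind, c(lapply(relations_by_primer, function(r) {
    r[, c("pair_id", "species_a", "species_b", "pident"), drop = FALSE]
  }), list(make.row.names = FALSE)))
  if (is.null(long) || nrow(long) == 0L) {
    return(list(
      frequency = data.frame(species_a = character(), species_b = character(),
                             frequency = integer(), stringsAsFactors = FALSE),
      long = data.frame(pair_id = character(), species_a = character(),
                        species_b = character(), pident = numeric(),
                        stringsAsFactors = FALSE)
    ))
  }
  key <- paste(long$species_a, long$species_b, sep = "\r")
  tab <- table(key)
  parts <- strsplit(names(tab), "\r", fixed = TRUE)
  freq <- data.frame(
    species_a = vapply(parts, `[[`, character(1L), 1L),
    species_b = vapply(parts, `[[`, character(1L), 2L),
    frequency = as.integer(tab),
    stringsAsFactors = FALSE
  )
  freq <- freq[order(-freq$frequency, freq$species_a, freq$species_b), ]
  rownames(freq) <- NULL
  list(frequency = freq, long = long)
}

#' Tally similarity relations within vs across a taxonomic rank
#'
#' Classifies each relation (or relation-occurrence, when the input
#' concatenates relations across primer pairs) by whether its two species
#' share the label at `rank`.
#'
#' @param relations relation `data.frame` (possibly rbind-ed across
#'   primer pairs; each row counts once).
#' @param lineages `data.frame` mapping species labels to ranks: needs a
#'   `species_label` column (`"SPn"`) plus the rank columns.
#' @param rank one of `"genus"`, `"family"`, `"order"`, `"class"`.
#' @return `list(n_same_rank, n_cross_rank, percent_cross)` with the
#'   percentage over all classified relations.
#' @export
cross_rank_tally <- function(relations, lineages,
                             rank = c("genus", "family", "order", "class")) {
  rank <- match.arg(rank)
  if (!all(c("species_label", rank) %in% names(lineages))) {
    stop("lineages needs columns 'species_label' and '", rank, "'",
         call. = FALSE)
  }
  if (nrow(relations) == 0L) {
    return(list(n_same_rank = 0L, n_cross_rank = 0L, percent_cross = NaN))
  }
  la <- lineages[[rank]][match(relations$species_a, lineages$species_label)]
  lb <- lineages[[rank]][match(relations$species_b, lineages$species_label)]
  if (anyNA(la) || anyNA(lb)) {
    miss <- unique(c(relations$species_a[is.na(la)],
                     relations$species_b[is.na(lb)]))
    stop("species lacking lineage: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  cross <- la != lb
  list(n_same_rank = sum(!cross), n_cross_rank = sum(cross),
       percent_cross = 100 * mean(cross))
}

#' Lineage lookup table for a genome set
#'
#' One row per species (`species_label` = `"SPn"`) with the eight
#' taxonomy ranks, for use with [cross_rank_tally()] and
#' [build_network()].
#'
#' @param genomes genome `data.frame` from [read_genomes()].
#' @return Lineage `data.frame`.
#' @export
species_lineages <- function(genomes) {
  first <- !duplicated(genomes$species_id)
  out <- data.frame(species_label = paste0("SP", genomes$species_id[first]),
                    genomes[first, TAXONOMY_RANKS, drop = FALSE],
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(genomes$species_id[first]), , drop = FALSE]
}
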