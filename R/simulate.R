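.DNA <- c("A", "C", "G", "T")

.random_dna <- function(n) paste(sample(.DNA, n, replace = TRUE), collapse = "")

.mutate_at <- function(chars, positions) {
  for (p in positions) {
    chars[p] <- sample(setdiff(.DNA, chars[p]), 1L)
  }
  chars
}

#' Specify a synthetic community with known ground truth
#'
#' Describes a community of `n_species` genomes carrying one planted
#' 16S-like segment per strain: a concrete realization of the forward
#' primer, a species-specific core, and the reverse complement of a
#' concrete realization of the reverse primer. Cores are derived from
#' per-block ancestor sequences by planting substitutions (no indels), so
#' the pairwise amplicon identities realize a block-structured design:
#' `within_identity` percent inside a block, `between_identity` percent
#' across blocks. Substitution counts are rounded to the nearest feasible
#' integers; the *realized* identities are recorded in the ground truth
#' and must stay at least `margin` percentage points away from the 97%
#' decision threshold.
#'
#' @param n_species number of species.
#' @param block_sizes integer vector partitioning the species into
#'   identity blocks (defaults to blocks of 3, remainder in the last).
#' @param within_identity designed percent identity inside a block
#'   (scalar or one value per block).
#' @param between_identity designed percent identity across blocks.
#' @param strains_per_species genomes per species (identical cores, so
#'   one expected variant per species).
#' @param coverage_gap fraction of species whose genomes carry no primer
#'   sites.
#' @param ambiguous_fraction fraction of genomes given a run of
#'   `ambiguous_run_length` consecutive `N`s (QC casualties).
#' @param ambiguous_run_length length of the planted ambiguous run.
#' @param core_length inter-primer core length (nt); chosen so that the
#'   reported amplicon length lies strictly inside (100, 2300).
#' @param pair one primer-catalog row to plant (default: the packaged
#'   KP_F078-OP_R010 pair).
#' @param background_length genome background length (nt).
#' @param species_per_genus,genera_per_family,families_per_order,orders_per_class
#'   taxonomy shape.
#' @param superkingdom domain label for all genomes.
#' @param margin minimal distance (percentage points) allowed between any
#'   realized identity and the 97% threshold.
#' @param seed RNG seed; regeneration with the same spec is byte-identical.
#' @return A validated list of class `community_spec`.
#' @export
community_spec <- function(n_species,
                           block_sizes = NULL,
                           within_identity = 98.5,
                           between_identity = 90,
                           strains_per_species = 1L,
                           coverage_gap = 0,
                           ambiguous_fraction = 0,
                           ambiguous_run_length = 25L,
                           core_length = 150L,
                           pair = NULL,
                           background_length = 3000L,
                           species_per_genus = 2L,
                           genera_per_family = 2L,
                           families_per_order = 2L,
                           orders_per_class = 2L,
                           superkingdom = "Bacteria",
                           margin = 0.5,
                           seed = 1L) {
  stopifnot(n_species >= 2L, core_length >= 30L, strains_per_species >= 1L,
            coverage_gap >= 0, coverage_gap < 1,
            ambiguous_fraction >= 0, ambiguous_fraction <= 1)
  if (is.null(block_sizes)) {
    block_sizes <- rep(3L, n_species %/% 3L)
    rem <- n_species - sum(block_sizes)
    if (rem > 0L) {
      if (length(block_sizes)) {
        block_sizes[length(block_sizes)] <- block_sizes[length(block_sizes)] + rem
      } else block_sizes <- rem
    }
  }
  if (sum(block_sizes) != n_species) {
    stop("block_sizes must sum to n_species", call. = FALSE)
  }
  if (is.null(pair)) {
    catalog <- load_primer_catalog()
    pair <- catalog[catalog$pair_id == "KP_F078-OP_R010", , drop = FALSE]
  }
  pair <- as.list(pair)
  n_blocks <- length(block_sizes)
  within_identity <- rep(within_identity, length.out = n_blocks)

  seg_len <- core_length + nchar(pair$f_seq) + nchar(pair$r_seq)
  reported <- seg_len - 1L
  if (!(reported > 100L && reported < 2300L)) {
    stop("core_length yields reported amplicon length ", reported,
         " outside (100, 2300)", call. = FALSE)
  }

  # feasible substitution counts (see generate_community for the layout)
  k_block <- round(seg_len * (100 - within_identity) / 100 / 2)
  m_anc <- max(0L, round((seg_len * (100 - between_identity) / 100 -
                            2 * mean(k_block)) / 2))
  realized_within <- 100 * (seg_len - 2 * k_block) / seg_len
  worst_between <- 100 * (seg_len - (2 * m_anc + 2 * max(k_block))) / seg_len
  best_between <- 100 * (seg_len - (2 * m_anc + 2 * min(k_block))) / seg_len
  realized <- c(realized_within, worst_between, best_between)
  if (any(abs(realized - 97) < margin)) {
    stop("designed identities land within ", margin,
         " percentage points of the 97% threshold (realized: ",
         paste(sprintf("%.2f", sort(unique(realized))), collapse = ", "),
         "); adjust the design", call. = FALSE)
  }
  need <- n_blocks * m_anc + sum(k_block * block_sizes)
  if (need > core_length) {
    stop("core_length ", core_length, " too short for ", need,
         " disjoint substitution positions", call. = FALSE)
  }

  structure(list(
    n_species = as.integer(n_species), block_sizes = as.integer(block_sizes),
    within_identity = within_identity, between_identity = between_identity,
    strains_per_species = as.integer(strains_per_species),
    coverage_gap = coverage_gap, ambiguous_fraction = ambiguous_fraction,
    ambiguous_run_length = as.integer(ambiguous_run_length),
    core_length = as.integer(core_length), pair = pair,
    background_length = as.integer(background_length),
    species_per_genus = as.integer(species_per_genus),
    genera_per_family = as.integer(genera_per_family),
    families_per_order = as.integer(families_per_order),
    orders_per_class = as.integer(orders_per_class),
    superkingdom = superkingdom, margin = margin,
    k_block = as.integer(k_block), m_anc = as.integer(m_anc),
    seg_len = as.integer(seg_len), seed = as.integer(seed)
  ), class = "community_spec")
}

.synthetic_taxonomy <- function(spec) {
  s <- seq_len(spec$n_species)
  gi <- ceiling(s / spec$species_per_genus)
  fi <- ceiling(gi / spec$genera_per_family)
  oi <- ceiling(fi / spec$families_per_order)
  ci <- ceiling(oi / spec$orders_per_class)
  data.frame(
    superkingdom = spec$superkingdom,
    phylum = "Synthphylum",
    class = sprintf("Synthclass_%02d", ci),
    order = sprintf("Synthorder_%02d", oi),
    family = sprintf("Synthfam_%02d", fi),
    genus = sprintf("Synthgenus_%02d", gi),
    species = sprintf("Synthgenus_%02d sp%03d", gi, s),
    stringsAsFactors = FALSE
  )
}

# union-find component labelling, kept free of igraph so the ground truth
# is independent of the pipeline's graph machinery
.uf_components <- function(n, edges) {
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  if (nrow(edges)) {
    for (e in seq_len(nrow(edges))) {
      ra <- find(edges[e, 1L]); rb <- find(edges[e, 2L])
      if (ra != rb) parent[ra] <- rb
    }
  }
  vapply(seq_len(n), find, integer(1L))
}

#' Generate a synthetic community with full ground truth
#'
#' Realizes a [community_spec()]: builds strain genomes embedding planted
#' primer sites at random loci and strands, and returns them alongside a
#' ground-truth object listing realized pairwise identities, the expected
#' similarity edge set, expected components, the expected amplicon per
#' species, discarded genomes and the analytically expected per-primer
#' summary.
#'
#' @param spec a [community_spec()].
#' @return `list(genomes, metadata, truth, spec)`; `genomes` has the same
#'   shape as the output of [read_genomes()].
#' @export
generate_community <- function(spec) {
  stopifnot(inherits(spec, "community_spec"))
  with_seed(spec$seed, .generate_community_impl(spec))
}

.generate_community_impl <- function(spec) {
  n <- spec$n_species
  pair <- spec$pair
  f_real <- sample(expand_degenerate(pair$f_seq), 1L)
  r_real <- sample(expand_degenerate(pair$r_seq), 1L)
  r_site <- reverse_complement(r_real)
  nf <- nchar(f_real); nr <- nchar(r_site)
  L <- spec$core_length
  seg_len <- spec$seg_len
  block_of <- rep(seq_along(spec$block_sizes), spec$block_sizes)
  k_sp <- spec$k_block[block_of]

  segments <- NULL
  for (attempt in 1:50) {
    root <- strsplit(.random_dna(L), "", fixed = TRUE)[[1L]]
    pos_pool <- sample.int(L)
    take <- function(k) {
      out <- pos_pool[seq_len(k)]
      pos_pool <<- pos_pool[-seq_len(k)]
      out
    }
    anc <- list()
    for (b in seq_along(spec$block_sizes)) {
      anc[[b]] <- .mutate_at(root, take(spec$m_anc))
    }
    cores <- character(n)
    for (s in seq_len(n)) {
      cores[s] <- paste(.mutate_at(anc[[block_of[s]]], take(k_sp[s])),
                        collapse = "")
    }
    segs <- paste0(f_real, cores, r_site)
    ok <- all(vapply(segs, function(sg) {
      identical(find_matches(sg, pair$f_seq), 1L) &&
        identical(find_matches(sg, reverse_complement(pair$r_seq)),
                  seg_len - nr + 1L) &&
        length(find_matches(sg, pair$r_seq)) == 0L &&
        length(find_matches(sg, reverse_complement(pair$f_seq))) == 0L
    }, logical(1L)))
    if (ok) { segments <- segs; break }
  }
  if (is.null(segments)) {
    stop("could not realize primer-clean cores in 50 attempts", call. = FALSE)
  }

  # realized pairwise identity matrix (substitution-only, disjoint positions)
  d <- matrix(0L, n, n)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    dd <- if (block_of[i] == block_of[j]) {
      k_sp[i] + k_sp[j]
    } else {
      2L * spec$m_anc + k_sp[i] + k_sp[j]
    }
    d[i, j] <- dd; d[j, i] <- dd
  }
  identity <- 100 * (seg_len - d) / seg_len
  diag(identity) <- 100

  covered <- rep(TRUE, n)
  n_gap <- round(spec$coverage_gap * n)
  if (n_gap > 0L) covered[sample.int(n, n_gap)] <- FALSE

  tax <- .synthetic_taxonomy(spec)
  n_genomes <- n * spec$strains_per_species
  n_amb <- round(spec$ambiguous_fraction * n_genomes)
  amb_idx <- if (n_amb > 0L) sample.int(n_genomes, n_amb) else integer()

  rows <- vector("list", n_genomes)
  g <- 0L
  for (s in seq_len(n)) {
    for (st in seq_len(spec$strains_per_species)) {
      g <- g + 1L
      genome <- NULL
      for (attempt in 1:50) {
        bg <- .random_dna(spec$background_length)
        insert_run <- function(seq, exclude_from = NULL, exclude_to = NULL) {
          # insertion boundary p: run goes between bases p and p+1; keep it
          # outside the planted segment so the run stays contiguous
          p_ok <- 0:nchar(seq)
          if (!is.null(exclude_from)) {
            p_ok <- p_ok[p_ok < exclude_from | p_ok >= exclude_to]
          }
          p <- sample(p_ok, 1L)
          paste0(substr(seq, 1L, p), strrep("N", spec$ambiguous_run_length),
                 substr(seq, p + 1L, nchar(seq)))
        }
        if (covered[s]) {
          strand <- sample(c("+", "-"), 1L)
          ins <- if (strand == "+") segments[s] else
            reverse_complement(segments[s])
          at <- sample.int(nchar(bg) - 1L, 1L)
          cand <- paste0(substr(bg, 1L, at), ins,
                         substr(bg, at + 1L, nchar(bg)))
          if (g %in% amb_idx) {
            cand <- insert_run(cand, exclude_from = at + 1L,
                               exclude_to = at + seg_len)
          }
          want_f <- if (strand == "+") "+" else "-"
          hits_f <- find_primer_sites(cand, pair$f_seq)
          hits_r <- find_primer_sites(cand, pair$r_seq)
          if (nrow(hits_f) == 1L && hits_f$strand == want_f &&
              nrow(hits_r) == 1L && hits_r$strand != want_f) {
            genome <- cand; break
          }
        } else {
          cand <- if (g %in% amb_idx) insert_run(bg) else bg
          if (nrow(find_primer_sites(cand, pair$f_seq)) == 0L &&
              nrow(find_primer_sites(cand, pair$r_seq)) == 0L) {
            genome <- cand; break
          }
        }
      }
      if (is.null(genome)) {
        stop("could not place a clean genome in 50 attempts", call. = FALSE)
      }
      rows[[g]] <- data.frame(
        accession = sprintf("SYN%04d", g), species_id = s,
        tax[s, , drop = FALSE],
        strain = sprintf("%s strain_%d", tax$species[s], st),
        sequence = genome, stringsAsFactors = FALSE, row.names = NULL
      )
    }
  }
  genomes <- do.call(rbind, rows)
  genomes <- genomes[, c("accession", "species_id", TAXONOMY_RANKS,
                         "sequence")]

  discarded <- genomes$accession[seq_len(n_genomes) %in% amb_idx]
  surviving <- !(seq_len(n_genomes) %in% amb_idx)
  species_surviving <- vapply(seq_len(n), function(s) {
    any(surviving[genomes$species_id == s])
  }, logical(1L))
  detected <- covered & species_surviving

  edges <- which(upper.tri(identity) & identity >= 97, arr.ind = TRUE)
  edges <- edges[detected[edges[, 1L]] & detected[edges[, 2L]], , drop = FALSE]
  edges <- edges[order(edges[, 1L], edges[, 2L]), , drop = FALSE]
  comp <- .uf_components(n, edges)
  comp_sizes <- table(comp[detected])

  truth <- list(
    seg_len = seg_len, reported_length = seg_len - 1L,
    f_realization = f_real, r_realization = r_real,
    amplicon_by_species = stats::setNames(segments, paste0("SP", seq_len(n))),
    identity = identity, block_of = block_of,
    covered = covered, detected = detected,
    discarded_accessions = discarded,
    edges = if (nrow(edges)) {
      data.frame(species_a = paste0("SP", edges[, 1L]),
                 species_b = paste0("SP", edges[, 2L]),
                 identity = identity[edges], stringsAsFactors = FALSE)
    } else {
      data.frame(species_a = character(), species_b = character(),
                 identity = numeric(), stringsAsFactors = FALSE)
    },
    n_components = sum(comp_sizes >= 2L),
    component_sizes = sort(as.integer(comp_sizes[comp_sizes >= 2L]),
                           decreasing = TRUE)
  )
  metadata <- genomes[, c("accession", TAXONOMY_RANKS)]
  list(genomes = genomes, metadata = metadata, truth = truth, spec = spec)
}

#' Analytically expected per-primer summary for a synthetic community
#'
#' Computed directly from the design/ground truth with plain arithmetic,
#' independently of the pipeline's matrix and summary code, for use as an
#' oracle in end-to-end recovery tests.
#'
#' @param spec the [community_spec()].
#' @param truth ground truth from [generate_community()].
#' @return One-row `data.frame` with the same columns as
#'   [summarize_primer()].
#' @export
expected_summary <- function(spec, truth) {
  n_total <- spec$n_species
  n_detected <- sum(truth$detected)
  endpoints <- unique(c(truth$edges$species_a, truth$edges$species_b))
  n_with <- length(endpoints)
  n_edges <- nrow(truth$edges)
  deg <- table(c(truth$edges$species_a, truth$edges$species_b))
  data.frame(
    pair_id = spec$pair$pair_id,
    n_total_species = as.integer(n_total),
    n_detected = as.integer(n_detected),
    n_species_with_asi97 = as.integer(n_with),
    n_asi97 = as.integer(n_edges),
    mean_asi97_per_species = if (n_with > 0) 2 * n_edges / n_with else 0,
    max_asi97_per_species = if (length(deg)) as.integer(max(deg)) else 0L,
    SC = 100 * n_detected / n_total,
    SC_ASI97 = 100 * n_with / n_total,
    SC_NASI97 = 100 * (n_detected - n_with) / n_total,
    non_SC = 100 * (n_total - n_detected) / n_total,
    stringsAsFactors = FALSE
  )
}

#' Write a synthetic community to disk
#'
#' Emits `genomes.fasta`, `metadata.tsv` and `ground_truth.json` (realized
#' identities, expected edges and components) so the pipeline can be run
#' from files exactly as with real data.
#'
#' @param community output of [generate_community()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_community <- function(community, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  seqs <- Biostrings::DNAStringSet(community$genomes$sequence)
  names(seqs) <- community$genomes$accession
  Biostrings::writeXStringSet(seqs, file.path(dir, "genomes.fasta"))
  write.table(community$metadata, file.path(dir, "metadata.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  truth <- community$truth
  truth$identity <- round(truth$identity, 6)
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
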