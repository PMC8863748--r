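#' Screen a genome set with a primer-pair catalog
#'
#' Runs the full in-silico analysis: QC-filters the genomes, routes every
#' catalog pair to the domains it targets, extracts zero-mismatch
#' amplicons within the length bounds, collapses per-species variants,
#' aligns all-vs-all, filters similarity relations (>= `threshold`
#' percent identity at 100% query coverage, one random representative per
#' species pair), and derives the per-primer similarity matrix, summary
#' statistics and potential-OTU network. Primer pairs that target a
#' domain absent from the genome set are skipped with a message; pairs
#' that yield no amplicon for a present domain produce a summary row with
#' SC = 0 and a warning.
#'
#' @param genomes genome `data.frame` from [read_genomes()] (or
#'   [generate_community()]`$genomes`).
#' @param catalog `primer_catalog` rows to evaluate.
#' @param threshold percent-identity threshold (default 97).
#' @param min_len,max_len strict amplicon length bounds (defaults
#'   100/2300).
#' @param max_ambiguous_run QC limit on consecutive non-ACGT characters.
#' @param seed base seed; per-pair representative-sampling seeds are
#'   derived as `(seed + 7919 * pair_index) mod (2^31 - 1)`.
#' @param n_total named vector of evaluated-species denominators per
#'   domain (`bacteria`, `archaea`); defaults to the number of distinct
#'   species of each domain in `genomes` (before QC).
#' @param mean_denominator passed to [summarize_primer()].
#' @return An object of class `asi_screen`: list with `summaries` (one
#'   row per pair x domain), and per-run lists `amplicons`, `relations`,
#'   `matrices`, `networks`, `otus`, plus `frequency` (per domain),
#'   `lineages`, `qc`, `config`.
#' @export
asi_screen <- function(genomes, catalog = load_primer_catalog(),
                       threshold = 97, min_len = 100L, max_len = 2300L,
                       max_ambiguous_run = 20L, seed = 1L, n_total = NULL,
                       mean_denominator = "species_with_asi97") {
  stopifnot(is.data.frame(genomes), nrow(genomes) >= 1L)
  if (!(threshold > 0 && threshold <= 100)) {
    stop("threshold must be in (0, 100]", call. = FALSE)
  }
  if (!(min_len > 0 && max_len > min_len)) {
    stop("need 0 < min_len < max_len", call. = FALSE)
  }
  qc <- qc_filter_genomes(genomes, max_ambiguous_run)
  lineages <- species_lineages(genomes)

  domain_of <- tolower(genomes$superkingdom)
  present <- unique(domain_of)
  totals <- vapply(c("bacteria", "archaea"), function(d) {
    length(unique(genomes$species_id[domain_of == d]))
  }, integer(1L))
  if (!is.null(n_total)) {
    totals[names(n_total)] <- n_total
  }

  runs <- list()
  summaries <- list()
  for (i in seq_len(nrow(catalog))) {
    pair <- catalog[i, , drop = FALSE]
    pair_domains <- if (pair$target_domain == "both") {
      c("bacteria", "archaea")
    } else pair$target_domain
    for (dom in pair_domains) {
      if (!dom %in% present) {
        message("skipping ", pair$pair_id, " for ", dom,
                ": no ", dom, " genomes in input")
        next
      }
      gset <- qc$kept[tolower(qc$kept$superkingdom) == dom, , drop = FALSE]
      key <- paste(pair$pair_id, dom, sep = "|")
      amp <- if (nrow(gset)) {
        extract_all(gset, pair, min_len, max_len)
      } else .empty_amplicons()
      if (nrow(amp) == 0L) {
        warning("no amplicons for ", pair$pair_id, " (", dom, ")",
                call. = FALSE)
        mat <- build_matrix(filter_asi97(data.frame(
          qcovs = numeric(), pident = numeric(), query_id = character(),
          subject_id = character(), species_q = integer(),
          species_s = integer())), character())
        rel <- .empty_relations()
      } else {
        res <- all_vs_all(amp)
        pair_seed <- (seed + 7919 * i) %% (2^31 - 1)
        rel <- filter_asi97(res, threshold, rng_seed = pair_seed)
        mat <- build_matrix(rel, paste0("SP", sort(unique(amp$species_id))))
      }
      summ <- summarize_primer(mat, max(totals[[dom]], ncol(mat)),
                               pair$pair_id, mean_denominator)
      summ$domain <- dom
      net <- build_network(rel, lineages, species = colnames(mat))
      runs[[key]] <- list(pair_id = pair$pair_id, domain = dom,
                          amplicons = amp, relations = rel, matrix = mat,
                          network = net, otus = potential_otus(net))
      summaries[[key]] <- summ
    }
  }
  summaries <- do.call(rbind, c(summaries, list(make.row.names = FALSE)))

  frequency <- lapply(stats::setNames(nm = intersect(c("bacteria", "archaea"),
                                                     present)),
                      function(dom) {
    rels <- lapply(Filter(function(r) r$domain == dom, runs), `[[`,
                   "relations")
    names(rels) <- vapply(Filter(function(r) r$domain == dom, runs),
                          `[[`, character(1L), "pair_id")
    pair_frequency(rels)
  })

  structure(list(summaries = summaries, runs = runs, frequency = frequency,
                 lineages = lineages, qc = qc,
                 config = list(threshold = threshold, min_len = min_len,
                               max_len = max_len,
                               max_ambiguous_run = max_ambiguous_run,
                               seed = seed, n_total = as.list(totals))),
            class = "asi_screen")
}

.empty_relations <- function() {
  data.frame(pair_id = character(), species_a = character(),
             species_b = character(), pident = numeric(),
             alignment_columns = integer(), identities = integer(),
             query_id = character(), subject_id = character(),
             stringsAsFactors = FALSE)
}

#' @export
print.asi_screen <- function(x, ...) {
  s <- x$summaries
  cat("In-silico amplicon similarity screen\n")
  cat(sprintf("  genomes: %d kept, %d discarded by QC (ambiguous runs > %d)\n",
              nrow(x$qc$kept), nrow(x$qc$discarded),
              x$config$max_ambiguous_run))
  cat(sprintf("  primer pair x domain runs: %d\n",
              if (is.null(s)) 0L else nrow(s)))
  if (!is.null(s) && nrow(s)) {
    cat(sprintf("  similarity threshold: %.1f%% (full query coverage)\n",
                x$config$threshold))
    best <- s[order(-s$SC_NASI97), ][1L, ]
    cat(sprintf("  best SC-NASI97: %s (%s) = %.2f%%\n",
                best$pair_id, best$domain, best$SC_NASI97))
  }
  invisible(x)
}

#' @export
#' @method summary asi_screen
summary.asi_screen <- function(object, digits = 2, ...) {
  s <- object$summaries
  for (col in c("SC", "SC_ASI97", "SC_NASI97", "non_SC",
                "mean_asi97_per_species")) {
    s[[col]] <- round(s[[col]], digits)
  }
  s
}

#' @export
#' @method plot asi_screen
plot.asi_screen <- function(x, pair_id = NULL, domain = NULL, ...) {
  keys <- names(x$runs)
  if (!length(keys)) stop("nothing to plot", call. = FALSE)
  if (is.null(pair_id)) {
    key <- keys[[1L]]
  } else {
    key <- paste(pair_id, domain %||% sub(".*\\|", "", keys[[1L]]), sep = "|")
    if (!key %in% keys) stop("no run for ", key, call. = FALSE)
  }
  run <- x$runs[[key]]
  g <- run$network
  genus <- igraph::vertex_attr(g, "genus") %||% rep("?", igraph::vcount(g))
  pal <- grDevices::rainbow(max(1L, length(unique(genus))))
  igraph::plot.igraph(g, vertex.color = pal[as.integer(factor(genus))],
                      vertex.size = 6, vertex.label.cex = 0.6,
                      main = sub("\\|", " / ", key), ...)
  invisible(x)
}

#' Run the full pipeline from a configuration and write all outputs
#'
#' Configuration fields (list or YAML file): `genomes_fasta`,
#' `metadata_tsv`, `catalog_tsv` (optional; packaged catalog by default),
#' `outdir`, and optional `threshold` (97), `min_len` (100), `max_len`
#' (2300), `max_ambiguous_run` (20), `seed` (1), `n_total` (named list).
#' Writes, per primer pair x domain, the amplicon FASTA, relations TSV,
#' similarity-matrix TSV and GraphML network, plus a combined summary
#' TSV, per-domain frequency TSVs and a JSON manifest with per-stage
#' record counts. Outputs are deterministic given the seed.
#'
#' @param config list or path to a YAML file.
#' @return The `asi_screen` object, invisibly.
#' @export
run_all <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  for (field in c("genomes_fasta", "metadata_tsv", "outdir")) {
    if (is.null(config[[field]])) {
      stop("config is missing '", field, "'", call. = FALSE)
    }
  }
  catalog <- if (is.null(config$catalog_tsv)) {
    load_primer_catalog()
  } else load_primer_catalog(config$catalog_tsv)
  genomes <- read_genomes(config$genomes_fasta, config$metadata_tsv)

  scr <- asi_screen(
    genomes, catalog,
    threshold = config$threshold %||% 97,
    min_len = config$min_len %||% 100L,
    max_len = config$max_len %||% 2300L,
    max_ambiguous_run = config$max_ambiguous_run %||% 20L,
    seed = config$seed %||% 1L,
    n_total = unlist(config$n_total)
  )

  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  counts <- list()
  for (key in names(scr$runs)) {
    run <- scr$runs[[key]]
    stem <- file.path(outdir, gsub("\\|", "_", key))
    write_amplicon_fasta(run$amplicons, paste0(stem, ".amplicons.fasta"))
    write_relations_tsv(run$relations, paste0(stem, ".relations.tsv"))
    write.table(run$matrix, paste0(stem, ".matrix.tsv"), sep = "\t",
                quote = FALSE, col.names = NA)
    export_graph(run$network, paste0(stem, ".graphml"), "graphml")
    counts[[key]] <- list(
      n_variants = nrow(run$amplicons),
      n_species_detected = length(unique(run$amplicons$species_id)),
      n_relations = nrow(run$relations),
      n_matrix_edges = sum(run$matrix) / 2,
      n_components = nrow(run$otus)
    )
  }
  write.table(scr$summaries, file.path(outdir, "summary.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  for (dom in names(scr$frequency)) {
    write.table(scr$frequency[[dom]]$frequency,
                file.path(outdir, paste0("frequency_", dom, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(scr$frequency[[dom]]$long,
                file.path(outdir, paste0("frequency_", dom, "_long.tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  manifest <- list(
    package = "ampliscreen",
    version = as.character(utils::packageVersion("ampliscreen")),
    config = scr$config,
    n_genomes_in = nrow(genomes),
    n_genomes_kept = nrow(scr$qc$kept),
    n_genomes_discarded = nrow(scr$qc$discarded),
    runs = counts
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(scr)
}
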