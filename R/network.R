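#' Build the species similarity graph for one primer pair
#'
#' Simple undirected graph whose nodes are species and whose edges are
#' similarity relations (>=97% identity at full query coverage). Node
#' attributes carry the taxonomy ranks; edge attributes carry the percent
#' identity of the representative alignment. Detected species without any
#' relation can be included as isolated vertices via `species`.
#'
#' @param relations relation `data.frame` from [filter_asi97()].
#' @param lineages lineage `data.frame` from [species_lineages()]
#'   (optional; vertices then gain rank attributes).
#' @param species optional character vector of vertex labels to include
#'   even when isolated (e.g. all detected species).
#' @return An [igraph::graph] object.
#' @export
build_network <- function(relations, lineages = NULL, species = NULL) {
  verts <- unique(c(species, relations$species_a, relations$species_b))
  vdf <- data.frame(name = verts, stringsAsFactors = FALSE)
  if (!is.null(lineages)) {
    idx <- match(verts, lineages$species_label)
    for (r in intersect(TAXONOMY_RANKS, names(lineages))) {
      vdf[[r]] <- lineages[[r]][idx]
    }
  }
  edf <- relations[, intersect(c("species_a", "species_b", "pident"),
                               names(relations)), drop = FALSE]
  g <- igraph::graph_from_data_frame(edf, directed = FALSE, vertices = vdf)
  igraph::simplify(g, edge.attr.comb = "first")
}

#' Potential OTUs: connected components of the similarity graph
#'
#' Each connected component with at least two species is a "potential
#' OTU" -- a cluster that 97%-similarity sequence clustering could merge
#' into a single unit -- reported with the number of distinct genera,
#' families, orders and classes it spans. Isolated species are not
#' components of interest (they are the SC-NASI97 species) and are
#' omitted.
#'
#' @param graph graph from [build_network()] with rank vertex attributes.
#' @return `data.frame`: `component_id`, `members` (semicolon-joined,
#'   sorted), `n_species`, `n_genera`, `n_families`, `n_orders`,
#'   `n_classes`; sorted by decreasing size, ties by member list.
#' @export
potential_otus <- function(graph) {
  comp <- igraph::components(graph)
  rank_attr <- c(n_genera = "genus", n_families = "family",
                 n_orders = "order", n_classes = "class")
  rows <- list()
  for (cid in seq_len(comp$no)) {
    members <- names(comp$membership)[comp$membership == cid]
    if (length(members) < 2L) next
    row <- data.frame(members = paste(sort(members), collapse = ";"),
                      n_species = length(members), stringsAsFactors = FALSE)
    for (col in names(rank_attr)) {
      attr_name <- rank_attr[[col]]
      row[[col]] <- if (attr_name %in% igraph::vertex_attr_names(graph)) {
        length(unique(igraph::vertex_attr(graph, attr_name, members)))
      } else NA_integer_
    }
    rows[[length(rows) + 1L]] <- row
  }
  if (!length(rows)) {
    return(data.frame(component_id = integer(), members = character(),
                      n_species = integer(), n_genera = integer(),
                      n_families = integer(), n_orders = integer(),
                      n_classes = integer(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- out[order(-out$n_species, out$members), , drop = FALSE]
  out <- cbind(component_id = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  out
}

#' Export a similarity graph to GraphML or an edge/node-list TSV
#'
#' Both formats are lossless for nodes, edges and their attributes:
#' re-importing with [import_graph()] reproduces the component
#' decomposition and the attributes.
#'
#' @param graph graph from [build_network()].
#' @param path output file path.
#' @param format `"graphml"` or `"tsv"` (a two-section node/edge table).
#' @return `path`, invisibly.
#' @export
export_graph <- function(graph, path, format = c("graphml", "tsv")) {
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(graph, path, format = "graphml")
    return(invisible(path))
  }
  vat <- igraph::vertex_attr_names(graph)
  vnames <- igraph::V(graph)$name %||% character()
  nodes <- data.frame(record = rep("node", length(vnames)),
                      name = vnames,
                      stringsAsFactors = FALSE)
  for (a in setdiff(vat, "name")) nodes[[a]] <- igraph::vertex_attr(graph, a)
  edges <- igraph::as_data_frame(graph, what = "edges")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#nodes\t", paste(names(nodes), collapse = "\t")), con)
  if (nrow(nodes)) {
    utils::write.table(nodes, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  writeLines(paste0("#edges\t",
                    paste(c("record", names(edges)), collapse = "\t")), con)
  if (nrow(edges)) {
    utils::write.table(cbind(record = "edge", edges), con, sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Re-import a graph written by [export_graph()]
#'
#' @param path file path.
#' @param format `"graphml"` or `"tsv"`.
#' @return An [igraph::graph] object.
#' @export
import_graph <- function(path, format = c("graphml", "tsv")) {
  format <- match.arg(format)
  if (format == "graphml") {
    return(igraph::read_graph(path, format = "graphml"))
  }
  lines <- readLines(path)
  node_hdr <- grep("^#nodes\t", lines)
  edge_hdr <- grep("^#edges\t", lines)
  stopifnot(length(node_hdr) == 1L, length(edge_hdr) == 1L)
  parse_block <- function(hdr_line, body) {
    cols <- strsplit(sub("^#\\w+\t", "", hdr_line), "\t")[[1L]]
    if (!length(body)) {
      df <- as.data.frame(stats::setNames(rep(list(character()), length(cols)), cols),
                          stringsAsFactors = FALSE)
      return(df)
    }
    df <- read.delim(text = body, header = FALSE, stringsAsFactors = FALSE)
    names(df) <- cols
    df
  }
  nodes <- parse_block(lines[node_hdr],
                       lines[seq(node_hdr + 1L, edge_hdr - 1L)][
                         seq_len(max(0L, edge_hdr - node_hdr - 1L))])
  edges <- parse_block(lines[edge_hdr],
                       if (edge_hdr < length(lines))
                         lines[seq(edge_hdr + 1L, length(lines))] else character())
  nodes$record <- NULL
  edges$record <- NULL
  nodes$name <- as.character(nodes$name)
  if (nrow(edges)) {
    edges$from <- as.character(edges$from)
    edges$to <- as.character(edges$to)
  }
  igraph::graph_from_data_frame(edges, directed = FALSE, vertices = nodes)
}
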