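#' Gene classes recognised on the interaction network
#'
#' The heterogeneous interaction network carries one coding class (`mRNA`)
#' and three non-coding classes (`lncRNA`, `miRNA`, `pseudogene`).
#' Pseudogenes are treated as non-coding throughout, so an edge is
#' coding–coding only when both endpoints are mRNAs.
#'
#' @format Character vectors.
#' @name gene_classes
NULL

#' @rdname gene_classes
#' @export
GENE_CLASSES <- c("mRNA", "lncRNA", "miRNA", "pseudogene")

#' @rdname gene_classes
#' @export
NONCODING_CLASSES <- c("lncRNA", "miRNA", "pseudogene")

#' Build a typed heterogeneous interaction network
#'
#' Constructs an undirected, simple graph whose nodes are genes labelled with
#' a gene class (`mRNA`, `lncRNA`, `miRNA`, `pseudogene`). Self-loops are
#' dropped and parallel edges are collapsed to a single edge; when the edge
#' table carries a `sources` column (comma-separated provenance labels) the
#' labels of collapsed duplicates are unioned.
#'
#' @param edges Data frame whose first two columns are the edge endpoints
#'   (gene ids); an optional `sources` column carries provenance labels.
#' @param node_types Data frame with columns `id` and `gene_class`; every id
#'   appearing in `edges` must be annotated here.
#' @param quiet Suppress the message reporting dropped self-loops/duplicates.
#' @return A `typed_network` object.
#' @examples
#' edges <- tibble::tibble(source = c("a", "b"), target = c("b", "c"))
#' types <- tibble::tibble(id = c("a", "b", "c"),
#'                         gene_class = c("mRNA", "mRNA", "miRNA"))
#' net <- typed_network(edges, types)
#' net
#' @export
typed_network <- function(edges, node_types, quiet = FALSE) {
  stopifnot(is.data.frame(edges), is.data.frame(node_types))
  if (ncol(edges) < 2) {
    stop("edge table must have at least two columns (source, target)",
         call. = FALSE)
  }
  edges <- tibble::as_tibble(edges)
  names(edges)[1:2] <- c("source", "target")
  node_types <- tibble::as_tibble(node_types)
  if (!all(c("id", "gene_class") %in% names(node_types))) {
    names(node_types)[1:2] <- c("id", "gene_class")
  }
  node_types <- dplyr::distinct(node_types, .data$id, .data$gene_class)

  bad_row <- which(is.na(edges$source) | is.na(edges$target) |
                     edges$source == "" | edges$target == "")
  if (length(bad_row)) {
    stop("malformed edge row(s) at line(s): ",
         paste(head(bad_row, 5), collapse = ", "), call. = FALSE)
  }
  if (anyNA(node_types$id) || any(node_types$id == "")) {
    stop("node type table contains empty gene ids", call. = FALSE)
  }
  if (anyDuplicated(node_types$id)) {
    dup <- unique(node_types$id[duplicated(node_types$id)])
    stop("conflicting class annotations for: ",
         paste(head(dup, 5), collapse = ", "), call. = FALSE)
  }
  bad_class <- setdiff(unique(node_types$gene_class), GENE_CLASSES)
  if (length(bad_class)) {
    stop("unknown gene class(es): ", paste(bad_class, collapse = ", "),
         "; allowed: ", paste(GENE_CLASSES, collapse = ", "), call. = FALSE)
  }
  unknown <- setdiff(unique(c(edges$source, edges$target)), node_types$id)
  if (length(unknown)) {
    stop("edge endpoint(s) with no class annotation: ",
         paste(head(sort(unknown), 10), collapse = ", "), call. = FALSE)
  }

  n_loops <- sum(edges$source == edges$target)
  edges <- edges[edges$source != edges$target, , drop = FALSE]
  has_src <- "sources" %in% names(edges)
  if (!has_src) edges$sources <- NA_character_
  edges <- edges |>
    dplyr::mutate(.a = pmin(.data$source, .data$target),
                  .b = pmax(.data$source, .data$target))
  n_dup <- sum(duplicated(paste(edges$.a, edges$.b, sep = "\r")))
  edges <- edges |>
    dplyr::group_by(.data$.a, .data$.b) |>
    dplyr::summarise(
      sources = {
        lab <- unlist(strsplit(.data$sources[!is.na(.data$sources)], ","))
        if (length(lab)) paste(sort(unique(lab)), collapse = ",")
        else NA_character_
      },
      .groups = "drop") |>
    dplyr::rename(source = ".a", target = ".b")
  if (!quiet && (n_loops + n_dup) > 0) {
    message("dropped ", n_loops, " self-loop(s) and collapsed ",
            n_dup, " duplicate edge(s)")
  }

  g <- igraph::graph_from_data_frame(
    edges, directed = FALSE,
    vertices = node_types[, c("id", "gene_class")])
  structure(list(graph = g), class = "typed_network")
}

#' Read a typed network from edge-list and node-type TSV files
#'
#' @param edge_path TSV with columns `source`, `target` and optionally
#'   `sources` (comma-separated provenance labels).
#' @param types_path TSV with columns `id`, `gene_class`.
#' @param quiet Passed to [typed_network()].
#' @return A `typed_network`.
#' @seealso [write_network()] for the round-tripping writer.
#' @export
read_network <- function(edge_path, types_path, quiet = FALSE) {
  for (p in c(edge_path, types_path)) {
    if (!file.exists(p)) stop("file not found: ", p, call. = FALSE)
  }
  edges <- read_tsv_quiet(edge_path,
                          col_types = readr::cols(.default = readr::col_character()))
  types <- read_tsv_quiet(types_path,
                          col_types = readr::cols(.default = readr::col_character()))
  if (ncol(edges) < 2) {
    stop("edge list ", edge_path, " must have >= 2 columns", call. = FALSE)
  }
  typed_network(edges, types, quiet = quiet)
}

#' Write a typed network to edge-list and node-type TSVs
#'
#' `read_network(write_network(net, ...))` is the identity on nodes, edges
#' and classes.
#'
#' @param net A `typed_network`.
#' @param edge_path,types_path Output paths.
#' @return Invisibly, `net`.
#' @export
write_network <- function(net, edge_path, types_path) {
  stopifnot(inherits(net, "typed_network"))
  ed <- network_edges(net)
  readr::write_tsv(ed, edge_path, progress = FALSE)
  readr::write_tsv(network_nodes(net), types_path, progress = FALSE)
  invisible(net)
}

#' Node and edge tables of a typed network
#'
#' @param net A `typed_network`.
#' @return `network_nodes()`: tibble with `id`, `gene_class`;
#'   `network_edges()`: tibble with `source`, `target`, `sources`.
#' @export
network_nodes <- function(net) {
  stopifnot(inherits(net, "typed_network"))
  tibble::tibble(id = igraph::V(net$graph)$name,
                 gene_class = igraph::V(net$graph)$gene_class)
}

#' @rdname network_nodes
#' @export
network_edges <- function(net) {
  stopifnot(inherits(net, "typed_network"))
  ed <- igraph::as_data_frame(net$graph, what = "edges")
  tibble::tibble(source = ed$from, target = ed$to,
                 sources = ed$sources %||% NA_character_)
}

# named gene_class lookup vector
node_classes <- function(net) {
  setNames(igraph::V(net$graph)$gene_class, igraph::V(net$graph)$name)
}

#' @export
print.typed_network <- function(x, ...) {
  s <- table(igraph::V(x$graph)$gene_class)
  cat("<typed_network> ", igraph::vcount(x$graph), " nodes, ",
      igraph::ecount(x$graph), " edges\n", sep = "")
  cat("  classes:", paste(names(s), s, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Summarize network size and edge-class composition
#'
#' Each edge is classified by its endpoint classes: coding–coding (`cc`,
#' both mRNA), non-coding–non-coding (`ncnc`, neither mRNA) or mixed
#' (`mixed`, one of each). Fractions sum to one.
#'
#' @param net A nonempty `typed_network`.
#' @return A `network_summary` object; use [glance()] for a one-row tibble.
#' @examples
#' net <- typed_network(
#'   tibble::tibble(source = c("a", "a", "b"), target = c("b", "c", "c")),
#'   tibble::tibble(id = c("a", "b", "c"),
#'                  gene_class = c("mRNA", "mRNA", "miRNA")))
#' glance(network_summary(net))
#' @export
network_summary <- function(net) {
  stopifnot(inherits(net, "typed_network"))
  if (igraph::vcount(net$graph) == 0) stop("empty network", call. = FALSE)
  cls <- node_classes(net)
  ed <- network_edges(net)
  coding_a <- cls[ed$source] == "mRNA"
  coding_b <- cls[ed$target] == "mRNA"
  kind <- ifelse(coding_a & coding_b, "cc",
                 ifelse(!coding_a & !coding_b, "ncnc", "mixed"))
  n_e <- nrow(ed)
  comp <- c(cc = sum(kind == "cc"), ncnc = sum(kind == "ncnc"),
            mixed = sum(kind == "mixed"))
  structure(list(
    n_nodes = igraph::vcount(net$graph),
    n_edges = n_e,
    nodes_by_class = tibble::tibble(gene_class = GENE_CLASSES,
                                    n = vapply(GENE_CLASSES,
                                               function(k) sum(cls == k),
                                               integer(1))),
    edge_counts = comp,
    edge_composition = if (n_e > 0) comp / n_e else comp * NA_real_
  ), class = "network_summary")
}

#' @export
print.network_summary <- function(x, ...) {
  cat("<network_summary> ", x$n_nodes, " nodes, ", x$n_edges, " edges\n",
      sep = "")
  cat("  nodes:", paste(x$nodes_by_class$gene_class, x$nodes_by_class$n,
                        sep = "=", collapse = ", "), "\n")
  cat("  edges:", paste(names(x$edge_composition),
                        sprintf("%.2f%%", 100 * x$edge_composition),
                        sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' @export
glance.network_summary <- function(x, ...) {
  tibble::tibble(
    n_nodes = x$n_nodes, n_edges = x$n_edges,
    n_mrna = x$nodes_by_class$n[x$nodes_by_class$gene_class == "mRNA"],
    frac_cc = unname(x$edge_composition["cc"]),
    frac_ncnc = unname(x$edge_composition["ncnc"]),
    frac_mixed = unname(x$edge_composition["mixed"]))
}

#' Subgraph induced by a gene set
#'
#' Returns the subgraph of `net` containing exactly the requested genes that
#' are present in the network and every edge of `net` with both endpoints in
#' that set. Ids absent from the network are silently ignored (a count is
#' messaged unless `quiet`).
#'
#' @param net A `typed_network`.
#' @param genes Character vector of gene ids.
#' @param quiet Suppress the dropped-id message.
#' @return A `typed_network`.
#' @export
induced_network <- function(net, genes, quiet = TRUE) {
  stopifnot(inherits(net, "typed_network"))
  genes <- unique(as.character(genes))
  keep <- intersect(genes, igraph::V(net$graph)$name)
  if (!quiet && length(keep) < length(genes)) {
    message(length(genes) - length(keep), " id(s) absent from the network")
  }
  structure(list(graph = igraph::induced_subgraph(net$graph, keep)),
            class = "typed_network")
}

#' Unweighted shortest-path length between two genes
#'
#' @param net A `typed_network`.
#' @param u,v Gene ids present in the network.
#' @return Hop count; `Inf` when `u` and `v` are in different components;
#'   0 when `u == v`.
#' @export
path_length <- function(net, u, v) {
  stopifnot(inherits(net, "typed_network"))
  nm <- igraph::V(net$graph)$name
  missing <- setdiff(c(u, v), nm)
  if (length(missing)) {
    stop("unknown gene id(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  as.numeric(igraph::distances(net$graph, v = u, to = v, weights = NA))
}
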