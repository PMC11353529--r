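#' Largest connected component of a typed network
#'
#' Returns the node set of the maximum-size connected component. Ties between
#' equal-size components are broken deterministically: the component whose
#' sorted node-id tuple is lexicographically smallest wins.
#'
#' @param net A `typed_network` (typically an induced subgraph).
#' @return Sorted character vector of node ids; empty for an empty graph.
#' @export
largest_component <- function(net) {
  stopifnot(inherits(net, "typed_network"))
  g <- net$graph
  if (igraph::vcount(g) == 0) return(character(0))
  comp <- igraph::components(g)
  smax <- max(comp$csize)
  cand <- which(comp$csize == smax)
  members <- lapply(cand, function(i) {
    sort(igraph::V(g)$name[comp$membership == i])
  })
  members[[lex_min_index(members)]]
}

new_module_result <- function(module_nodes, n_components, iso_mrnas, net,
                              kind, beta = NA_real_) {
  cls <- node_classes(net)
  mc <- cls[module_nodes]
  structure(list(
    kind = kind,
    beta = beta,
    module_nodes = module_nodes,
    slcc = length(module_nodes),
    n_components = n_components,
    iso_mrnas = sort(iso_mrnas),
    node_classes = mc,
    member_classes = vapply(GENE_CLASSES, function(k) sum(mc == k),
                            integer(1))
  ), class = "module_result")
}

#' Coding omnigenic module (COModule)
#'
#' The COModule at threshold beta is the largest connected component of the
#' subgraph induced by the affected coding genes `DE_mRNAs(beta)`.
#'
#' @param net A `typed_network`.
#' @param affected An `affected_sets` object from [select_affected()].
#' @return A `module_result`; `iso_mrnas` is always empty for a COModule.
#' @export
comodule <- function(net, affected) {
  stopifnot(inherits(affected, "affected_sets"))
  sub <- induced_network(net, affected$de_mrnas)
  lcc <- largest_component(sub)
  n_comp <- if (igraph::vcount(sub$graph) == 0) 0L
            else igraph::components(sub$graph)$no
  new_module_result(lcc, n_comp, character(0), net, "COModule",
                    affected$cfg$beta)
}

#' Non-coding-RNA extended omnigenic module (NeOModule)
#'
#' The NeOModule is the largest connected component of the subgraph induced
#' by `DE_mRNAs(beta) U DE_ncRNAs`. Its Iso_mRNAs are the coding members
#' that lie outside the COModule — coding genes that only join the module
#' because ncRNAs bridge them in.
#'
#' @inheritParams comodule
#' @return A `module_result` whose `iso_mrnas` holds the bridged-in coding
#'   genes; the matching COModule is attached as attribute `comodule`.
#' @export
neomodule <- function(net, affected) {
  stopifnot(inherits(affected, "affected_sets"))
  co <- comodule(net, affected)
  sub <- induced_network(net, union(affected$de_mrnas, affected$de_ncrnas))
  lcc <- largest_component(sub)
  n_comp <- if (igraph::vcount(sub$graph) == 0) 0L
            else igraph::components(sub$graph)$no
  cls <- node_classes(net)
  mod_mrnas <- lcc[cls[lcc] == "mRNA"]
  iso <- setdiff(mod_mrnas, co$module_nodes)
  out <- new_module_result(lcc, n_comp, iso, net, "NeOModule",
                           affected$cfg$beta)
  attr(out, "comodule") <- co
  out
}

#' @export
print.module_result <- function(x, ...) {
  cat("<module_result> ", x$kind,
      if (!is.na(x$beta)) paste0("(beta=", x$beta, ")"),
      ": sLCC=", x$slcc, ", components=", x$n_components,
      ", Iso_mRNAs=", length(x$iso_mrnas), "\n", sep = "")
  invisible(x)
}

#' @export
tidy.module_result <- function(x, ...) {
  tibble::tibble(
    gene_id = x$module_nodes,
    gene_class = unname(x$node_classes),
    is_iso = x$module_nodes %in% x$iso_mrnas)
}

#' @export
glance.module_result <- function(x, ...) {
  tibble::tibble(
    kind = x$kind, beta = x$beta, slcc = x$slcc,
    n_components = x$n_components,
    n_mrna = unname(x$member_classes["mRNA"]),
    n_lncrna = unname(x$member_classes["lncRNA"]),
    n_mirna = unname(x$member_classes["miRNA"]),
    n_pseudogene = unname(x$member_classes["pseudogene"]),
    n_iso = length(x$iso_mrnas),
    iso_ratio = iso_ratio(x))
}

#' Fraction of module coding genes bridged in by ncRNAs
#'
#' The ratio of Iso_mRNAs to module coding genes. The denominator defaults
#' to the number of mRNAs in the module; `"module"` uses the full module
#' size instead.
#'
#' @param module A `module_result` (normally from [neomodule()]).
#' @param denominator `"mrna"` (default) or `"module"`.
#' @return A value in `[0, 1]`; 0 when the module has no coding genes.
#' @export
iso_ratio <- function(module, denominator = c("mrna", "module")) {
  stopifnot(inherits(module, "module_result"))
  denominator <- match.arg(denominator)
  den <- if (denominator == "mrna") unname(module$member_classes["mRNA"])
         else module$slcc
  if (is.na(den) || den == 0) return(0)
  length(module$iso_mrnas) / den
}

#' Enumerate ceRNA triples inside a module
#'
#' A triple is a path ncRNA–miRNA–mRNA within the subgraph induced by the
#' module nodes: an lncRNA or pseudogene and an mRNA that share a miRNA
#' neighbour, the structure under which the two can compete for the miRNA
#' (competing endogenous RNA hypothesis).
#'
#' @param net A `typed_network`.
#' @param module_nodes Gene ids, all present in `net`.
#' @param ncrna_classes Classes admitted in the ncRNA slot (default lncRNA
#'   and pseudogene; widen to include `"miRNA"` if desired).
#' @return Tibble with columns `ncrna`, `mirna`, `mrna`, deduplicated and in
#'   lexicographic order.
#' @export
enumerate_triples <- function(net, module_nodes,
                              ncrna_classes = c("lncRNA", "pseudogene")) {
  stopifnot(inherits(net, "typed_network"))
  module_nodes <- unique(as.character(module_nodes))
  missing <- setdiff(module_nodes, igraph::V(net$graph)$name)
  if (length(missing)) {
    stop("module node(s) not in network: ",
         paste(head(missing, 5), collapse = ", "), call. = FALSE)
  }
  sub <- induced_network(net, module_nodes)
  g <- sub$graph
  nm <- igraph::V(g)$name
  cls <- setNames(igraph::V(g)$gene_class, nm)
  mirs <- nm[cls == "miRNA"]
  empty <- tibble::tibble(ncrna = character(0), mirna = character(0),
                          mrna = character(0))
  if (length(mirs) == 0) return(empty)
  rows <- purrr::map(mirs, function(mi) {
    nb <- igraph::V(g)$name[as.integer(igraph::neighbors(g, mi))]
    nc <- nb[cls[nb] %in% ncrna_classes]
    mr <- nb[cls[nb] == "mRNA"]
    if (length(nc) == 0 || length(mr) == 0) return(NULL)
    tidyr::expand_grid(ncrna = nc, mrna = mr) |>
      dplyr::mutate(mirna = mi)
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) return(empty)
  out |>
    dplyr::select("ncrna", "mirna", "mrna") |>
    dplyr::distinct() |>
    dplyr::arrange(.data$ncrna, .data$mirna, .data$mrna)
}
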