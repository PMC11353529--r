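#' Configuration for the synthetic heterogeneous-network generator
#'
#' Defaults emulate the statistical structure the module detector assumes:
#' a scale-free heterogeneous network whose edge composition is dominated
#' by coding–coding interactions (target mix 87.4% coding–coding, 11.5%
#' non-coding–non-coding, 1.1% mixed) with roughly a quarter of nodes
#' non-coding, plus a planted fragmented coding module whose fragments are
#' joined only through ncRNA bridges.
#'
#' @param n_mrna,n_lnc,n_mi,n_pseudo Node counts per gene class.
#' @param attachment_m Average edges per node (total edges is
#'   `attachment_m` times the node count).
#' @param edge_mix Target fractions `c(cc, ncnc, mixed)`; must sum to 1.
#' @param n_fragments Number of planted coding fragments.
#' @param fragment_size mRNAs per fragment.
#' @param n_bridges ncRNA bridge nodes wired to every fragment.
#' @param effect_beta Floor of planted `|log2fc|`.
#' @param background_scale Exponential scale of background `|log2fc|`.
#' @param seed Integer seed driving all generator randomness.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_mrna = 1500, n_lnc = 200, n_mi = 200,
                             n_pseudo = 100, attachment_m = 5,
                             edge_mix = c(cc = 0.874, ncnc = 0.115,
                                          mixed = 0.011),
                             n_fragments = 3, fragment_size = 15,
                             n_bridges = 4, effect_beta = 3,
                             background_scale = 0.3, seed = 1) {
  counts <- c(n_mrna, n_lnc, n_mi, n_pseudo)
  if (any(counts < 0) || n_mrna < 2) {
    stop("class counts must be non-negative with n_mrna >= 2", call. = FALSE)
  }
  if (length(edge_mix) != 3 || abs(sum(edge_mix) - 1) > 1e-9) {
    stop("edge_mix must be three fractions summing to 1", call. = FALSE)
  }
  names(edge_mix) <- c("cc", "ncnc", "mixed")
  structure(list(
    n_mrna = n_mrna, n_lnc = n_lnc, n_mi = n_mi, n_pseudo = n_pseudo,
    attachment_m = attachment_m, edge_mix = edge_mix,
    n_fragments = n_fragments, fragment_size = fragment_size,
    n_bridges = n_bridges, effect_beta = effect_beta,
    background_scale = background_scale, seed = as.integer(seed)
  ), class = "synthetic_config")
}

# heavy-tailed simple graph on n nodes with exactly n_edges edges
# (power-law fitness), as an edge index matrix
fitness_edges <- function(n, n_edges, exponent = 2.1) {
  if (n_edges == 0 || n < 2) return(matrix(integer(0), ncol = 2))
  max_e <- n * (n - 1) / 2
  if (n_edges > max_e) {
    stop("requested more edges than pairs allow", call. = FALSE)
  }
  g <- igraph::sample_fitness_pl(n, n_edges, exponent.out = exponent,
                                 loops = FALSE, multiple = FALSE)
  igraph::as_edgelist(g, names = FALSE)
}

#' Generate a synthetic scale-free heterogeneous network
#'
#' Builds a typed network whose realized edge-class composition lies within
#' 0.05 of `cfg$edge_mix`: a power-law-fitness graph over the mRNAs for the
#' coding–coding block, another over the pooled ncRNAs for the
#' non-coding–non-coding block, degree-biased mixed edges between the two,
#' and finally one connecting edge per stray component (class-compatible
#' endpoints) so that the network is connected. Deterministic under
#' `cfg$seed`.
#'
#' @param cfg A [synthetic_config()].
#' @return A `typed_network`.
#' @export
generate_network <- function(cfg = synthetic_config()) {
  stopifnot(inherits(cfg, "synthetic_config"))
  n_nc <- cfg$n_lnc + cfg$n_mi + cfg$n_pseudo
  n_tot <- cfg$n_mrna + n_nc
  e_tot <- round(cfg$attachment_m * n_tot)
  e_cc <- round(cfg$edge_mix[["cc"]] * e_tot)
  e_nn <- round(cfg$edge_mix[["ncnc"]] * e_tot)
  e_mx <- e_tot - e_cc - e_nn
  if ((e_nn > 0 && n_nc < 2) || (e_mx > 0 && n_nc < 1)) {
    stop("edge mix infeasible for the given class counts", call. = FALSE)
  }

  withr::with_seed(cfg$seed, {
    mrna_ids <- sprintf("G%05d", seq_len(cfg$n_mrna))
    nc_ids <- c(sprintf("LNC%04d", seq_len(cfg$n_lnc)),
                sprintf("MIR%04d", seq_len(cfg$n_mi)),
                sprintf("PSG%04d", seq_len(cfg$n_pseudo)))
    nc_cls <- c(rep("lncRNA", cfg$n_lnc), rep("miRNA", cfg$n_mi),
                rep("pseudogene", cfg$n_pseudo))
    if (n_nc > 0) {  # decouple degree from class
      ord <- sample(n_nc)
      nc_ids <- nc_ids[ord]
    }
    node_types <- tibble::tibble(
      id = c(mrna_ids, nc_ids),
      gene_class = c(rep("mRNA", cfg$n_mrna), nc_cls))

    cc <- fitness_edges(cfg$n_mrna, e_cc)
    cc_edges <- tibble::tibble(source = mrna_ids[cc[, 1]],
                               target = mrna_ids[cc[, 2]])
    nn_edges <- tibble::tibble(source = character(0), target = character(0))
    if (e_nn > 0) {
      nn <- fitness_edges(n_nc, e_nn)
      nn_edges <- tibble::tibble(source = nc_ids[nn[, 1]],
                                 target = nc_ids[nn[, 2]])
    }
    mx_edges <- tibble::tibble(source = character(0), target = character(0))
    if (e_mx > 0 && n_nc > 0) {
      deg_m <- tabulate(as.vector(cc), nbins = cfg$n_mrna) + 1
      deg_n <- tabulate(as.vector(if (e_nn > 0) nn else
                                    matrix(integer(0), ncol = 2)),
                        nbins = n_nc) + 1
      pick <- unique(tibble::tibble(
        source = sample(nc_ids, 4 * e_mx, replace = TRUE, prob = deg_n),
        target = sample(mrna_ids, 4 * e_mx, replace = TRUE, prob = deg_m)))
      mx_edges <- head(pick, e_mx)
    }
    edges <- dplyr::bind_rows(cc_edges, nn_edges, mx_edges)
    net <- typed_network(edges, node_types, quiet = TRUE)

    # stitch stray components to the giant one, keeping endpoints in the
    # same coding status so the edge mix barely moves
    comp <- igraph::components(net$graph)
    if (comp$no > 1) {
      nm <- igraph::V(net$graph)$name
      cls <- node_classes(net)
      giant <- which.max(comp$csize)
      giant_nodes <- nm[comp$membership == giant]
      extra <- purrr::map_dfr(setdiff(seq_len(comp$no), giant), function(ci) {
        v <- sample(nm[comp$membership == ci], 1)
        pool <- giant_nodes[(cls[giant_nodes] == "mRNA") ==
                              (cls[[v]] == "mRNA")]
        if (length(pool) == 0) pool <- giant_nodes
        tibble::tibble(source = v, target = sample(pool, 1))
      })
      net <- typed_network(dplyr::bind_rows(edges, extra), node_types,
                           quiet = TRUE)
    }

    realized <- network_summary(net)$edge_composition
    if (any(abs(realized - cfg$edge_mix[names(realized)]) > 0.05)) {
      stop("realized edge mix deviates from target by more than 0.05",
           call. = FALSE)
    }
    net
  })
}

#' Plant a fragmented coding module joined by ncRNA bridges
#'
#' Selects `n_fragments` connected mRNA clusters that are pairwise
#' disconnected within the subgraph induced by all planted mRNAs, then
#' wires `n_bridges` ncRNA nodes to one gene of every fragment, so that the
#' fragments are joined only through ncRNA paths. This is the ground-truth
#' construction for benchmarking: the coding-only module sees one fragment
#' at a time while the ncRNA-extended module recovers all of them.
#'
#' @param net A `typed_network` (modified copy is returned).
#' @param cfg A [synthetic_config()].
#' @param max_tries Resampling budget for the disconnection constraint.
#' @return List with `planted_mrnas`, `bridges`, `fragments` (list of id
#'   vectors) and the modified `net`.
#' @export
plant_bridged_module <- function(net, cfg = synthetic_config(),
                                 max_tries = 500) {
  stopifnot(inherits(net, "typed_network"),
            inherits(cfg, "synthetic_config"))
  cls <- node_classes(net)
  mrnas <- names(cls)[cls == "mRNA"]
  ncs <- names(cls)[cls != "mRNA"]
  if (length(mrnas) < cfg$n_fragments * cfg$fragment_size) {
    stop("not enough mRNA nodes to plant the fragments", call. = FALSE)
  }
  if (length(ncs) < cfg$n_bridges) {
    stop("not enough ncRNA nodes for the bridges", call. = FALSE)
  }
  g_m <- induced_network(net, mrnas)$graph

  withr::with_seed(cfg$seed + 1L, {
    deg_m <- igraph::degree(g_m)
    nbrs_of <- function(ids) {
      unique(unlist(lapply(igraph::adjacent_vertices(g_m, ids),
                           function(vs) igraph::V(g_m)$name[as.integer(vs)])))
    }
    fragments <- list()
    used <- character(0)
    nb_used <- character(0)  # external coding neighbours of fragments
    tries <- 0
    while (length(fragments) < cfg$n_fragments && tries < max_tries) {
      tries <- tries + 1
      # candidates grow outside previous fragments and their coding
      # neighbourhoods (coding distance >= 2)
      forbidden <- if (length(used)) unique(c(used, nb_used)) else used
      allowed <- setdiff(mrnas, forbidden)
      if (length(allowed) < cfg$fragment_size) break
      # grow over low-degree (peripheral) coding genes: affected genes in
      # the omnigenic picture sit at the network margin, and compact
      # neighbourhoods keep the planted fragments cleanly separated
      low <- allowed[deg_m[allowed] <= stats::quantile(deg_m[allowed],
                                                       0.5)]
      start <- sample(if (length(low)) low else allowed, 1)
      frag <- start
      frontier <- setdiff(intersect(nbrs_of(start), allowed), frag)
      while (length(frag) < cfg$fragment_size && length(frontier) > 0) {
        nxt <- frontier[order(deg_m[frontier],
                              stats::runif(length(frontier)))][1]
        frag <- c(frag, nxt)
        frontier <- setdiff(
          unique(c(frontier, intersect(nbrs_of(nxt), allowed))), frag)
      }
      if (length(frag) < cfg$fragment_size) next
      fragments[[length(fragments) + 1]] <- frag
      used <- c(used, frag)
      nb_used <- union(nb_used, setdiff(nbrs_of(frag), frag))
    }
    if (length(fragments) < cfg$n_fragments) {
      stop("could not place ", cfg$n_fragments,
           " disconnected fragments within ", max_tries, " tries",
           call. = FALSE)
    }
    bridges <- sample(ncs, cfg$n_bridges)
    extra <- purrr::map_dfr(bridges, function(b) {
      tibble::tibble(source = b,
                     target = vapply(fragments, function(fr)
                       sample(fr, 1), character(1)))
    })
    edges <- dplyr::bind_rows(network_edges(net)[, c("source", "target")],
                              extra)
    net2 <- typed_network(edges, network_nodes(net), quiet = TRUE)
    list(planted_mrnas = sort(used), bridges = sort(bridges),
         fragments = fragments, net = net2)
  })
}

#' Generate a perturbation table with planted effects
#'
#' Ground-truth genes receive `|log2fc| = effect_beta + Exp(background_scale)`
#' and background genes `|log2fc| ~ Exp(background_scale)`, each with a
#' random sign.
#'
#' When `fragments` and `net` are supplied the draw is additionally
#' conditioned on benchmark identifiability: no background coding gene with
#' a perturbation within one log2 unit of the planted floor may neighbour
#' two planted fragments (such a gene would silently fuse them and corrupt
#' the planted ground truth). Violating tables — rare under the defaults —
#' are redrawn by rejection sampling.
#'
#' @param ground_truth Planted gene ids (subset of `all_nodes`).
#' @param all_nodes All gene ids to emit.
#' @param cfg A [synthetic_config()].
#' @param fragments Optional list of planted coding fragments (from
#'   [plant_bridged_module()]) for the identifiability guarantee.
#' @param net The `typed_network` the fragments live in (required with
#'   `fragments`).
#' @return Tibble `gene_id`, `log2fc`.
#' @export
generate_perturbations <- function(ground_truth, all_nodes,
                                   cfg = synthetic_config(),
                                   fragments = NULL, net = NULL) {
  stopifnot(inherits(cfg, "synthetic_config"))
  ground_truth <- unique(as.character(ground_truth))
  all_nodes <- unique(as.character(all_nodes))
  if (length(setdiff(ground_truth, all_nodes))) {
    stop("ground_truth must be a subset of all_nodes", call. = FALSE)
  }
  glue_capable <- character(0)
  if (!is.null(fragments)) {
    stopifnot(inherits(net, "typed_network"))
    cls <- node_classes(net)
    mrnas <- names(cls)[cls == "mRNA"]
    g_m <- induced_network(net, mrnas)$graph
    planted_all <- unlist(fragments)
    touch <- sapply(fragments, function(fr) {
      nb <- unique(unlist(lapply(
        igraph::adjacent_vertices(g_m, intersect(fr, mrnas)),
        function(vs) igraph::V(g_m)$name[as.integer(vs)])))
      mrnas %in% setdiff(nb, planted_all)
    })
    glue_capable <- mrnas[rowSums(touch) >= 2]
  }
  draw <- function(seed) {
    withr::with_seed(seed, {
      n <- length(all_nodes)
      mag <- rexp(n, rate = 1 / cfg$background_scale)
      planted <- all_nodes %in% ground_truth
      mag[planted] <- cfg$effect_beta + mag[planted]
      sgn <- sample(c(-1, 1), n, replace = TRUE)
      tibble::tibble(gene_id = all_nodes, log2fc = sgn * mag)
    })
  }
  floor_thr <- max(cfg$effect_beta - 1, 0)
  for (attempt in 0:49) {
    tab <- draw(cfg$seed + 2L + 1000L * attempt)
    if (length(glue_capable) == 0) return(tab)
    hot <- tab$gene_id %in% setdiff(glue_capable, ground_truth) &
      abs(tab$log2fc) >= floor_thr
    if (!any(hot)) return(tab)
  }
  stop("could not draw an identifiable perturbation table", call. = FALSE)
}

#' Generate a synthetic drug benchmark
#'
#' Positive drugs (known indication for `disease`) target genes inside or
#' adjacent to the module; `positive_mode = "module_only"` restricts
#' positives to module members (forced separation, downstream AUC 1).
#' Negative drugs target uniformly random non-module genes. With
#' `positive_mode = "background"` positives are drawn exactly like
#' negatives — a null benchmark whose expected AUC is 0.5.
#'
#' @param net A `typed_network`.
#' @param module Nonempty module gene ids.
#' @param n_pos,n_neg Drug counts.
#' @param n_targets Targets per drug.
#' @param disease Disease label attached to positive drugs.
#' @param positive_mode `"module"` (default), `"module_only"` or
#'   `"background"`.
#' @param seed Integer seed.
#' @return Tibble `drug_id`, `targets` (list), `indications` (list).
#' @export
generate_drug_benchmark <- function(net, module, n_pos = 10, n_neg = 30,
                                    n_targets = 3, disease = "SIM",
                                    positive_mode = c("module",
                                                      "module_only",
                                                      "background"),
                                    seed = 1) {
  positive_mode <- match.arg(positive_mode)
  stopifnot(inherits(net, "typed_network"))
  nm <- igraph::V(net$graph)$name
  module <- intersect(unique(as.character(module)), nm)
  if (length(module) == 0) stop("empty module", call. = FALSE)
  nbrs <- unique(unlist(lapply(
    igraph::adjacent_vertices(net$graph, module),
    function(vs) nm[as.integer(vs)])))
  pos_pool <- union(module, nbrs)
  neg_pool <- setdiff(nm, module)
  withr::with_seed(as.integer(seed), {
    draw <- function(pool) sample(pool, min(n_targets, length(pool)))
    pos <- lapply(seq_len(n_pos), function(i) {
      switch(positive_mode,
             module = draw(pos_pool),
             module_only = draw(module),
             background = draw(neg_pool))
    })
    neg <- lapply(seq_len(n_neg), function(i) draw(neg_pool))
    tibble::tibble(
      drug_id = c(sprintf("DPOS%03d", seq_len(n_pos)),
                  sprintf("DNEG%03d", seq_len(n_neg))),
      targets = c(pos, neg),
      indications = c(replicate(n_pos, disease, simplify = FALSE),
                      replicate(n_neg, character(0), simplify = FALSE)))
  })
}
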