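#' Jaccard coefficient of two gene sets
#'
#' @param a,b Character vectors (not both empty).
#' @return `|a n b| / |a u b|` in `[0, 1]`.
#' @export
jaccard <- function(a, b) {
  a <- unique(as.character(a)); b <- unique(as.character(b))
  if (length(a) == 0 && length(b) == 0) {
    stop("both sets are empty", call. = FALSE)
  }
  length(intersect(a, b)) / length(union(a, b))
}

#' Pairwise module similarity between diseases
#'
#' Jaccard similarity between the (optionally filtered) module gene sets of
#' every disease pair.
#'
#' @param modules Named list (>= 2 diseases) of gene-id vectors or
#'   `module_result` objects. The `mrna_only` and `iso_only` filters require
#'   `module_result` inputs (which carry node classes and Iso_mRNAs).
#' @param gene_filter `"all"`, `"mrna_only"` or `"iso_only"`.
#' @return A `similarity_matrix` object (labels + symmetric matrix with
#'   unit diagonal for nonempty filtered sets; `NA` diagonal for empty
#'   ones). [tidy()] returns the long pair table.
#' @export
pairwise_similarity <- function(modules,
                                gene_filter = c("all", "mrna_only",
                                                "iso_only")) {
  gene_filter <- match.arg(gene_filter)
  if (length(modules) < 2 || is.null(names(modules)) ||
      any(names(modules) == "")) {
    stop("modules must be a named list of >= 2 diseases", call. = FALSE)
  }
  sets <- lapply(modules, function(m) {
    if (inherits(m, "module_result")) {
      switch(gene_filter,
             all = m$module_nodes,
             mrna_only = m$module_nodes[m$node_classes == "mRNA"],
             iso_only = m$iso_mrnas)
    } else {
      if (gene_filter != "all") {
        stop("gene_filter '", gene_filter,
             "' requires module_result inputs", call. = FALSE)
      }
      unique(as.character(m))
    }
  })
  labs <- names(sets)
  k <- length(labs)
  vals <- matrix(NA_real_, k, k, dimnames = list(labs, labs))
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (j < i) next
      vals[i, j] <- if (length(sets[[i]]) == 0 && length(sets[[j]]) == 0) {
        if (i == j) NA_real_ else 0
      } else {
        jaccard(sets[[i]], sets[[j]])
      }
      vals[j, i] <- vals[i, j]
    }
  }
  structure(list(labels = labs, values = vals), class = "similarity_matrix")
}

#' @export
print.similarity_matrix <- function(x, digits = 3, ...) {
  cat("<similarity_matrix> ", length(x$labels), " diseases\n", sep = "")
  print(round(x$values, digits))
  invisible(x)
}

#' @export
tidy.similarity_matrix <- function(x, ...) {
  k <- length(x$labels)
  idx <- which(upper.tri(x$values), arr.ind = TRUE)
  tibble::tibble(
    disease_a = x$labels[idx[, 1]],
    disease_b = x$labels[idx[, 2]],
    similarity = x$values[idx])
}

#' Read a labelled square similarity matrix from TSV
#'
#' First column holds row labels; remaining column names are the column
#' labels.
#'
#' @param path TSV path.
#' @return A `similarity_matrix`.
#' @export
read_similarity_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- read_tsv_quiet(path)
  labs <- as.character(tab[[1]])
  vals <- as.matrix(tab[, -1, drop = FALSE])
  rownames(vals) <- labs
  if (!setequal(labs, colnames(vals))) {
    stop("row and column labels differ in ", path, call. = FALSE)
  }
  vals <- vals[labs, labs]
  structure(list(labels = labs, values = vals), class = "similarity_matrix")
}

#' Correlate a module-based similarity matrix with a reference
#'
#' Pearson correlation over the strict upper triangle of the two matrices
#' after aligning on the shared disease labels; pairs with a missing
#' reference value are dropped.
#'
#' @param ours,reference `similarity_matrix` objects (or square labelled
#'   matrices).
#' @return Pearson r.
#' @export
correlate_similarities <- function(ours, reference) {
  as_sm <- function(x) {
    if (inherits(x, "similarity_matrix")) x
    else structure(list(labels = rownames(x), values = x),
                   class = "similarity_matrix")
  }
  ours <- as_sm(ours); reference <- as_sm(reference)
  shared <- intersect(ours$labels, reference$labels)
  if (length(shared) < 3) {
    stop("need at least 3 shared diseases", call. = FALSE)
  }
  a <- ours$values[shared, shared]
  b <- reference$values[shared, shared]
  ut <- upper.tri(a)
  xa <- a[ut]; xb <- b[ut]
  keep <- is.finite(xa) & is.finite(xb)
  if (sum(keep) < 3) stop("fewer than 3 shared pairs", call. = FALSE)
  if (sd(xa[keep]) == 0 || sd(xb[keep]) == 0) return(NA_real_)
  cor(xa[keep], xb[keep])
}

#' Network proximity of a drug target set to a disease module
#'
#' Mean over targets of the closest shortest-path distance to any module
#' gene (the standard closest-distance form of target–module proximity).
#' Targets unreachable from every module gene contribute nothing when other
#' targets reach the module; when none do, the distance is `Inf`.
#'
#' @param net A `typed_network`.
#' @param targets Drug target gene ids (at least one present in `net`).
#' @param module Nonempty module gene ids.
#' @param method `"closest"` (default, mean of per-target minima) or
#'   `"mean_all"` (mean over all target-module pairs).
#' @return Non-negative distance, 0 iff some network target lies in the
#'   module.
#' @export
drug_module_distance <- function(net, targets, module,
                                 method = c("closest", "mean_all")) {
  method <- match.arg(method)
  stopifnot(inherits(net, "typed_network"))
  nm <- igraph::V(net$graph)$name
  targets <- intersect(unique(as.character(targets)), nm)
  module <- intersect(unique(as.character(module)), nm)
  if (length(targets) == 0) stop("no target in the network", call. = FALSE)
  if (length(module) == 0) stop("empty module", call. = FALSE)
  d <- igraph::distances(net$graph, v = targets, to = module, weights = NA)
  per_target <- if (method == "closest") apply(d, 1, min)
                else apply(d, 1, mean)
  reach <- per_target[is.finite(per_target)]
  if (length(reach) == 0) return(Inf)
  mean(reach)
}

#' Rank drugs by module proximity and evaluate with ROC/AUC
#'
#' Computes the module distance for every drug, ranks drugs from closest to
#' farthest (ties broken by drug id), labels each drug positive when the
#' disease appears among its known indications, and builds the ROC using
#' score = -distance. Tied scores contribute their average rank, so the AUC
#' equals the probability that a random positive outranks a random negative
#' (ties count one half).
#'
#' @param net A `typed_network`.
#' @param drugs Tibble with columns `drug_id`, `targets` (list column of id
#'   vectors) and `indications` (list column of disease names).
#' @param module Nonempty module gene ids.
#' @param disease Disease name used to label positives.
#' @param method Passed to [drug_module_distance()].
#' @return A `proximity_ranking` with elements `ranking` (tibble `drug_id`,
#'   `distance`, `rank`, `label`), `roc` (tibble `fpr`, `tpr`), `auc`,
#'   `disease`.
#' @export
rank_and_auc <- function(net, drugs, module, disease,
                         method = c("closest", "mean_all")) {
  method <- match.arg(method)
  stopifnot(is.data.frame(drugs),
            all(c("drug_id", "targets", "indications") %in% names(drugs)))
  label <- purrr::map_lgl(drugs$indications, ~ disease %in% .x)
  if (!any(label) || all(label)) {
    stop("need at least one positive and one negative drug for '",
         disease, "'", call. = FALSE)
  }
  dist <- purrr::map_dbl(drugs$targets, function(tg) {
    tryCatch(drug_module_distance(net, tg, module, method),
             error = function(e) Inf)
  })
  ord <- order(dist, drugs$drug_id)
  ranking <- tibble::tibble(
    drug_id = drugs$drug_id[ord],
    distance = dist[ord],
    rank = seq_along(ord),
    label = label[ord])
  score <- -ranking$distance
  n1 <- sum(ranking$label); n0 <- sum(!ranking$label)
  r <- rank(score)  # average ranks under ties
  auc <- (sum(r[ranking$label]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  # ROC points at decreasing score thresholds
  thr <- sort(unique(score), decreasing = TRUE)
  roc <- purrr::map_dfr(c(Inf, thr), function(t) {
    tibble::tibble(fpr = sum(!ranking$label & score >= t) / n0,
                   tpr = sum(ranking$label & score >= t) / n1)
  })
  structure(list(ranking = ranking, roc = roc, auc = auc,
                 disease = disease),
            class = "proximity_ranking")
}

#' @export
print.proximity_ranking <- function(x, ...) {
  cat("<proximity_ranking> ", x$disease, ": ", nrow(x$ranking),
      " drugs, AUC=", sprintf("%.3f", x$auc), "\n", sep = "")
  print(head(x$ranking, 5))
  invisible(x)
}

#' @export
tidy.proximity_ranking <- function(x, ...) x$ranking

#' @export
glance.proximity_ranking <- function(x, ...) {
  tibble::tibble(disease = x$disease, n_drugs = nrow(x$ranking),
                 n_positive = sum(x$ranking$label), auc = x$auc)
}

#' Read a GMT gene-set collection
#'
#' @param path GMT path.
#' @return Named list of gene-id vectors.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  fgsea::gmtPathways(path)
}

#' Hypergeometric over-representation analysis
#'
#' One-sided hypergeometric (Fisher) enrichment of a module in each gene
#' set of a collection, with Benjamini–Hochberg adjusted q-values. Gene
#' sets and the module are intersected with the background universe first.
#'
#' @param module Gene ids (subset of `background`; extras are dropped with
#'   a message).
#' @param collection Named list of gene-id vectors.
#' @param background Nonempty background universe of gene ids.
#' @param fdr_method Adjustment method passed to [stats::p.adjust()]
#'   (default `"BH"`).
#' @return Tibble `set_name`, `set_size`, `overlap`, `p`, `q`, ordered by
#'   `p`; zero-overlap sets get `p = 1`.
#' @export
ora_enrichment <- function(module, collection, background,
                           fdr_method = "BH") {
  background <- unique(as.character(background))
  if (length(background) == 0) stop("empty background", call. = FALSE)
  module0 <- unique(as.character(module))
  module <- intersect(module0, background)
  if (length(module) < length(module0)) {
    message(length(module0) - length(module),
            " module gene(s) outside the background were dropped")
  }
  N <- length(background)
  k <- length(module)
  res <- purrr::imap_dfr(collection, function(set, nm) {
    s <- intersect(unique(as.character(set)), background)
    ov <- length(intersect(s, module))
    p <- if (ov == 0) 1 else
      phyper(ov - 1, length(s), N - length(s), k, lower.tail = FALSE)
    tibble::tibble(set_name = nm, set_size = length(s), overlap = ov, p = p)
  })
  res$q <- p.adjust(res$p, method = fdr_method)
  dplyr::arrange(res, .data$p, .data$set_name)
}
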