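#' Perturbation degree of a gene
#'
#' The perturbation degree f_g of a gene in a disease state is the absolute
#' log2 fold change between disease and normal samples; up- and
#' down-regulation are treated symmetrically.
#'
#' @param logfc Numeric vector of log2 fold changes (finite).
#' @return `|logfc|`.
#' @export
perturbation_degree <- function(logfc) {
  if (!is.numeric(logfc) || length(logfc) == 0 || any(!is.finite(logfc))) {
    stop("logfc must be finite numeric", call. = FALSE)
  }
  abs(logfc)
}

#' Read a differential-expression table
#'
#' @param path TSV with header `gene_id  log2fc  [padj]`.
#' @return Tibble with columns `gene_id`, `log2fc` and optionally `padj`.
#' @export
read_de_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- read_tsv_quiet(path)
  if (ncol(tab) < 2) stop("DE table needs >= 2 columns", call. = FALSE)
  names(tab)[1:2] <- c("gene_id", "log2fc")
  if (ncol(tab) >= 3 && !"padj" %in% names(tab)) names(tab)[3] <- "padj"
  tab$gene_id <- as.character(tab$gene_id)
  tab$log2fc <- as.numeric(tab$log2fc)
  tab
}

#' Perturbation threshold configuration
#'
#' beta is the perturbation threshold for coding genes; the gamma values are
#' the per-class thresholds for lncRNAs, miRNAs and pseudogenes. An optional
#' adjusted-p cut filters rows before thresholding (off by default).
#'
#' @param beta Non-negative mRNA threshold on `|log2fc|`.
#' @param gamma_lnc,gamma_mi,gamma_pseudo Non-negative per-class ncRNA
#'   thresholds (defaults 1).
#' @param padj_cut Optional adjusted-p cutoff in `[0, 1]`.
#' @return A `threshold_config` list.
#' @export
threshold_config <- function(beta = 1.5, gamma_lnc = 1, gamma_mi = 1,
                             gamma_pseudo = 1, padj_cut = NULL) {
  vals <- c(beta = beta, gamma_lnc = gamma_lnc, gamma_mi = gamma_mi,
            gamma_pseudo = gamma_pseudo)
  if (any(!is.finite(vals)) || any(vals < 0)) {
    stop("all thresholds must be finite and >= 0", call. = FALSE)
  }
  if (!is.null(padj_cut) &&
      (!is.numeric(padj_cut) || padj_cut < 0 || padj_cut > 1)) {
    stop("padj_cut must be in [0, 1]", call. = FALSE)
  }
  structure(list(beta = beta, gamma_lnc = gamma_lnc, gamma_mi = gamma_mi,
                 gamma_pseudo = gamma_pseudo, padj_cut = padj_cut),
            class = "threshold_config")
}

#' Select disease-affected coding and non-coding gene sets
#'
#' Projects a differential-expression table onto the network and selects
#' `DE_mRNAs(beta) = {g in mRNAs : f_g >= beta}` and, per non-coding class,
#' `DE_ncRNAs = {g : f_g >= gamma_class}`. Genes absent from the network are
#' excluded. When `padj_cut` is set, rows with `padj > padj_cut` are removed
#' before thresholding.
#'
#' @param table Data frame with columns `gene_id`, `log2fc`, optional `padj`.
#' @param net A `typed_network`.
#' @param cfg A [threshold_config()].
#' @param quiet Suppress the not-in-network message.
#' @return An `affected_sets` object with elements `de_mrnas`, `de_ncrnas`
#'   (character vectors) and `by_class` (tibble gene_id/gene_class/pdeg).
#' @export
select_affected <- function(table, net, cfg = threshold_config(),
                            quiet = TRUE) {
  stopifnot(is.data.frame(table), inherits(net, "typed_network"),
            inherits(cfg, "threshold_config"))
  if (nrow(table) == 0) stop("empty perturbation table", call. = FALSE)
  tab <- tibble::as_tibble(table)
  if (!all(c("gene_id", "log2fc") %in% names(tab))) {
    names(tab)[1:2] <- c("gene_id", "log2fc")
  }
  tab <- dplyr::distinct(tab, .data$gene_id, .keep_all = TRUE)
  if (!is.null(cfg$padj_cut) && "padj" %in% names(tab)) {
    tab <- tab[!is.na(tab$padj) & tab$padj <= cfg$padj_cut, , drop = FALSE]
  }
  cls <- node_classes(net)
  in_net <- tab$gene_id %in% names(cls)
  if (!quiet && any(!in_net)) {
    message(sum(!in_net), " gene(s) in the table are absent from the network")
  }
  tab <- tab[in_net, , drop = FALSE]
  tab$gene_class <- unname(cls[tab$gene_id])
  tab$pdeg <- perturbation_degree(tab$log2fc)
  gam <- c(lncRNA = cfg$gamma_lnc, miRNA = cfg$gamma_mi,
           pseudogene = cfg$gamma_pseudo)
  thr <- ifelse(tab$gene_class == "mRNA", cfg$beta, gam[tab$gene_class])
  sel <- tab[tab$pdeg >= thr, , drop = FALSE]
  structure(list(
    de_mrnas = sort(sel$gene_id[sel$gene_class == "mRNA"]),
    de_ncrnas = sort(sel$gene_id[sel$gene_class != "mRNA"]),
    by_class = tibble::as_tibble(
      sel[order(sel$gene_id), c("gene_id", "gene_class", "pdeg")]),
    cfg = cfg
  ), class = "affected_sets")
}

#' @export
print.affected_sets <- function(x, ...) {
  cat("<affected_sets> beta=", x$cfg$beta, ": ",
      length(x$de_mrnas), " DE_mRNAs, ",
      length(x$de_ncrnas), " DE_ncRNAs\n", sep = "")
  invisible(x)
}

#' @export
tidy.affected_sets <- function(x, ...) x$by_class

#' Affected sets over a grid of coding thresholds
#'
#' Applies [select_affected()] at each beta of a strictly increasing grid;
#' the selected coding sets are antitone in beta (a higher threshold selects
#' a subset).
#'
#' @param table,net As in [select_affected()].
#' @param betas Strictly increasing numeric vector of coding thresholds.
#' @param cfg A [threshold_config()]; its `beta` is ignored in favour of
#'   each grid value.
#' @return Named list of `affected_sets`, one per beta.
#' @export
threshold_grid <- function(table, net, betas, cfg = threshold_config()) {
  if (length(betas) == 0 || !is.numeric(betas) || anyNA(betas) ||
      (length(betas) > 1 && any(diff(betas) <= 0))) {
    stop("betas must be strictly increasing", call. = FALSE)
  }
  out <- lapply(betas, function(b) {
    c2 <- cfg
    c2$beta <- b
    select_affected(table, net, c2)
  })
  names(out) <- as.character(betas)
  out
}
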