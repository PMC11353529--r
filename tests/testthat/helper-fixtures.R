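# small typed networks from compact edge strings like c("a-b", "b-c")
tn <- function(edge_str, classes) {
  sp <- strsplit(edge_str, "-", fixed = TRUE)
  edges <- tibble::tibble(source = vapply(sp, `[`, "", 1),
                          target = vapply(sp, `[`, "", 2))
  typed_network(edges,
                tibble::tibble(id = names(classes),
                               gene_class = unname(classes)),
                quiet = TRUE)
}

# random Erdos-Renyi typed network with isolated nodes kept
random_typed_net <- function(n = 30, p = 0.12, seed = 1,
                             class_prob = c(0.6, 0.15, 0.15, 0.1)) {
  withr::with_seed(seed, {
    g <- igraph::sample_gnp(n, p)
    ids <- sprintf("n%03d", seq_len(n))
    cls <- sample(GENE_CLASSES, n, replace = TRUE, prob = class_prob)
    el <- igraph::as_edgelist(g)
    edges <- if (nrow(el) > 0) {
      tibble::tibble(source = ids[el[, 1]], target = ids[el[, 2]])
    } else {
      tibble::tibble(source = ids[1], target = ids[2])
    }
    typed_network(edges, tibble::tibble(id = ids, gene_class = cls),
                  quiet = TRUE)
  })
}

# directory with the paper's deposited supplementary tables converted to
# TSV; reproduction tests require it and fail when it is not supplied
paper_data_dir <- function() Sys.getenv("NEOMODULE_PAPER_DATA", "")
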