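#' Pipeline configuration
#'
#' Declarative configuration for a full multi-disease run: network and
#' node-type paths, one differential-expression table per disease, module
#' thresholds, the randomization scheme, and optional drug, gene-set and
#' reference-similarity inputs.
#'
#' @param network,types Paths to the edge-list and node-type TSVs.
#' @param de_tables Named character vector/list: disease -> DE table path.
#' @param out_dir Output directory (created if absent).
#' @param thresholds A [threshold_config()].
#' @param randomization A [randomization_config()].
#' @param drugs Optional TSV `drug_id  target_id`.
#' @param indications Optional TSV `drug_id  disease`.
#' @param gene_sets Optional GMT path for enrichment.
#' @param reference_similarity Optional named vector of labelled square
#'   similarity TSVs.
#' @param seed Integer seed recorded in every output.
#' @return A validated `pipeline_config`.
#' @export
pipeline_config <- function(network, types, de_tables, out_dir,
                            thresholds = threshold_config(),
                            randomization =
                              randomization_config(n_samples = 200),
                            drugs = NULL, indications = NULL,
                            gene_sets = NULL,
                            reference_similarity = NULL, seed = 1) {
  if (length(de_tables) == 0 || is.null(names(de_tables)) ||
      any(names(de_tables) == "")) {
    stop("de_tables must be a named disease -> path collection",
         call. = FALSE)
  }
  paths <- c(network = network, types = types, unlist(de_tables),
             drugs = drugs, indications = indications,
             gene_sets = gene_sets, unlist(reference_similarity))
  missing <- paths[!file.exists(paths)]
  if (length(missing)) {
    stop("input path(s) do not exist: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  structure(list(network = network, types = types,
                 de_tables = as.list(de_tables), out_dir = out_dir,
                 thresholds = thresholds, randomization = randomization,
                 drugs = drugs, indications = indications,
                 gene_sets = gene_sets,
                 reference_similarity =
                   as.list(reference_similarity %||% list()),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read pipeline configuration from YAML
#'
#' Top-level keys mirror the [pipeline_config()] arguments, with
#' `thresholds` and `randomization` as nested maps of their respective
#' arguments.
#'
#' @param path YAML file.
#' @param overrides Named list overriding top-level YAML keys.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path, overrides = list()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  y <- yaml::read_yaml(path)
  y <- modifyList(y, overrides)
  thr <- do.call(threshold_config, y$thresholds %||% list())
  rnd <- do.call(randomization_config,
                 y$randomization %||% list(n_samples = 200))
  pipeline_config(
    network = y$network, types = y$types, de_tables = y$de_tables,
    out_dir = y$out_dir %||% ".", thresholds = thr, randomization = rnd,
    drugs = y$drugs, indications = y$indications,
    gene_sets = y$gene_sets,
    reference_similarity = y$reference_similarity, seed = y$seed %||% 1)
}

read_drug_records <- function(drug_path, indication_path) {
  tg <- read_tsv_quiet(drug_path)
  names(tg)[1:2] <- c("drug_id", "target_id")
  ind <- if (!is.null(indication_path)) {
    x <- read_tsv_quiet(indication_path)
    names(x)[1:2] <- c("drug_id", "disease")
    x
  } else tibble::tibble(drug_id = character(0), disease = character(0))
  tg |>
    dplyr::group_by(.data$drug_id) |>
    dplyr::summarise(targets = list(unique(.data$target_id)),
                     .groups = "drop") |>
    dplyr::mutate(indications = purrr::map(.data$drug_id, function(d) {
      unique(ind$disease[ind$drug_id == d])
    }))
}

#' Run the full module-detection workflow
#'
#' Executes the five-stage workflow — network construction, projection of
#' per-disease differential expression, topological significance, module
#' extraction, and role/application analyses — and writes per-disease
#' module TSVs, statistic reports, similarity matrices (with reference
#' correlations when provided), drug rankings, enrichment tables and a JSON
#' manifest of all parameters. Every output carries the seed and a config
#' hash in its header; reruns with the same configuration are
#' byte-identical.
#'
#' @param cfg A `pipeline_config`.
#' @return Invisibly, a list with the per-disease module results, the scan
#'   tibble, similarity matrices, drug rankings, enrichment tables and the
#'   manifest.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  # the hash identifies the analysis, not where it is written
  chash <- rlang::hash(unclass(cfg)[setdiff(names(cfg), "out_dir")])
  hdr <- c(paste0("seed=", cfg$seed), paste0("config_hash=", chash))

  net <- stage("network", read_network(cfg$network, cfg$types,
                                       quiet = TRUE))
  rnd <- cfg$randomization
  rnd$seed <- rnd$seed %||% cfg$seed

  diseases <- names(cfg$de_tables)
  results <- list()
  stats_rows <- list()
  for (d in diseases) {
    tab <- stage(paste0("de:", d), read_de_table(cfg$de_tables[[d]]))
    aff <- stage(paste0("affected:", d),
                 select_affected(tab, net, cfg$thresholds))
    neo <- stage(paste0("modules:", d), neomodule(net, aff))
    co <- attr(neo, "comodule")
    membership <- tidy(neo) |>
      dplyr::mutate(in_comodule = .data$gene_id %in% co$module_nodes) |>
      dplyr::select("gene_id", "gene_class", "in_comodule",
                    is_iso = "is_iso")
    write_tsv_commented(membership,
                        file.path(cfg$out_dir, paste0(d, "_module.tsv")),
                        hdr)
    triples <- enumerate_triples(net, neo$module_nodes)
    write_tsv_commented(triples,
                        file.path(cfg$out_dir, paste0(d, "_triples.tsv")),
                        hdr)
    rep_co <- stage(paste0("stats:", d),
                    significance(net, aff$de_mrnas, "slcc", rnd))
    rep_neo <- significance(net, union(aff$de_mrnas, aff$de_ncrnas),
                            "slcc", rnd)
    stats_rows[[d]] <- dplyr::bind_rows(
      dplyr::mutate(tidy(rep_co), disease = d, kind = "COModule"),
      dplyr::mutate(tidy(rep_neo), disease = d, kind = "NeOModule"))
    results[[d]] <- list(affected = aff, comodule = co, neomodule = neo,
                         triples = triples)
  }
  stats_tbl <- dplyr::bind_rows(stats_rows)
  write_tsv_commented(stats_tbl, file.path(cfg$out_dir, "stat_reports.tsv"),
                      hdr)

  sims <- NULL
  correlations <- NULL
  if (length(diseases) >= 2) {
    mods <- lapply(results, `[[`, "neomodule")
    sims <- list(
      neomodule = pairwise_similarity(mods, "all"),
      comodule = pairwise_similarity(lapply(results, `[[`, "comodule"),
                                     "all"),
      iso = pairwise_similarity(mods, "iso_only"))
    for (nm in names(sims)) {
      m <- sims[[nm]]
      out <- cbind(tibble::tibble(disease = m$labels),
                   tibble::as_tibble(m$values))
      write_tsv_commented(out,
                          file.path(cfg$out_dir,
                                    paste0("similarity_", nm, ".tsv")),
                          hdr)
    }
    if (length(cfg$reference_similarity)) {
      correlations <- purrr::imap_dfr(cfg$reference_similarity,
                                      function(p, rname) {
        ref <- read_similarity_matrix(p)
        purrr::imap_dfr(sims, function(sm, kind) {
          tibble::tibble(reference = rname, kind = kind,
                         pearson_r = tryCatch(
                           correlate_similarities(sm, ref),
                           error = function(e) NA_real_))
        })
      })
      write_tsv_commented(correlations,
                          file.path(cfg$out_dir,
                                    "similarity_correlations.tsv"), hdr)
    }
  }

  rankings <- NULL
  if (!is.null(cfg$drugs)) {
    drugs <- stage("drugs", read_drug_records(cfg$drugs, cfg$indications))
    rankings <- purrr::map(diseases, function(d) {
      tryCatch(rank_and_auc(net, drugs, results[[d]]$neomodule$module_nodes,
                            d),
               error = function(e) NULL)
    })
    names(rankings) <- diseases
    rk <- purrr::compact(rankings)
    if (length(rk)) {
      write_tsv_commented(
        dplyr::bind_rows(purrr::imap(rk, function(r, d) {
          dplyr::mutate(tidy(r), disease = d, auc = r$auc)
        })),
        file.path(cfg$out_dir, "drug_rankings.tsv"), hdr)
    }
  }

  enrichment <- NULL
  if (!is.null(cfg$gene_sets)) {
    coll <- stage("gene_sets", read_gmt(cfg$gene_sets))
    bg <- network_nodes(net)$id
    enrichment <- purrr::imap_dfr(results, function(r, d) {
      dplyr::mutate(ora_enrichment(r$neomodule$module_nodes, coll, bg),
                    disease = d)
    })
    write_tsv_commented(enrichment,
                        file.path(cfg$out_dir, "enrichment.tsv"), hdr)
  }

  manifest <- list(
    seed = cfg$seed, config_hash = chash,
    thresholds = unclass(cfg$thresholds),
    randomization = unclass(cfg$randomization),
    inputs = list(network = cfg$network, types = cfg$types,
                  de_tables = cfg$de_tables, drugs = cfg$drugs,
                  indications = cfg$indications,
                  gene_sets = cfg$gene_sets,
                  reference_similarity = cfg$reference_similarity),
    diseases = diseases,
    outputs = list.files(cfg$out_dir))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")

  invisible(list(network = net, results = results, stats = stats_tbl,
                 similarities = sims, correlations = correlations,
                 rankings = rankings, enrichment = enrichment,
                 manifest = manifest))
}

#' Write a simulated study bundle to disk
#'
#' Generates a synthetic network with a planted ncRNA-bridged module, the
#' matching perturbation table, a drug benchmark and the ground truth, and
#' writes them as plain TSV/JSON files ready for [run_pipeline()] or the
#' command-line interface.
#'
#' @param cfg A [synthetic_config()].
#' @param out_dir Output directory.
#' @return Invisibly, the list from [plant_bridged_module()] plus file
#'   paths.
#' @export
simulate_bundle <- function(cfg = synthetic_config(), out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  net <- generate_network(cfg)
  planted <- plant_bridged_module(net, cfg)
  net <- planted$net
  truth <- c(planted$planted_mrnas, planted$bridges)
  tab <- generate_perturbations(truth, network_nodes(net)$id, cfg,
                                fragments = planted$fragments, net = net)
  module_guess <- planted$planted_mrnas
  drugs <- generate_drug_benchmark(net, module_guess, seed = cfg$seed)
  paths <- list(
    network = file.path(out_dir, "network.tsv"),
    types = file.path(out_dir, "types.tsv"),
    de = file.path(out_dir, "de.tsv"),
    drugs = file.path(out_dir, "drugs.tsv"),
    indications = file.path(out_dir, "indications.tsv"),
    truth = file.path(out_dir, "ground_truth.json"))
  write_network(net, paths$network, paths$types)
  readr::write_tsv(tab, paths$de, progress = FALSE)
  readr::write_tsv(
    tidyr::unnest(drugs[, c("drug_id", "targets")],
                  "targets") |>
      dplyr::rename(target_id = "targets"),
    paths$drugs, progress = FALSE)
  readr::write_tsv(
    drugs |>
      dplyr::filter(lengths(.data$indications) > 0) |>
      dplyr::transmute(drug_id = .data$drug_id,
                       disease = purrr::map_chr(.data$indications, 1)),
    paths$indications, progress = FALSE)
  jsonlite::write_json(list(planted_mrnas = planted$planted_mrnas,
                            bridges = planted$bridges,
                            seed = cfg$seed),
                       paths$truth, auto_unbox = TRUE, pretty = TRUE)
  invisible(c(planted, list(paths = paths, table = tab, drugs = drugs)))
}
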