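#' Internal edge density of a gene set
#'
#' Number of edges among members of `S` divided by the number of possible
#' pairs `|S| (|S|-1) / 2`.
#'
#' @param net A `typed_network`.
#' @param S Gene ids (at least 2, all treated as a set).
#' @return Density in `[0, 1]`.
#' @export
subgraph_density <- function(net, S) {
  stopifnot(inherits(net, "typed_network"))
  S <- unique(as.character(S))
  if (length(S) < 2) stop("S must contain at least 2 genes", call. = FALSE)
  sub <- induced_network(net, S)
  n <- igraph::vcount(sub$graph)
  igraph::ecount(sub$graph) / (n * (n - 1) / 2)
}

#' Conductance of a gene set
#'
#' Cut edges between `S` and the rest of the network divided by the smaller
#' of the two degree volumes (degrees taken in the full network). Low values
#' mean the set interacts mostly internally.
#'
#' @inheritParams subgraph_density
#' @return Conductance in `[0, 1]`.
#' @export
conductance <- function(net, S) {
  stopifnot(inherits(net, "typed_network"))
  S <- unique(as.character(S))
  nm <- igraph::V(net$graph)$name
  S <- intersect(S, nm)
  if (length(S) == 0 || length(S) == igraph::vcount(net$graph)) {
    stop("S must be a nonempty proper subset of the network", call. = FALSE)
  }
  deg <- igraph::degree(net$graph)
  vol_s <- sum(deg[S])
  vol_rest <- sum(deg) - vol_s
  if (vol_s == 0) stop("S has zero degree volume", call. = FALSE)
  in_s <- nm %in% S
  names(in_s) <- nm
  ed <- igraph::as_data_frame(net$graph, what = "edges")
  cut <- sum(xor(in_s[ed$from], in_s[ed$to]))
  cut / min(vol_s, vol_rest)
}

#' Spatial network association of a gene set
#'
#' Local-aggregation score: the mean over members of the fraction of each
#' member's neighbours (in the full network) that also belong to the set.
#' 1 for an isolated clique, 0 for a set with no internal edges. This is a
#' documented stand-in aggregation statistic; supply your own function to
#' [significance()] for alternatives.
#'
#' @inheritParams subgraph_density
#' @return Score in `[0, 1]`; zero-degree members are ignored (error when
#'   every member has degree zero).
#' @export
spatial_na <- function(net, S) {
  stopifnot(inherits(net, "typed_network"))
  S <- unique(as.character(S))
  S <- intersect(S, igraph::V(net$graph)$name)
  if (length(S) == 0) stop("S is empty", call. = FALSE)
  deg <- igraph::degree(net$graph, v = S)
  members <- S[deg > 0]
  if (length(members) == 0) {
    stop("every member of S has degree zero", call. = FALSE)
  }
  adj <- igraph::adjacent_vertices(net$graph, members)
  frac <- vapply(seq_along(members), function(i) {
    nb <- igraph::V(net$graph)$name[as.integer(adj[[i]])]
    sum(nb %in% S) / length(nb)
  }, numeric(1))
  mean(frac)
}

#' Randomization configuration for counterpart gene sets
#'
#' @param n_samples Number of random counterpart sets (default 1000).
#' @param scheme `"uniform_by_class"` draws nodes uniformly within each gene
#'   class; `"degree_binned_by_class"` additionally matches the template's
#'   per-class degree-bin histogram (log-spaced bins).
#' @param seed Optional integer seed; fixed seed gives identical samples.
#' @param degree_bins Number of log-spaced degree bins (default 10).
#' @return A `randomization_config` list.
#' @export
randomization_config <- function(n_samples = 1000,
                                 scheme = c("uniform_by_class",
                                            "degree_binned_by_class"),
                                 seed = NULL, degree_bins = 10) {
  scheme <- match.arg(scheme)
  if (!is.numeric(n_samples) || n_samples < 2) {
    stop("n_samples must be >= 2", call. = FALSE)
  }
  structure(list(n_samples = as.integer(n_samples), scheme = scheme,
                 seed = seed, degree_bins = as.integer(degree_bins)),
            class = "randomization_config")
}

#' Sample random counterpart gene sets matched on class composition
#'
#' Draws `n_samples` gene sets with exactly the same per-class node counts
#' as the template set. Under `degree_binned_by_class` the per-class
#' degree-bin histogram of the template is matched as well; when a bin has
#' too few nodes the deficit is borrowed from the nearest nonempty bins with
#' a warning.
#'
#' @param net A `typed_network`.
#' @param template Gene ids present in `net`.
#' @param cfg A [randomization_config()].
#' @return List of character vectors, each a counterpart set.
#' @export
sample_counterparts <- function(net, template,
                                cfg = randomization_config()) {
  stopifnot(inherits(net, "typed_network"),
            inherits(cfg, "randomization_config"))
  template <- unique(as.character(template))
  cls <- node_classes(net)
  missing <- setdiff(template, names(cls))
  if (length(missing)) {
    stop("template id(s) not in network: ",
         paste(head(missing, 5), collapse = ", "), call. = FALSE)
  }
  tcls <- cls[template]
  classes <- unique(unname(tcls))
  pools <- lapply(classes, function(k) names(cls)[cls == k])
  names(pools) <- classes
  need <- vapply(classes, function(k) sum(tcls == k), integer(1))
  short <- classes[need > lengths(pools)[classes]]
  if (length(short)) {
    stop("network has fewer nodes than the template in class(es): ",
         paste(short, collapse = ", "), call. = FALSE)
  }

  if (cfg$scheme == "uniform_by_class") {
    draw_one <- function() {
      unlist(lapply(classes, function(k) {
        sample(pools[[k]], need[[k]])
      }), use.names = FALSE)
    }
  } else {
    deg <- igraph::degree(net$graph)
    breaks <- exp(seq(log(1), log(max(deg) + 2), length.out =
                        cfg$degree_bins + 1))
    breaks[1] <- -0.5  # degree-0 nodes land in the first bin
    bin_of <- function(ids) findInterval(deg[ids], breaks,
                                         rightmost.closed = TRUE)
    pool_bins <- lapply(classes, function(k) bin_of(pools[[k]]))
    names(pool_bins) <- classes
    tmpl_bins <- lapply(classes, function(k) bin_of(template[tcls == k]))
    names(tmpl_bins) <- classes
    draw_one <- function() {
      unlist(lapply(classes, function(k) {
        pb <- pool_bins[[k]]
        pool <- pools[[k]]
        counts <- tabulate(tmpl_bins[[k]], nbins = cfg$degree_bins)
        picked <- character(0)
        for (b in which(counts > 0)) {
          avail <- setdiff(pool[pb == b], picked)
          k_need <- counts[b]
          if (length(avail) < k_need) {
            warning("degree bin ", b, " (class ", k,
                    ") too small; borrowing from nearest bins",
                    call. = FALSE)
            # widen symmetrically until enough candidates
            w <- 1
            while (length(avail) < k_need && w <= cfg$degree_bins) {
              nb_bins <- c(b - w, b + w)
              avail <- unique(c(avail,
                                setdiff(pool[pb %in% nb_bins], picked)))
              w <- w + 1
            }
          }
          picked <- c(picked, sample(avail, min(k_need, length(avail))))
        }
        picked
      }), use.names = FALSE)
    }
  }
  with_opt_seed(cfg$seed, replicate(cfg$n_samples, draw_one(),
                                    simplify = FALSE))
}

# largest-component sizes of many induced node sets at once: one edge-list
# extraction, vectorized masking of induced edges per set, then a plain
# union-find over the few surviving edges (the randomization hot loop)
slcc_sizes <- function(net, sets) {
  g <- net$graph
  n <- igraph::vcount(g)
  if (n == 0) return(rep(0L, length(sets)))
  el <- igraph::as_edgelist(g, names = FALSE)
  e_from <- as.integer(el[, 1])
  e_to <- as.integer(el[, 2])
  name2id <- stats::setNames(seq_len(n), igraph::V(g)$name)
  vapply(sets, function(S) {
    ids <- unname(name2id[unique(S)])
    ids <- ids[!is.na(ids)]
    k <- length(ids)
    if (k == 0) return(0L)
    in_s <- logical(n)
    in_s[ids] <- TRUE
    sel <- in_s[e_from] & in_s[e_to]
    if (!any(sel)) return(1L)
    pos <- integer(n)
    pos[ids] <- seq_len(k)
    a <- pos[e_from[sel]]
    b <- pos[e_to[sel]]
    parent <- seq_len(k)
    for (e in seq_along(a)) {
      x <- a[e]
      while (parent[x] != x) {
        parent[x] <- parent[parent[x]]
        x <- parent[x]
      }
      y <- b[e]
      while (parent[y] != y) {
        parent[y] <- parent[parent[y]]
        y <- parent[y]
      }
      if (x != y) parent[x] <- y
    }
    roots <- integer(k)
    for (i in seq_len(k)) {
      x <- i
      while (parent[x] != x) x <- parent[x]
      roots[i] <- x
    }
    max(tabulate(roots, nbins = k))
  }, integer(1))
}

# built-in subgraph statistics, all of signature function(net, S)
stat_function <- function(name) {
  switch(name,
    slcc = function(net, S) {
      length(largest_component(induced_network(net, S)))
    },
    density = subgraph_density,
    conductance = conductance,
    spatialNA = spatial_na,
    spatial_na = spatial_na,
    triple_count = function(net, S) {
      S <- intersect(S, igraph::V(net$graph)$name)
      nrow(enumerate_triples(net, S))
    },
    iso_count = function(net, S) {
      cls <- node_classes(net)
      S <- intersect(unique(S), names(cls))
      mr <- S[cls[S] == "mRNA"]
      lcc_full <- largest_component(induced_network(net, S))
      lcc_m <- largest_component(induced_network(net, mr))
      length(setdiff(lcc_full[cls[lcc_full] == "mRNA"], lcc_m))
    },
    stop("unknown statistic: ", name, call. = FALSE)
  )
}

#' Significance of a subgraph statistic against randomized counterparts
#'
#' Evaluates the statistic on the observed gene set and on randomized
#' counterpart sets with matched class composition, and reports the Z-score
#' `(observed - null mean) / null sd` together with a pseudocount empirical
#' p-value `(1 + #as-or-more-extreme) / (n_samples + 1)`. The set is called
#' significant when `Z >= 1.65` in the `greater` direction (`Z <= -1.65`
#' for `less`), the one-sided 5% rule under a normal null.
#'
#' @param net A `typed_network`.
#' @param S Observed gene set (template for the null).
#' @param statistic Name of a built-in statistic (`"slcc"`, `"density"`,
#'   `"conductance"`, `"spatialNA"`, `"triple_count"`, `"iso_count"`) or a
#'   function `function(net, S)`.
#' @param cfg A [randomization_config()].
#' @param direction `"greater"` (default) or `"less"` — the one-sided
#'   alternative.
#' @return A `stat_report`; use [tidy()] for a one-row tibble. When the null
#'   is degenerate (`sd == 0`) the Z-score is `NA` and the report is flagged
#'   not significant.
#' @export
significance <- function(net, S, statistic = "slcc",
                         cfg = randomization_config(),
                         direction = c("greater", "less")) {
  direction <- match.arg(direction)
  f <- if (is.function(statistic)) statistic else stat_function(statistic)
  stat_name <- if (is.function(statistic)) "custom" else statistic
  S <- unique(as.character(S))
  samples <- sample_counterparts(net, S, cfg)
  if (identical(stat_name, "slcc")) {
    sizes <- slcc_sizes(net, c(list(S), samples))
    observed <- sizes[1]
    nulls <- as.numeric(sizes[-1])
  } else {
    observed <- f(net, S)
    nulls <- vapply(samples, function(s) f(net, s), numeric(1))
  }
  mu <- mean(nulls)
  sdev <- sd(nulls)
  degenerate <- !is.finite(sdev) || sdev == 0
  z <- if (degenerate) NA_real_ else (observed - mu) / sdev
  n_extreme <- if (direction == "greater") sum(nulls >= observed)
               else sum(nulls <= observed)
  emp_p <- (1 + n_extreme) / (length(nulls) + 1)
  signif <- !degenerate &&
    ((direction == "greater" && z >= 1.65) ||
     (direction == "less" && z <= -1.65))
  structure(list(
    statistic_name = stat_name, observed = observed, null_mean = mu,
    null_sd = sdev, zscore = z, emp_p = emp_p, significant = signif,
    direction = direction, scheme = cfg$scheme,
    n_samples = cfg$n_samples, degenerate = degenerate,
    null_values = nulls
  ), class = "stat_report")
}

#' @export
print.stat_report <- function(x, ...) {
  cat("<stat_report> ", x$statistic_name, " (", x$direction, ", ",
      x$scheme, ", n=", x$n_samples, ")\n", sep = "")
  cat(sprintf("  observed=%.4g null=%.4g +/- %.4g Z=%.3f p=%.4g %s\n",
              x$observed, x$null_mean, x$null_sd,
              ifelse(is.na(x$zscore), NaN, x$zscore), x$emp_p,
              if (x$significant) "significant" else "n.s."))
  invisible(x)
}

#' @export
tidy.stat_report <- function(x, ...) {
  tibble::tibble(
    statistic = x$statistic_name, observed = x$observed,
    null_mean = x$null_mean, null_sd = x$null_sd, zscore = x$zscore,
    emp_p = x$emp_p, significant = x$significant,
    direction = x$direction, scheme = x$scheme, n_samples = x$n_samples,
    degenerate = x$degenerate)
}

#' Threshold scan of module connectivity significance
#'
#' For each coding threshold beta, selects the affected sets, builds the
#' COModule and NeOModule, and reports the observed sLCC with its Z-score
#' and empirical p against class-matched random counterparts; for the
#' NeOModule also the Iso_mRNA count/ratio and the ceRNA triple count (with
#' significance when `triple_stats = TRUE`).
#'
#' @param net A `typed_network`.
#' @param table Differential-expression table (see [select_affected()]).
#' @param betas Strictly increasing coding thresholds.
#' @param cfg A [threshold_config()] supplying the ncRNA gammas.
#' @param rand A [randomization_config()].
#' @param triple_stats Also randomize the triple count (slower).
#' @return A `beta_scan` tibble: one row per beta and module kind with
#'   columns `beta`, `kind`, `n_input`, `slcc`, `zscore`, `emp_p`,
#'   `significant`, `n_iso`, `iso_ratio`, `triple_count`, `triple_zscore`,
#'   `degenerate`.
#' @export
scan_beta <- function(net, table, betas, cfg = threshold_config(),
                      rand = randomization_config(n_samples = 200),
                      triple_stats = FALSE) {
  grid <- threshold_grid(table, net, betas, cfg)
  rows <- purrr::imap(grid, function(aff, bchr) {
    b <- as.numeric(bchr)
    s_co <- aff$de_mrnas
    s_neo <- union(aff$de_mrnas, aff$de_ncrnas)
    neo <- neomodule(net, aff)
    co <- attr(neo, "comodule")
    one <- function(kind, S, mod) {
      if (length(S) == 0) {
        return(tibble::tibble(
          beta = b, kind = kind, n_input = 0L, slcc = 0L,
          zscore = NA_real_, emp_p = NA_real_, significant = FALSE,
          n_iso = 0L, iso_ratio = NA_real_,
          triple_count = NA_integer_, triple_zscore = NA_real_,
          degenerate = TRUE))
      }
      rep <- significance(net, S, "slcc", rand, "greater")
      tc <- if (kind == "NeOModule") {
        nrow(enumerate_triples(net, mod$module_nodes))
      } else NA_integer_
      tz <- NA_real_
      if (kind == "NeOModule" && triple_stats) {
        tz <- significance(net, S, "triple_count", rand, "greater")$zscore
      }
      tibble::tibble(
        beta = b, kind = kind, n_input = length(S), slcc = mod$slcc,
        zscore = rep$zscore, emp_p = rep$emp_p,
        significant = rep$significant,
        n_iso = length(mod$iso_mrnas),
        iso_ratio = if (kind == "NeOModule") iso_ratio(mod) else NA_real_,
        triple_count = tc, triple_zscore = tz,
        degenerate = rep$degenerate)
    }
    dplyr::bind_rows(one("COModule", s_co, co),
                     one("NeOModule", s_neo, neo))
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("beta_scan", class(out))
  out
}

#' Mann–Whitney rank-sum test
#'
#' Exact test by enumeration of all `C(n+m, n)` group assignments (average
#' ranks, so ties are handled) when `min(n, m) <= 8`; otherwise the normal
#' approximation with tie correction.
#'
#' @param x,y Nonempty numeric vectors.
#' @param alternative `"two.sided"`, `"less"` or `"greater"` (of `x`
#'   relative to `y`).
#' @return The p-value.
#' @export
rank_sum_test <- function(x, y, alternative = c("two.sided", "less",
                                                "greater")) {
  alternative <- match.arg(alternative)
  if (length(x) == 0 || length(y) == 0) {
    stop("both samples must be nonempty", call. = FALSE)
  }
  n <- length(x); m <- length(y); N <- n + m
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  if (min(n, m) <= 8) {
    # exact: U over every choice of which ranks belong to x
    idx <- utils::combn(N, n)
    us <- colSums(matrix(r[idx], nrow = n)) - n * (n + 1) / 2
    eps <- 1e-9
    p_le <- mean(us <= u_obs + eps)
    p_ge <- mean(us >= u_obs - eps)
    p <- switch(alternative,
                less = p_le, greater = p_ge,
                two.sided = min(1, 2 * min(p_le, p_ge)))
  } else {
    mu <- n * m / 2
    tie <- table(r)
    sig2 <- n * m / 12 * ((N + 1) - sum(tie^3 - tie) / (N * (N - 1)))
    if (sig2 <= 0) return(1)
    z <- (u_obs - mu) / sqrt(sig2)
    p <- switch(alternative,
                less = pnorm(z), greater = pnorm(z, lower.tail = FALSE),
                two.sided = 2 * pnorm(-abs(z)))
  }
  min(1, p)
}
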