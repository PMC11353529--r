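path4 <- tn(c("a-b", "b-c", "c-d"),
            c(a = "mRNA", b = "mRNA", c = "mRNA", d = "mRNA"))

test_that("density, conductance and spatialNA reproduce closed-form toy values", {
  tri <- tn(c("a-b", "a-c", "b-c"),
            c(a = "mRNA", b = "mRNA", c = "mRNA"))
  expect_equal(subgraph_density(tri, c("a", "b", "c")), 1)
  expect_error(subgraph_density(tri, "a"), "at least 2")

  iso3 <- tn(c("a-b"), c(a = "mRNA", b = "mRNA", c = "mRNA",
                         d = "mRNA", e = "mRNA"))
  expect_equal(subgraph_density(iso3, c("c", "d", "e")), 0)
  expect_equal(subgraph_density(path4, c("a", "b", "c", "d")), 0.5)

  edge1 <- tn(c("a-b"), c(a = "mRNA", b = "mRNA"))
  expect_equal(conductance(edge1, "a"), 1)
  two_tri <- tn(c("a-b", "a-c", "b-c", "d-e", "d-f", "e-f"),
                c(a = "mRNA", b = "mRNA", c = "mRNA",
                  d = "mRNA", e = "mRNA", f = "mRNA"))
  expect_equal(conductance(two_tri, c("a", "b", "c")), 0)
  expect_equal(conductance(path4, c("a", "b")), 1 / 3)
  expect_error(conductance(path4, character(0)), "nonempty")
  expect_error(conductance(path4, c("a", "b", "c", "d")), "proper subset")

  # isolated clique scores 1; edgeless set 0; star centre + leaf 0.625
  expect_equal(spatial_na(two_tri, c("a", "b", "c")), 1)
  expect_equal(spatial_na(path4, c("a", "d")), 0)
  star <- tn(c("h-l1", "h-l2", "h-l3", "h-l4"),
             c(h = "mRNA", l1 = "mRNA", l2 = "mRNA", l3 = "mRNA",
               l4 = "mRNA"))
  expect_equal(spatial_na(star, c("h", "l1")), (1 / 4 + 1) / 2)
  lonely <- tn(c("a-b"), c(a = "mRNA", b = "mRNA", z = "mRNA"))
  expect_error(spatial_na(lonely, "z"), "degree zero")
})

test_that("topological statistics always lie in [0, 1]", {
  for (s in 1:20) {
    net <- random_typed_net(n = 30, p = 0.1, seed = 700 + s)
    ids <- network_nodes(net)$id
    S <- withr::with_seed(s, sample(ids, 10))
    d <- subgraph_density(net, S)
    expect_gte(d, 0); expect_lte(d, 1)
    cnd <- tryCatch(conductance(net, S), error = function(e) NA)
    if (!is.na(cnd)) { expect_gte(cnd, 0); expect_lte(cnd, 1) }
    sna <- tryCatch(spatial_na(net, S), error = function(e) NA)
    if (!is.na(sna)) { expect_gte(sna, 0); expect_lte(sna, 1) }
  }
})

test_that("counterpart sampling preserves class counts, is seed-deterministic, and is uniform within class", {
  net <- random_typed_net(n = 60, p = 0.08, seed = 77)
  nd <- network_nodes(net)
  template <- withr::with_seed(1, sample(nd$id, 20))
  tmpl_counts <- table(nd$gene_class[nd$id %in% template])
  for (scheme in c("uniform_by_class", "degree_binned_by_class")) {
    cfg <- randomization_config(n_samples = 30, scheme = scheme, seed = 5)
    draws <- suppressWarnings(sample_counterparts(net, template, cfg))
    expect_length(draws, 30)
    for (s in draws) {
      expect_equal(table(nd$gene_class[nd$id %in% s])[names(tmpl_counts)],
                   tmpl_counts)
    }
    again <- suppressWarnings(sample_counterparts(net, template, cfg))
    expect_identical(draws, again)
  }

  # forced draw: template = every mRNA
  all_m <- nd$id[nd$gene_class == "mRNA"]
  forced <- sample_counterparts(net, all_m,
                                randomization_config(n_samples = 3,
                                                     seed = 2))
  for (s in forced) expect_setequal(s, all_m)

  # uniform inclusion frequency ~ Binomial(n_samples, k/n_class)
  big <- typed_network(
    tibble::tibble(source = sprintf("g%03d", 1:499),
                   target = sprintf("g%03d", 2:500)),
    tibble::tibble(id = sprintf("g%03d", 1:500), gene_class = "mRNA"))
  tmpl <- sprintf("g%03d", 1:50)
  cfg <- randomization_config(n_samples = 1000, seed = 11)
  draws <- sample_counterparts(big, tmpl, cfg)
  freq <- table(factor(unlist(draws), levels = sprintf("g%03d", 1:500)))
  p <- 50 / 500
  sdb <- sqrt(1000 * p * (1 - p)) / 1000
  expect_true(all(abs(freq / 1000 - p) <= 4 * sdb))
  expect_error(
    sample_counterparts(net, template,
                        randomization_config(n_samples = 1)),
    "n_samples")
})

test_that("Z-score reports behave at the edges and flag degenerate nulls", {
  net <- random_typed_net(n = 40, p = 0.1, seed = 88)
  nd <- network_nodes(net)
  all_m <- nd$id[nd$gene_class == "mRNA"]
  # forced null (template = all mRNAs) -> sd 0, flagged, not significant
  rep0 <- significance(net, all_m, "slcc",
                       randomization_config(n_samples = 20, seed = 1))
  expect_true(rep0$degenerate)
  expect_false(rep0$significant)
  expect_true(is.na(rep0$zscore))
  expect_equal(rep0$observed, rep0$null_mean)

  S <- withr::with_seed(2, sample(nd$id, 12))
  rep1 <- significance(net, S, "slcc",
                       randomization_config(n_samples = 50, seed = 3))
  expect_equal(rep1$zscore,
               (rep1$observed - rep1$null_mean) / rep1$null_sd)
  expect_gte(rep1$emp_p, 1 / 51)
  expect_lte(rep1$emp_p, 1)
  td <- tidy(rep1)
  expect_equal(td$observed, rep1$observed)
  # custom statistic plugin
  repc <- significance(net, S, function(net, S) length(S),
                       randomization_config(n_samples = 10, seed = 4))
  expect_true(repc$degenerate)
})

test_that("rank-sum test matches enumeration oracle and wilcox.test", {
  expect_equal(rank_sum_test(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(rank_sum_test(c(1, 2, 3), c(10, 11, 12), "less"), 0.05)
  expect_error(rank_sum_test(numeric(0), 1), "nonempty")

  withr::with_seed(21, {
    for (i in 1:20) {
      x <- round(stats::rnorm(6), 1)  # rounding induces occasional ties
      y <- round(stats::rnorm(6, mean = 0.5), 1)
      for (alt in c("two.sided", "less", "greater")) {
        expect_equal(rank_sum_test(x, y, alt),
                     oracle_ranksum_p(x, y, alt), tolerance = 1e-12)
      }
    }
    # large-sample path against the normal-approximation reference
    x <- stats::rnorm(30); y <- stats::rnorm(25, mean = 0.3)
    ref <- stats::wilcox.test(x, y, exact = FALSE,
                              correct = FALSE)$p.value
    expect_equal(rank_sum_test(x, y), ref, tolerance = 1e-9)
  })
})

test_that("threshold scan reports both module kinds and flags empty inputs", {
  cfg <- synthetic_config(n_mrna = 300, n_lnc = 40, n_mi = 40,
                          n_pseudo = 20, fragment_size = 8,
                          n_bridges = 3, seed = 31)
  pl <- plant_bridged_module(generate_network(cfg), cfg)
  tab <- generate_perturbations(c(pl$planted_mrnas, pl$bridges),
                                network_nodes(pl$net)$id, cfg,
                                fragments = pl$fragments, net = pl$net)
  scan <- scan_beta(pl$net, tab, c(2),
                    rand = randomization_config(n_samples = 30, seed = 7))
  expect_s3_class(scan, "beta_scan")
  expect_equal(nrow(scan), 2)
  at2 <- scan[scan$beta == 2, ]
  neo_z <- at2$zscore[at2$kind == "NeOModule"]
  co_z <- at2$zscore[at2$kind == "COModule"]
  expect_gt(neo_z, co_z)  # planted bridges drive NeOModule connectivity
  expect_gte(at2$slcc[at2$kind == "NeOModule"],
             at2$slcc[at2$kind == "COModule"])
  hi <- scan_beta(pl$net, tab, c(99),
                  cfg = threshold_config(gamma_lnc = 99, gamma_mi = 99,
                                         gamma_pseudo = 99),
                  rand = randomization_config(n_samples = 30, seed = 7))
  expect_true(all(hi$degenerate))
  expect_true(all(hi$slcc == 0))
  p <- autoplot(scan)
  expect_s3_class(p, "ggplot")
})
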