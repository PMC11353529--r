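mk_aff <- function(net, mrnas = character(0), ncrnas = character(0),
                   beta = 1) {
  structure(list(de_mrnas = sort(mrnas), de_ncrnas = sort(ncrnas),
                 by_class = tibble::tibble(),
                 cfg = threshold_config(beta = beta)),
            class = "affected_sets")
}

test_that("largest component matches flood-fill oracle and breaks ties lexicographically", {
  empty <- typed_network(
    tibble::tibble(source = character(0), target = character(0)),
    tibble::tibble(id = character(0), gene_class = character(0)))
  expect_equal(largest_component(empty), character(0))

  # two components of equal size: {a,b} vs {c,d} -> the lexicographically
  # smallest sorted tuple wins
  tie <- tn(c("c-d", "a-b"),
            c(a = "mRNA", b = "mRNA", c = "mRNA", d = "mRNA"))
  expect_equal(largest_component(tie), c("a", "b"))

  for (s in 1:20) {
    net <- random_typed_net(n = 30, p = 0.06, seed = 300 + s)
    comps <- oracle_components(network_nodes(net)$id, network_edges(net))
    sizes <- lengths(comps)
    best <- comps[sizes == max(sizes)]
    best <- best[order(vapply(best, paste, "", collapse = "\r"))][[1]]
    expect_equal(largest_component(net), best)
  }
})

test_that("COModule is the coding LCC; isolated affected genes give singletons", {
  net <- tn(c("a-b", "b-c", "d-e"),
            c(a = "mRNA", b = "mRNA", c = "mRNA", d = "mRNA", e = "mRNA"))
  co <- comodule(net, mk_aff(net, mrnas = c("a", "b", "c", "d", "e")))
  expect_equal(co$module_nodes, c("a", "b", "c"))
  expect_equal(co$slcc, 3)
  expect_equal(co$n_components, 2)
  expect_length(co$iso_mrnas, 0)

  # no internal edges -> deterministic singleton
  iso <- comodule(net, mk_aff(net, mrnas = c("a", "d")))
  expect_equal(iso$module_nodes, "a")
  expect_equal(iso$slcc, 1)

  # planted connected clique recovered exactly
  k4 <- tn(c("p-q", "p-r", "p-s", "q-r", "q-s", "r-s"),
           c(p = "mRNA", q = "mRNA", r = "mRNA", s = "mRNA"))
  expect_setequal(
    comodule(k4, mk_aff(k4, mrnas = c("p", "q", "r", "s")))$module_nodes,
    c("p", "q", "r", "s"))
})

test_that("NeOModule extends the COModule through ncRNA bridges", {
  # m1 and m2 share no edge; lncRNA n1 bridges them
  net <- tn(c("m1-n1", "n1-m2"),
            c(m1 = "mRNA", m2 = "mRNA", n1 = "lncRNA"))
  aff <- mk_aff(net, mrnas = c("m1", "m2"), ncrnas = "n1")
  neo <- neomodule(net, aff)
  expect_setequal(neo$module_nodes, c("m1", "m2", "n1"))
  expect_equal(neo$slcc, 3)
  co <- attr(neo, "comodule")
  expect_equal(co$module_nodes, "m1")  # lexicographic tie-break
  expect_equal(neo$iso_mrnas, "m2")

  # without affected ncRNAs the NeOModule equals the COModule
  neo0 <- neomodule(net, mk_aff(net, mrnas = c("m1", "m2")))
  expect_equal(neo0$module_nodes, attr(neo0, "comodule")$module_nodes)
  expect_length(neo0$iso_mrnas, 0)

  # ncRNAs hanging off non-affected genes grow the nc side only
  net6 <- tn(c("m1-m2", "n1-n2", "n2-m3"),
             c(m1 = "mRNA", m2 = "mRNA", m3 = "mRNA",
               n1 = "lncRNA", n2 = "lncRNA"))
  aff6 <- mk_aff(net6, mrnas = c("m1", "m2"), ncrnas = c("n1", "n2"))
  neo6 <- neomodule(net6, aff6)
  expect_setequal(neo6$module_nodes, c("m1", "m2"))
  expect_length(neo6$iso_mrnas, 0)
  # nc-nc growth can dominate when the nc chain is longer
  aff6b <- mk_aff(net6, mrnas = "m3", ncrnas = c("n1", "n2"))
  neo6b <- neomodule(net6, aff6b)
  expect_setequal(neo6b$module_nodes, c("m3", "n1", "n2"))
  expect_equal(neo6b$iso_mrnas, character(0))  # m3 is its own COModule
})

test_that("NeOModule sLCC dominates COModule sLCC on random inputs", {
  for (s in 1:15) {
    net <- random_typed_net(n = 40, p = 0.08, seed = 400 + s)
    nd <- network_nodes(net)
    mr <- nd$id[nd$gene_class == "mRNA"]
    nc <- nd$id[nd$gene_class != "mRNA"]
    aff <- withr::with_seed(s, mk_aff(
      net, mrnas = sample(mr, min(12, length(mr))),
      ncrnas = if (length(nc)) sample(nc, min(6, length(nc)))
               else character(0)))
    neo <- neomodule(net, aff)
    co <- attr(neo, "comodule")
    expect_gte(neo$slcc, co$slcc)
    expect_length(intersect(neo$iso_mrnas, co$module_nodes), 0)
  }
})

test_that("removing ncRNA bridges disconnects every Iso_mRNA from the coding core", {
  for (s in 1:10) {
    net <- random_typed_net(n = 40, p = 0.08, seed = 500 + s)
    nd <- network_nodes(net)
    mr <- nd$id[nd$gene_class == "mRNA"]
    nc <- nd$id[nd$gene_class != "mRNA"]
    if (length(nc) < 3) next
    aff <- withr::with_seed(s, mk_aff(
      net, mrnas = sample(mr, min(12, length(mr))),
      ncrnas = sample(nc, min(8, length(nc)))))
    neo <- neomodule(net, aff)
    co <- attr(neo, "comodule")
    if (!length(neo$iso_mrnas)) next
    # induced subgraph of module coding genes only
    coding_only <- induced_network(
      net, neo$module_nodes[neo$node_classes == "mRNA"])
    comps <- oracle_components(network_nodes(coding_only)$id,
                               network_edges(coding_only))
    for (g in neo$iso_mrnas) {
      comp_g <- comps[[which(vapply(comps, function(cc) g %in% cc,
                                    TRUE))]]
      expect_length(intersect(comp_g, co$module_nodes), 0)
    }
  }
})

test_that("iso_ratio uses module coding genes as denominator", {
  net <- tn(c("m1-n1", "n1-m2"),
            c(m1 = "mRNA", m2 = "mRNA", n1 = "lncRNA"))
  neo <- neomodule(net, mk_aff(net, c("m1", "m2"), "n1"))
  expect_equal(iso_ratio(neo), 0.5)  # {m2} of {m1, m2}
  expect_equal(iso_ratio(neo, "module"), 1 / 3)
  co <- attr(neo, "comodule")
  expect_equal(iso_ratio(co), 0)

  # 4 module mRNAs, 1 iso -> 0.25
  net4 <- tn(c("a-b", "b-c", "c-n", "n-d"),
             c(a = "mRNA", b = "mRNA", c = "mRNA", d = "mRNA",
               n = "lncRNA"))
  neo4 <- neomodule(net4, mk_aff(net4, c("a", "b", "c", "d"), "n"))
  expect_equal(iso_ratio(neo4), 0.25)
})

test_that("ceRNA triples are the nc-miRNA-mRNA paths of the module subgraph", {
  base <- tn(c("l-x", "x-g"),
             c(l = "lncRNA", x = "miRNA", g = "mRNA"))
  tr <- enumerate_triples(base, c("l", "x", "g"))
  expect_equal(nrow(tr), 1)
  expect_equal(tr$ncrna, "l")

  # H19-like hub: 1 lncRNA, 5 miRNAs, 2 mRNAs, 6 triples
  cls <- c(h = "lncRNA",
           setNames(rep("miRNA", 5), paste0("mi", 1:5)),
           g1 = "mRNA", g2 = "mRNA")
  hub <- tn(c("h-mi1", "h-mi2", "h-mi3", "h-mi4", "h-mi5",
              "mi1-g1", "mi1-g2", "mi2-g1", "mi3-g1", "mi4-g2",
              "mi5-g2"),
            cls)
  tr6 <- enumerate_triples(hub, names(cls))
  expect_equal(nrow(tr6), 6)
  expect_equal(length(unique(tr6$ncrna)), 1)
  expect_equal(length(unique(tr6$mirna)), 5)
  expect_equal(length(unique(tr6$mrna)), 2)

  # miRNA excluded from the ncRNA slot unless widened
  mm <- tn(c("a-x", "x-g"), c(a = "miRNA", x = "miRNA", g = "mRNA"))
  expect_equal(nrow(enumerate_triples(mm, c("a", "x", "g"))), 0)
  expect_equal(nrow(enumerate_triples(
    mm, c("a", "x", "g"),
    ncrna_classes = c("lncRNA", "pseudogene", "miRNA"))), 1)

  expect_error(enumerate_triples(base, c("l", "zz")), "not in network")
})

test_that("triple enumeration agrees with the brute-force oracle", {
  for (s in 1:20) {
    net <- random_typed_net(n = 20, p = 0.2, seed = 600 + s,
                            class_prob = c(0.4, 0.2, 0.25, 0.15))
    mod <- withr::with_seed(s, sample(network_nodes(net)$id, 14))
    got <- enumerate_triples(net, mod)
    exp <- oracle_triples(net, mod)
    expect_equal(as.data.frame(got), as.data.frame(exp),
                 ignore_attr = TRUE)
  }
})
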