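# neomodule

Connectivity-based detection of omnigenic disease modules on a
heterogeneous gene interaction network, with explicit treatment of the
non-coding RNAs that hold those modules together.

## The problem

When the genes perturbed in a disease state (by differential expression
between disease and normal samples) are projected onto an interaction
network, the classical assumption is that they form a densely connected
neighbourhood. For cancer-affected coding genes this is frequently not
what happens: the induced subgraph is fragmented. Non-coding RNAs —
lncRNAs, miRNAs, pseudogenes — act as bridges between those coding
fragments, so a module definition that ignores them misses both genes and
structure.

`neomodule` implements that analysis end to end for anyone working with a
typed interaction network (nodes labelled `mRNA`, `lncRNA`, `miRNA`,
`pseudogene`) and per-condition differential-expression tables:

* **Affected sets** — with perturbation degree `f_g = |log2FC|`, the
  coding set `DE_mRNAs(β) = {g ∈ mRNAs : f_g ≥ β}` and per-class
  non-coding sets `DE_ncRNAs = {g : f_g ≥ γ_class}`.
* **Modules** — `COModule(β)`, the largest connected component (LCC) of
  the subgraph induced by `DE_mRNAs(β)`, and `NeOModule(β)`, the LCC
  induced by `DE_mRNAs(β) ∪ DE_ncRNAs`. The *Iso_mRNAs* are the coding
  genes of the NeOModule outside the COModule — coding genes bridged in by
  ncRNAs. `sLCC` is the LCC's node count.
* **Significance** — any subgraph statistic (sLCC, density, conductance,
  a spatial aggregation score, ceRNA triple counts) is compared against
  randomized counterpart gene sets matched on class composition (and
  optionally degree bins): `Z = (observed − null mean)/null sd`, one-sided
  significance at `Z ≥ 1.65`, plus a pseudocount empirical p-value.
* **ceRNA triples** — ncRNA–miRNA–mRNA paths inside a module, the
  configuration under which an lncRNA/pseudogene and an mRNA compete for a
  shared miRNA.
* **Applications** — Jaccard disease–disease similarity from module gene
  sets (with correlation against reference similarity matrices),
  drug–module proximity ranking (mean closest shortest path from the
  drug's targets to the module) with ROC/AUC against known indications,
  and hypergeometric over-representation analysis with BH correction.
* **Synthetic studies** — a generator for scale-free heterogeneous
  networks (~87% coding–coding / ~11% non-coding–non-coding / ~1% mixed
  edges) with planted ncRNA-bridged coding fragments, matched perturbation
  tables and drug benchmarks, so the whole pipeline is testable offline.

Everything is tidyverse-shaped: data frames in, tibbles out, `tidy()` /
`glance()` methods on fitted objects, `autoplot()` for scans, similarity
matrices and ROC curves.

## Worked example

A synthetic study: generate a network, plant a fragmented coding module
joined by ncRNA bridges, generate perturbations, and detect.

```r
library(neomodule)

cfg <- synthetic_config(seed = 1)          # 2,000 nodes, 3×15 planted mRNAs
pl  <- plant_bridged_module(generate_network(cfg), cfg)
net <- pl$net
tab <- generate_perturbations(c(pl$planted_mrnas, pl$bridges),
                              network_nodes(net)$id, cfg,
                              fragments = pl$fragments, net = net)

aff <- select_affected(tab, net, threshold_config(beta = 2))
neo <- neomodule(net, aff)
print(attr(neo, "comodule"))
print(neo)
```

```
<affected_sets> beta=2: 46 DE_mRNAs, 20 DE_ncRNAs
<module_result> COModule(beta=2): sLCC=16, components=3, Iso_mRNAs=0
<module_result> NeOModule(beta=2): sLCC=51, components=16, Iso_mRNAs=30
```

The coding-only module sees a single 16-gene fragment (one planted
fragment plus an attached background gene); adding the affected ncRNAs
pulls all 45 planted coding genes into one 51-node component, 30 of them
Iso_mRNAs — exactly the bridge phenomenon the method is built to detect.
Planted recall here is 100%. Connectivity significance against 1,000
class-matched random counterparts:

```r
significance(net, union(aff$de_mrnas, aff$de_ncrnas), "slcc",
             randomization_config(n_samples = 1000, seed = 2))
```

```
<stat_report> slcc (greater, uniform_by_class, n=1000)
  observed=51 null=5.396 +/- 3.237 Z=14.090 p=0.000999 significant
```

An observed sLCC of 51 against a null mean of 5.4 — the planted module is
overwhelmingly more connected than random class-matched gene sets.

For real data, `read_network()`, `read_de_table()` and `run_pipeline()`
(or the `inst/cli/neomodule.R` script with subcommands `build-network`,
`detect`, `stats`, `scan`, `similarity`, `drugs`, `enrich`, `simulate`,
`run`) execute the same workflow from TSV/GMT/YAML inputs and write
per-disease module tables, statistic reports, similarity matrices, drug
rankings and a JSON manifest.

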