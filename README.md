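# netfx

Network-effect scoring of differentially expressed genes over a weighted
gene association network, with the full downstream pipeline around it:
cuffdiff-style differential-expression filtering, mouse-to-human ortholog
mapping, influenced-subnetwork extraction, simulated-annealing cluster
decomposition, pathway scoring and ranking, and small in-silico sequence
utilities (primer amplicon prediction, response-element motif scanning).

## The problem

An RNA-Seq contrast (for example, glucocorticoid-receptor conditional
knockout versus control in bone marrow mesenchymal stem cells) yields a
handful of strongly differentially expressed (DE) genes. Those genes do not
act alone: through functional linkages they perturb a much wider
neighbourhood. Given a weighted human gene association network whose edge
weights `W_ij ∈ [0, 1]` express the confidence that genes *i* and *j* work
in a common process, every network gene is scored by the one-step weighted
sum of DE node weights over its linkages:

    S_i = Σ_j w_j(v) · W_ij(e)

where `w_j(v) = |log2 ratio|` if gene *j* is differentially expressed and 0
otherwise, `W_ij(e)` is the edge weight (0 for non-adjacent pairs), and the
self-linkage `W_ii` is fixed at 1, so a DE gene always scores at least its
own weight. Genes above a score cut are "significantly influenced"; the
subnetwork they induce (keeping only links above an edge-weight cut) is
decomposed into dense clusters by simulated annealing on weighted
modularity, and pathways are ranked by the mean `S_i` of their member genes
among those significantly enriched (one-sided hypergeometric,
Benjamini-Hochberg) with the top-scored genes.

The package is tidyverse-native: every stage takes a data frame and returns
a tibble, so stages chain with the pipe; clustering results carry
`tidy()` / `glance()` / `autoplot()` methods.

## Worked example

All inputs can be generated with known ground truth, at the study's
conditions (15 genes up 3- to 10-fold, 70 down 2.7- to 10-fold, 739 genes
at p < 0.05, 85 mouse DE genes collapsing to 75 distinct human genes):

```r
library(netfx)

cfg <- synth_config(seed = 1)
gen <- generate_synthetic_data("synth/", cfg)

res <- run_influence_pipeline(
  gen$paths$diff, gen$paths$network,
  ortholog_file = gen$paths$orthologs,
  gmt_file      = gen$paths$gmt,
  fold_threshold = 2.7,       # the generator's minimum planted fold
  score_quantile = 0.75,      # scale-appropriate influenced-gene cut
  seed = 1
)

nrow(res$de_genes)   # 85 DE genes pass the fold and q cuts
nrow(res$human_de)   # 75 distinct human genes after ortholog collapse

res$subnetwork
#> Influenced subnetwork: 100 nodes, 1478 links (edge weight > 0.2)
#>   DE nodes: 75

glance(res$clustering)
#> # A tibble: 1 × 5
#>   n_nodes     k modularity  n_de  seed
#> 1     100     6      0.127    75     1

head(res$ranked_pathways[, c("rank", "pathway", "mean_score",
                             "mapped_genes", "enrichment_q")], 1)
#>    rank pathway mean_score mapped_genes enrichment_q
#> 1     1 PW_M1         49.7           80     3.04e-64
```

The DE genes were planted inside network module 1, and the pipeline finds
exactly that: the influenced subnetwork is the DE module, and the pathway
built on that module (`PW_M1`) ranks first with essentially zero
enrichment q. On a real analysis the same call takes the cuffdiff
`gene_exp.diff` file, the association-network edge list, an ortholog table
and a GMT file, with `score_threshold = 150` (the full-scale
linkage-network calibration) in place of `score_quantile`.

The sequence utilities work the same way on real or generated FASTA:

```r
prom <- read_fasta(gen$paths$fasta)
cas  <- gen$truth$promoter$cassettes[[1]]
in_silico_pcr(prom, cas$forward, cas$reverse)
#>   seq_id   start   end length orientation
#> 1 promoter  1002  1135    134 +

scan_motif(prom, "GGTACANNNTGTTCT", threshold = 1)   # 4 planted GREs
```

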