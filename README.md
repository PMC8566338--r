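# cfmm

Ranks the proteins of a protein–protein interaction (PPI) network by
predicted **essentiality** — the positive class being proteins whose loss is
lethal to the organism. The package implements CFMM, a ranking method for
systems biologists working with yeast-scale interaction data who want to
prioritize knockout candidates by combining network topology with protein
annotations.

## The method

Four stages, each exposed as package functions and run end to end by
`run_cfmm()`:

1. **Collaborative-filtering densification** of the sparse protein–domain
   bipartite network. Proteins are scored as similar when they share Pfam
   domains, `SM(i,j) = |N(i) ∩ N(j)| / √(|N(i)||N(j)|)`; the recommendation
   matrix `RM = SM × AM` proposes new protein–domain edges wherever an entry
   strictly exceeds its column mean. The same pass runs from the domain
   side, and the two are merged (logical OR) into a mutual recommendation
   matrix that only ever *adds* edges.
2. **Gaussian interaction-profile kernel** edge weights:
   `WBP(i,j) = exp(−δ_p ‖IP(i) − IP(j)‖²)` over the densified domain
   profiles, with bandwidth normalized by the mean squared profile norm,
   then rescaled by `(1 + max WBP)/2` and masked to the PPI edge set.
3. **Feature fusion.** Subcellular-localization, orthology and
   neighbor-co-expression scores are fused with entropy weights (features
   with lower Shannon entropy across proteins — more discriminating — get
   more weight) and blended with a triangle topology score:
   `proscore = λ·proBio + (1−λ)·ProTri`, normalized to a probability
   vector.
4. **Damped propagation** (modified PageRank): over the distribution-rate
   matrix `DRPM(k,r) ∝ WP(k,r)·proscore(r)`, iterate
   `s ← α·s·DRPM + (1−α)·s₀` to convergence and rank by the fixed point.
   Defaults: α = 0.9, λ = 0.65, ε = 1e−6.

Evaluation utilities (top-k% precision with ceiling cutoffs, jackknife
cumulative curves, ROC/PR with Mann–Whitney AUC, top-k overlap differences
between two methods) and a seeded synthetic-data generator with planted
essential labels round out the package.

## Worked example

```r
library(cfmm)

## desk example: 5 proteins, 4 domains, traceable by hand
toy <- toy_pdi()
cf  <- run_cf(toy$pdi)
cf$rm_pd["p3", "d1"]    # 0.7071068  > column standard 0.4414214
cf$rm_pd["p2", "d2"]    # 0.5
cf$added                # 6 edges added by the two merged passes

## full pipeline on a seeded synthetic dataset with planted essentials
sim <- simulate_data(n = 300, m_domains = 150, essential_frac = 0.2, seed = 7)
res <- run_cfmm(sim$ppi, sim$pdi, sim$annotations,
                essential = sim$essential, verbose = TRUE)
#> collaborative filtering: 3579 edges added (624 -> 4203)
#> entropy weights: ProSub=0.140, ProOrt=0.141, ProExp=0.719
#> propagation: 25 iterations, residual 4.66e-07, converged: TRUE

head(res$ranking, 3)
#>   rank protein      score
#> 1    1   P0003 0.11166094
#> 2    2   P0006 0.08529446
#> 3    3   P0010 0.07562370

res$evaluation$topk
#>   percent cutoff hits precision
#> 1       1      3    3 100.00000
#> 2       5     15   10  66.66667
#> 3      10     30   20  66.66667
#> 4      15     45   27  60.00000
#> 5      20     60   30  50.00000
#> 6      25     75   31  41.33333
res$evaluation$roc_pr$auc
#> [1] 0.8011111
```

The top-1% precision of 100% and AUC of 0.80 say that, at the planted
effect sizes (degree boost, compartment enrichment, ortholog and
co-expression contrasts on the essential class), the propagation
concentrates the essentials at the head of the ranking; with
`effects = null_effects()` the AUC sits at chance.

A thin command-line wrapper with `simulate`, `cf`, `rank`, `evaluate` and
`sweep` subcommands is installed under `inst/cli/cfmm.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/cfmm.R", package="cfmm"))')" \
  rank --ppi ppi.tsv --pdi pdi.tsv --subcell subcell.tsv \
       --ortho ortho.tsv --expr expr.tsv -o ranking.tsv
```

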