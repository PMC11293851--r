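# benthicnet

Quantifying **co-occurrence social diversity** in sessile benthic
communities: how much of a community's spatial arrangement is shaped by
which species sit next to which, beyond what abundance alone explains.

Line-transect surveys record a species identity at every centimetre along
a 5 m tape. `benthicnet` collapses each transect into maximal same-species
runs, turns shared run boundaries into an undirected species co-occurrence
network (edge multiplicities = number of abutments; vertex covariates
`size` = total cm, `count` = number of runs), and fits exponential random
graph models

Pr(Y = y) = exp[ Σ_A β_A g_A(y) ] / k(θ)

with the statistics `edges`, fixed-decay geometrically weighted edgewise
shared partners `gwesp(0.25, fixed)` (the triad term), `nodecov(size)`,
`nodecov(count)` and the species-factor `nodefactor(vertex.names)`.
Estimation is by exact enumeration (small graphs), maximum
pseudolikelihood (dyad-independent models, where it is exact), and
Monte-Carlo maximum likelihood with a Metropolis–Hastings dyad-toggle
sampler (the triad model). Fits are screened by simulation-based goodness
of fit and degeneracy diagnostics, with an automatic fallback from the
triad model to its covariate-only restriction. Across a survey campaign
the per-network fits are pooled into species-level consistent-association
tables, phylum summaries, per-site triad-coefficient profiles, a
co-occurrence social diversity proportion, and a random-forest
relative-influence decomposition of the triad goodness of fit over site,
depth, aspect and network size. A seeded synthetic transect generator with
planted pairwise affinities and site-level triad propensities makes every
stage testable against known truth.

## Worked example

```r
library(benthicnet)

tr <- transectRecord("T1", "siteA", 7, "photophilous",
                     strsplit("AAAAABBBBCCAA", "")[[1]])
runLengthEncode(tr)
#>   species start length
#> 1       A     1      5
#> 2       B     6      4
#> 3       C    10      2
#> 4       A    12      2

net <- buildNetwork(runLengthEncode(tr), surveyId = "T1")
vertexTable(net)
#>   code size count  phylum
#> 1    A    7     2 unknown
#> 2    B    4     1 unknown
#> 3    C    2     1 unknown
edgeTable(net)
#>   u v multiplicity
#> 1 A B            1
#> 2 A C            1
#> 3 B C            1
```

The three runs of A, B, C abut pairwise, so the network is the triangle
A–B, B–C, C–A with size attributes 7, 4, 2 cm; on a triangle the gwesp
statistic equals 3 for any decay:

```r
computeStatistics(net, presetModel("model1"))
#>            edges gwesp.fixed.0.25     nodecov.size    nodecov.count
#>                3                3               26                8
```

A full synthetic campaign (17 surveys × 5 depths = 85 transects) runs
end to end in a few minutes:

```r
camp <- simulateCampaign(seed = 1)
attrs <- communityAttributes(camp$truth$community)
nets <- buildNetworks(camp$records, attrs = attrs)
bundles <- lapply(seq_along(nets), function(i)
  fitWithFallback(nets[[i]], seed = childSeed(1, "fit", i)))
cls <- classifyPreferences(collectSpeciesEffects(bundles, attrs))
dp <- diversityProportions(bundles, cls)
dp$proportion           # share of networks with dyad+triad structural support
#> [1] 0.8
scoreRecovery(camp$truth, speciesTable = cls)[c("sensitivity", "specificity")]
#> $sensitivity
#> [1] 1
#> $specificity
#> [1] 1
```

Here 68 of the 85 networks qualify as showing co-occurrence social
diversity (triad model converged and both `edges` and `gwesp`
goodness-of-fit p-values above 0.05), and the three planted consistent
associates are recovered exactly, with no neutral species misclassified.

See the vignette (`vignettes/cooccurrence-social-diversity.Rmd`) for the
model, the estimation algorithms and the generator design.

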