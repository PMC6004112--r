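# hsta — Hidden-State Taxonomic Assignment for coxI Metabarcoding

`hsta` assigns animal metabarcoding reads (cytochrome oxidase I, the
standard animal DNA barcode) to taxa **without an OTU clustering step**.
Instead of clustering reads at a similarity threshold and classifying
cluster representatives, every denoised read is scored directly against a
collection of per-taxon nucleotide profile hidden Markov models and
classified by a Bayes-factor rule over the competing scores. The package
is aimed at researchers building or benchmarking metabarcoding
assignment pipelines on mock or environmental invertebrate communities.

## The method

**Reference profiles.** For each candidate taxon (order rank and species
rank are modelled as separate collections), reference coding sequences
are translated, aligned at the protein level, and the codons are threaded
back through the protein alignment (*back-alignment*), so the nucleotide
alignment stays in frame. A plan-7 profile HMM over `{A,C,G,T}` is
estimated from each alignment: columns with gap fraction < 0.5 become
match states; emissions and transitions are Laplace-smoothed counts.

**Scoring.** A read *i* receives, from each profile, a forward-algorithm
bit score

&nbsp;&nbsp;&nbsp;&nbsp;*S* = log₂ [ P(read | profile, local alignment) / P(read | background) ],

summed over all local (fragment) alignments, with hmmer-style uniform
fragment entry/exit and a length-modelled background. Significance comes
from a per-profile Gumbel calibration fitted to scores of random
background sequences, giving E-values.

**Classification.** With per-profile scores `S₁ ≥ S₂ ≥ … ≥ Sₙ` passing
the E-value gate, the log Bayes factor of the best hit is

&nbsp;&nbsp;&nbsp;&nbsp;ln(BF) = S₁ − ln Σ₂ⁿ exp(Sᵢ)

and each read is **Good** (ln BF > 3, assigned to the best profile's
taxon), **Ambiguous** (significant but ln BF ≤ 3), or **Unclassified**
(best E-value above the gate).

**Diagnostics and evaluation.** The package also provides the
GC-content/site-diversity regression diagnostic
(`Dreads ~ Dref + GCref`, per-site Hill-number diversity of reads and
references with a 100-bp GC window, sequential ANOVA), detection ratios
against an expected community, Pearson correlation of read abundance with
biomass, species-pair read-count ratios, and a biomass-weighted
mock-community read simulator with a GC-dependent error component.

## Worked example

Simulate a three-order, seven-species invertebrate community (biomasses
taken from the packaged mock-community table), build calibrated species
profiles from the same references, and classify 300 reads:

```r
library(hsta)

spec <- exampleCommunitySpec(seed = 1,
  errorModel = errorModel(baseSubRate = 0.01, homopolymerIndelRate = 0.005))
refs <- evolveReferences(spec)
refs
#> TaxonSet with 27 sequences; 3 order label(s), 9 species label(s)

sim <- sampleReads(refs, spec, nReads = 300)
profiles <- buildTaxonProfiles(refs, rank = "species", seed = 2)
profiles[["Coleoptera_sp01"]]
#> ProfileHMM 'Coleoptera_sp01' (rank species): 657 match states, calibrated

res <- assignAll(sim$reads, profiles)
table(res$assignments$category)
#> Good
#>  300
head(res$assignments[, c("query_id", "category", "taxon", "ln_bf")], 3)
#>              query_id category           taxon    ln_bf
#> read000001 read000001     Good Coleoptera_sp03 29.80081
#> read000002 read000002     Good Coleoptera_sp01 33.88431
#> read000003 read000003     Good Coleoptera_sp06 41.06515
```

Every read is Good and carries a large ln(BF): at ~5% between-species
divergence and 1% read error, the best profile outcompetes its rivals
decisively. Abundances track biomass at the order rank:

```r
expected <- readExpectedCommunity()   # packaged mock-community biomasses
ord <- assignAll(sim$reads, buildTaxonProfiles(refs, rank = "order", seed = 3))
biomassCorrelation(ord$abundance, expected, "order")
#> [1] 0.9994289
```

The sequential-ANOVA arithmetic of the GC diagnostic, applied to a
published decomposition (5′ region of a beetle reference set):

```r
anovaFromDecomposition(
  c(GCref = 4.518, Dref = 58.766, Residuals = 123.808), c(1, 1, 562))
#>        term  df  sum_sq    mean_sq  f_value      p_value explained_pct
#> 1     GCref   1   4.518  4.5180000  20.5085 7.253082e-06      2.414855
#> 2      Dref   1  58.766 58.7660000 266.7557 2.341397e-49     31.410215
#> 3 Residuals 562 123.808  0.2202989       NA           NA     66.174930
```

GC content explains a small but highly significant share of the per-site
diversity of reads beyond what reference diversity predicts — the
signature of GC-dependent sequencing error surviving denoising.

A command-line front end over the same functions ships at
`inst/cli/hsta.R` (`simulate`, `backalign`, `build`, `scan`, `classify`,
`gcmodel`, `evaluate`), writing a JSON manifest of seeds, thresholds and
input digests next to every output.

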