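---
title: "Profile-HMM taxonomic assignment for coxI metabarcoding: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profile-HMM taxonomic assignment for coxI metabarcoding: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hsta)
```

## The assignment model

`hsta` classifies amplicon reads of the animal barcode region (coxI, a
mitochondrial protein-coding fragment) by scoring each read against a
collection of per-taxon nucleotide profile hidden Markov models and
applying a Bayes-factor decision rule. The defining property of the
approach is the absence of an OTU clustering step: no similarity
threshold intervenes between denoised reads and taxonomic labels, so
the clustering-threshold calibration problem disappears entirely.

### Back-alignment

Because coxI is protein coding, reference alignments are built at the
protein level and the nucleotides are threaded back through them: each
aligned residue expands to its source codon and each protein gap to
`---`. This keeps every alignment column in frame and concentrates
indels at codon boundaries, where they occur biologically. The package
accepts an externally produced protein MSA and also ships a small
progressive aligner (UPGMA guide tree on 3-mer distances,
profile–profile Needleman–Wunsch with BLOSUM62, linear gap penalty −8)
so that the whole pipeline runs without external binaries. The shipped
aligner is adequate for the closely related within-taxon sets profiles
are built from; for distant or frameshifted references a dedicated
aligner should be used upstream. Ungapping any back-aligned row
reproduces the in-frame input sequence byte for byte — this invariant
is tested, and it is what guarantees profiles are built from the
sequences the user supplied.

The genetic code defaults to the invertebrate mitochondrial table
(NCBI table 5), since coxI is mitochondrial; the standard code is
selectable. Reading frames are rarely annotated in reference sets, so
the frame is chosen per sequence as the one with the fewest internal
stops (ties to the lowest frame). Internal stop codons translate to a
warning rather than an error: reference databases contain
pseudogene-like entries, and rejecting them silently would bias the
reference set.

### Profile architecture and estimation

Profiles are plan-7 models (match/insert/delete per consensus column)
over `{A,C,G,T}`:

* **Match columns**: alignment columns with gap fraction strictly below
  `occupancyThreshold` (default 0.5). The strict inequality is a
  documented tie rule: a column at exactly 50% gaps is *not* a match
  column.
* **Emissions**: column base counts plus a Laplace pseudocount
  (default 1), normalised; `N` characters are excluded from counts.
  Insert states emit the background distribution (uniform by default),
  so inserts are score-neutral per residue.
* **Transitions**: counted from each row's observed match/insert/delete
  path with the same pseudocount. State classes never observed (e.g.
  inserts in a gapless alignment when the pseudocount is 0) default to
  the deterministic continue-to-next-match transition.

Scoring uses the forward algorithm — the sum over all local alignments,
not just the best one — in log-odds bits against the background.
Locality follows the uniform-fragment convention: entry into any match
state with probability `2/(M(M+1))` and exit from any match state, so a
read covering any sub-region of the barcode is scored without penalty
for what it does not cover. Flanking read sequence outside the aligned
fragment is emitted by background states under an hmmer-style length
model (flank self-loop `L/(L+2)`, geometric null with continuation
`L/(L+1)`), which keeps scores nearly invariant when a full-coverage
query is padded with unrelated background sequence. For reads covering
only part of the profile, extra flanking sequence can still shift the
score by a few bits, because the forward sum legitimately gains
alignment-extension paths into the uncovered profile region; this is a
property of local forward scoring, not an artefact. Multihit scoring
and the accelerated filter pipeline of full search tools are
deliberately out of scope at desk-scale profile counts.

The implementation runs in scaled probability space (per-column
renormalisation with the log of the scale accumulated separately), so
the inner loop is pure multiply–add. It is verified against a
brute-force path-enumeration oracle to below 10⁻⁹ bits on small
profiles; the oracle enumerates every state path explicitly and shares
no code with the dynamic program.

### Significance and the Bayes-factor rule

Raw bit scores are converted to E-values through a per-profile Gumbel
calibration: `nShuffles` (default 200) i.i.d. background sequences of
consensus length are scored and a Gumbel location/rate is fitted by
maximum likelihood (moment-based start, Nelder–Mead). The calibration
seed is recorded in the profile serialization, so calibrated profiles
are exactly reproducible. The E-value gate defaults to 10, the
conventional reporting threshold; 0.01 is the natural stricter preset
(both are exposed, since "default significance" in search tools is
genuinely ambiguous between the two).

Reads passing the gate are classified by the log Bayes factor
`ln(BF) = S₁ − ln Σᵢ₌₂ⁿ exp(Sᵢ)` over the *significant* hits, with
threshold 3.0. Two design points deserve emphasis:

* **Units.** The canonical rule applies natural `exp`/`ln` directly to
  bit scores (base-2 logs). That mixes bases, but it is the rule as
  specified, and the threshold 3.0 is calibrated to it; a `units =
  "nats"` option converts bits to nats first for the
  dimensionally-consistent variant. Both behaviours are tested; the
  default is the literal rule.
* **Competitor set.** The sum runs over hits passing the E-value gate
  rather than all profiles, so noise-level scores cannot manufacture
  Ambiguous calls.

Ties for the best hit break by profile name; since an exact tie gives
`ln(BF) = 0 < 3`, the tie-break can never change a category, only the
name recorded for an Ambiguous read. A single-profile collection makes
every significant read Good (`n = 1` leaves no competitor, BF infinite)
— the rule degenerates exactly as the arithmetic says it should.

Order-rank and species-rank profiles are kept in separate collections
and scanned independently, giving one assignment per rank. Mixing ranks
in one collection would make order profiles compete with their own
species profiles inside the Bayes factor, which conflates two different
questions.

## The GC/diversity diagnostic

GC-dependent sequencing error that survives denoising shows up as
excess per-site diversity in reads relative to references. The
diagnostic regresses `Dreads`, the per-site exponential Shannon entropy
(Hill number of order 1, the effective number of bases at a column;
gaps and `N` excluded) of reads placed in reference coordinates, on
`Dref`, the same quantity in the reference alignment, and `GCref`, the
reference GC percentage averaged over sequences per column and smoothed
with a centred 100-column moving average (edge-truncated). Reads enter
reference coordinates through their Viterbi alignment to the taxon
profile, so read and reference columns correspond exactly; inserted
read bases, having no reference column, are dropped.

Two analysis regions follow the barcode's two sequencing directions:
columns 1–400 (5′) and 200–end (3′), 1-based inclusive. The model is an
OLS fit with a sequential (type I) ANOVA. Sequential decompositions are
order dependent, and the package reports rather than hides this: both
term orders are available, swapping them changes term sums of squares
but never the residual. The reporting default lists GC first, matching
the published table layout. For *testing* the GC effect, however, the
GC term must enter after diversity — that is the model-formula order,
and the only order in which its sequential F is a valid test of GC's
added contribution. Fitted first against a strong diversity effect, the
GC term absorbs chance covariance with the omitted predictor and its
null rejection rate is far above nominal (we measure ~26% at α = 0.05
in the null simulation, versus ~5% in the formula order). The
null-calibration test and the acceptance script therefore test GC after
diversity.

Degenerate inputs are handled explicitly: an all-gap column is flagged
and excluded from model rows; a constant covariate (e.g. uniform GC) is
reported as a zero-variance row with a warning rather than an error,
while genuine collinearity between varying covariates raises an error
naming the terms.

## The mock-community simulator

The generator produces labelled communities with the statistical
structure the assignment problem assumes, and it is first-class, tested
code — the end-to-end guarantees of the package are statements about
data with these properties:

* **References**: a random in-frame, stop-free ancestor (invertebrate
  mitochondrial code, default 219 codons ≈ the 657-bp barcode), evolved
  along star trees in three tiers — order (default 0.2
  substitutions/site), species (0.05), individual (0.005, `nIndividuals
  = 3` per species). Substitution rates are codon-position weighted
  (3rd position 4× the 1st, 1st 2× the 2nd), and substitutions that
  would create stops are repaired, so the sequences stay coding-like.
  The individual tier is needed because a species profile requires at
  least two sequences; its default is an order of magnitude below the
  species tier, in line with intraspecific barcode variation. Star
  trees, not realistic phylogenies: the tiers exist to control
  divergence, and a star is the simplest object that does so.
* **Reads**: counts are multinomial over species with weights
  biomass × amplification bias (bias only, when emulating a
  biomass-equalised sample — one boolean switches between the two study
  designs). Each read is a random-start fragment (default 250 bp, a
  typical pyrosequencing length), labelled 5′/3′ by which half of the
  reference its midpoint covers, mirroring direction-separated read
  sets. Errors: substitutions at `baseSubRate + gcSubSlope × (100-bp
  window GC fraction)` — the GC-dependent component the diagnostic is
  designed to detect — plus single-base indels at homopolymers of
  length ≥ 3, the characteristic pyrosequencing failure mode.
* **Not emulated**: flowgram-level noise, chimeras, primer sequence,
  length variation of real amplicons, and real phylogenetic structure.
  Passing the end-to-end tests therefore demonstrates correctness of
  the machinery under the stated statistical assumptions, not field
  performance on environmental samples.

The default community for end-to-end checks
(`exampleCommunitySpec()`) is the three most abundant orders of the
packaged mock community — beetles with seven species at 22.89 g total,
flies at 4.12 g, grasshoppers at 2.44 g — with unbiased amplification.

## Numerical choices

* Forward DP in scaled probability space; per-column renormalisation by
  the column maximum; no transcendentals in the inner loop. Equivalence
  with explicit path enumeration to < 10⁻⁹ bits is part of the test
  suite and the acceptance script.
* `N` in queries emits at background in both match and insert states
  (log-odds 0); queries never contain gaps.
* Gumbel survival saturates at exactly 1.0 in double precision a few
  nats below the location parameter; E-values are strictly decreasing
  from the location upward, which is the regime that matters.
* Log-sum-exp everywhere a sum of exponentials appears (Bayes factor,
  calibration), max-shifted for overflow safety; verified against a
  naive two-pass computation for scores up to 500.
* All coordinates are 1-based inclusive alignment columns; the region
  bounds 400 and 200 are parameters, not constants.
* Every stochastic step (ancestor, evolution, read sampling,
  calibration shuffles) funnels through an explicit seed, and seeded
  helpers restore the caller's RNG state.

## Problem sizes

Test and acceptance runs use a compact community (60-codon barcode,
five species) for unit-level properties and the full-size community
(219 codons, 9 species, 300 reads, 200 calibration shuffles per
profile) for end-to-end recovery; the null calibration of the GC test
uses 1000 replicates of 564-row fits, matching the residual degrees of
freedom of the published decomposition. These sizes are the package's
reference conditions; all of them are parameters.

## Known limitations

* The Bayes-factor rule inherits the units ambiguity discussed above;
  comparisons across tools should fix `units` explicitly.
* Detection ratios are reported as fractions in [0, 1]; published
  percentage figures for such ratios are sometimes misprinted fractions
  (e.g. "0.45%" for 5/11), so the package never formats them as
  percentages.
* E-value calibration assumes i.i.d. background composition; strongly
  biased query composition (low-complexity reads) will make E-values
  optimistic. No composition correction is applied.
* The simulator's indel model acts on the read only; profiles built
  from indel-containing reference alignments are supported, but
  frameshifted references are not repaired.
* Species-level discrimination degrades as between-species divergence
  approaches the read error rate; the package reports Ambiguous in that
  regime rather than guessing, which is the intended failure mode.
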