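# Shared small fixtures, built once per test run. The compact community
# (short barcode, few taxa) keeps per-test cost low; full-size defaults
# are exercised in the acceptance tests.

compactSpec <- function(seed = 101L, ...) {
  taxa <- data.frame(
    order_label = c("Coleoptera", "Diptera", "Orthoptera"),
    n_species = c(3L, 1L, 1L),
    biomass_g = c(22.89, 4.12, 2.44),
    bias_multiplier = c(1, 1, 1))
  args <- list(taxa = taxa, ancestorLengthCodons = 60L,
               errorModel = errorModel(baseSubRate = 0.01,
                                       readLength = 120L),
               seed = seed)
  override <- list(...)
  args[names(override)] <- override
  do.call(communitySpec, args)
}

.fixtureCache <- new.env(parent = emptyenv())

compactRefs <- function() {
  if (is.null(.fixtureCache$refs))
    .fixtureCache$refs <- evolveReferences(compactSpec())
  .fixtureCache$refs
}

compactOrderProfiles <- function() {
  if (is.null(.fixtureCache$orderProf))
    .fixtureCache$orderProf <- buildTaxonProfiles(
      compactRefs(), rank = "order", nShuffles = 200L, seed = 7L)
  .fixtureCache$orderProf
}

compactSpeciesProfiles <- function() {
  if (is.null(.fixtureCache$spProf))
    .fixtureCache$spProf <- buildTaxonProfiles(
      compactRefs(), rank = "species", nShuffles = 200L, seed = 7L)
  .fixtureCache$spProf
}
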