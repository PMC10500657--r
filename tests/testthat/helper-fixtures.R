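# Shared fixtures, built once per test session. The planted knowledge graph
# uses the generator's default study conditions (200 entities, 8 relations,
# 3 numeric attributes, sigma = 0.05); the trained spaces use the default
# training configuration.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixture_cache[[name]])) .fixture_cache[[name]] <- build()
  .fixture_cache[[name]]
}

planted_fixture <- function() fixture("planted", function() {
  generate_planted_kg(synthetic_config(seed = 20260926L))
})

planted_exact_fixture <- function() fixture("planted_exact", function() {
  generate_planted_kg(synthetic_config(seed = 20260926L, geom_noise = 0,
                                       sigma = 0))
})

trained_fixture <- function(method = "TransRA") fixture(
  paste0("space_", method), function() {
    p <- planted_fixture()
    train_embeddings(training_kg(p), method, training_config(seed = 7L))
  })

# a small chemistry-flavoured label table for entity-linking examples
chem_kg_fixture <- function() fixture("chem_kg", function() {
  tri <- data.frame(
    head = c("sp:benzene", "sp:benzene", "sp:ethanol", "sp:methane"),
    relation = c("rel:has_use", "rel:has_use", "rel:has_use", "rel:has_use"),
    tail = c("use:solvent", "use:precursor", "use:solvent", "use:fuel"),
    stringsAsFactors = FALSE)
  at <- data.frame(
    entity = c("sp:benzene", "sp:ethanol", "sp:methane"),
    attribute = "attr:molecular_weight",
    value = c(78.11, 46.07, 16.04), unit = "g/mol", stringsAsFactors = FALSE)
  labels <- data.frame(
    iri = c("sp:benzene", "sp:ethanol", "sp:methane", "use:solvent",
            "use:precursor", "use:fuel"),
    label = c("benzene", "ethanol", "methane", "solvent", "precursor", "fuel"),
    type = c("species", "species", "species", "use", "use", "use"),
    aliases = c("C6H6|benzol", "C2H5OH|alcohol", "CH4", "", "", ""),
    stringsAsFactors = FALSE)
  knowledge_graph(tri, at, labels, "chem")
})
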