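# Heavy shared fixtures, built once per test run.  Factor-graph
# enumeration for Zeb1 (4242 regions) dominates parameter-graph
# construction, so each graph variant is memoised.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, builder(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

emt <- function() cached("emt_net", emt_network)
toggle <- function() cached("toggle_net", toggle_switch_network)

emt_pg <- function(mode = "full") {
  key <- paste0("emt_pg_", mode)
  cached(key, function() {
    if (mode == "full") parameter_graph(emt(), "full")
    else if (mode == "essential") essential_parameter_graph(emt())
    else general_parameter_graph(emt(), mode)
  })
}

toggle_pg <- function() cached("toggle_pg", function() parameter_graph(toggle()))

label_to_cell <- function(lb) {
  as.integer(strsplit(gsub("FP\\(|\\)", "", lb), ",")[[1]])
}

# distinct active regions of a gene restricted to one layer
layer_pool <- function(pg, gene, layer) {
  which(pg$factor_graphs[[gene]]$layer[pg$active[[gene]]] == layer)
}
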