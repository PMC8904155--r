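# Shared fixtures.  Reduced pairs are deterministic; cache them per session
# so every test file does not pay the construction cost again.
reduced_pair_cached <- local({
  cache <- new.env(parent = emptyenv())
  function(budget = 12) {
    key <- as.character(budget)
    if (is.null(cache[[key]])) cache[[key]] <- make_reduced_pair(budget)
    cache[[key]]
  }
})

zero_densities <- function() {
  setNames(as.list(rep(0, 7)),
           c("g_Na", "g_K", "g_KA", "g_KCa", "g_Ca", "g_h", "g_T"))
}

soma_only_morph <- function(d = 20) {
  morphology(data.frame(id = 1L, parent_id = NA_integer_, kind = "soma",
                        length = d, diameter = d, n_segments = 1L),
             paths = list("1" = rbind(c(-d / 2, 0, 0), c(d / 2, 0, 0))))
}

# single soma compartment with only leak (plus optional h conductance)
passive_soma_cell <- function(g_h = 0, d = 20) {
  ov <- zero_densities()
  ov$g_h <- g_h
  build_preset_cell("A2", soma_only_morph(d),
                    overrides = list(densities = list(soma = ov)))
}

# a small hand-written SWC: 2-point soma, a branching dendrite, an axon
example_swc_lines <- function() {
  c("# test neuron",
    "1 1 0 0 0 6 -1",
    "2 1 8 0 0 6 1",
    "3 3 20 0 0 1.5 2",
    "4 3 35 5 0 1.2 3",
    "5 3 50 15 2 1.0 4",
    "6 3 50 -15 2 1.0 4",
    "7 3 65 -25 4 0.8 6",
    "8 2 -12 0 0 0.8 1",
    "9 2 -30 0 0 0.8 8",
    "10 2 -60 0 0 0.7 9")
}
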