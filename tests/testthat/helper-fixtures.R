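# Shared fixtures. The study-scale simulation runs (N = 484, 12 groups) are
# expensive, so they are computed once per session and memoised; several
# end-to-end checks share them.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# A tiny hand-written trait table: 3 specimens, TL + one shape trait + one
# count trait.
tiny_table <- function() {
  trait_table(
    data.frame(specimen_id = c("a", "b", "c"),
               TL = c(400, 500, 600),
               HL = c(20, 24, 30),
               ven = c(150L, 160L, 155L)),
    trait_kinds = c(TL = "morphometric", HL = "morphometric", ven = "meristic"),
    tl_name = "TL"
  )
}

# Small planted simulation for module-level tests.
small_sim <- function(seed = 1, n = 120, groups = 4, separation = 3,
                      n_morph = 6, n_mer = 4) {
  simulate_morphotypes(sim_config(
    n_specimens = n, n_groups = groups, n_morphometric = n_morph,
    n_meristic = n_mer, separation = separation, seed = seed
  ))
}

# Full-pipeline core (preprocess -> k-NN(4) -> GAE(d = 8) -> reconstruct ->
# Louvain) on the study-shaped simulation, per seed.
study_run <- function(seed, separation = 3) {
  memo(paste0("study_", seed, "_", separation), {
    sim <- default_porthidium_like(seed = seed, separation = separation)
    x <- preprocess_traits(sim$trait_table)
    g <- knn_graph(x, 4)
    fit <- gae_train(x, g, gae_config(d = 8, seed = derive_seed_for_tests(seed)))
    rg <- reconstruct_graph(fit$a_hat)
    part <- louvain_cluster(rg, seed = seed)
    list(Q = part$Q, n_communities = part$n_communities,
         nmi_planted = nmi(part$labels, sim$planted_labels))
  })
}

derive_seed_for_tests <- function(seed) (seed * 7919) %% 2147483647
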