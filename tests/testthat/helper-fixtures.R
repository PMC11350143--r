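# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# a small hierarchy: 4 fine types in 3 coarse groups plus one cancer type
tiny_hierarchy <- function() {
  cell_type_hierarchy(
    fine_types = c("naive_T", "memory_T", "B", "endothelial"),
    coarse_of = c(naive_T = "T_cells", memory_T = "T_cells",
                  B = "B_cells", endothelial = "endothelial"),
    cancer_types = "cancer_X")
}

tiny_config <- function(...) {
  synthetic_config(n_genes = 150, markers_per_type = 5,
                   marker_fold_change = 8, baseline_dispersion = 0.1,
                   batch_effect_sd = 0.05, seed = 42L, ...)
}

tiny_profiles <- function() {
  cached("tiny_profiles", generate_profiles(tiny_config(), tiny_hierarchy()))
}

# the full default panel, used by heavier integration tests
default_profiles <- function() {
  cached("default_profiles",
         generate_profiles(synthetic_config(seed = 7L), default_hierarchy()))
}

default_signature <- function() {
  cached("default_signature", build_signature(default_profiles()))
}

# noiseless admixtures over the tiny panel with known proportions
tiny_mixture <- function(n = 12, seed = 3) {
  profiles <- tiny_profiles()
  h <- tiny_hierarchy()
  set.seed(seed)
  types <- c(h$fine_types, h$cancer_types)
  props <- broken_stick(length(types), proportion_constraint(step = 0.001),
                        n_candidates = n)
  colnames(props) <- types
  meta <- data.frame(dataset = rep(c("D1", "D2"), length.out = n),
                     cancer_type = "cancer_X",
                     batch = rep(c("batch1", "batch2"), length.out = n),
                     origin = "in_silico", design_class = "unconstrained")
  design <- admixture_design(props, meta)
  list(design = design, dataset = mix_tpm(profiles, design))
}
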