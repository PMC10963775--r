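# Shared synthetic cohorts, built once per test run and cached.
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, builder(), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# Study-conditions cohort: 1000 genes x 120 samples, three planted
# processes at 20x the noise SD, equal normal/transition/AML thirds.
default_cohort <- function() cached("default", function() {
  gen <- generate_dataset(synthetic_spec(seed = 42))
  res <- run_pipeline(gen$expression, gen$meta, seed = 42)
  list(gen = gen, res = res)
})

# Sparser, higher-dimensional cohort emulating the 1-3-active-of-many
# process structure of real AML cohorts (six planted processes).
sparse_cohort <- function() cached("sparse", function() {
  spec <- synthetic_spec(n_processes = 6,
                         active_fraction = c(2/3, 0.33, 0.22, 0.15, 0.1, 0.07),
                         seed = 1)
  gen <- generate_dataset(spec)
  res <- run_pipeline(gen$expression, gen$meta, seed = 1)
  list(gen = gen, res = res)
})

# independent trapezoidal quadrature used by the dynamics tests
trapz_ <- function(x, y) sum(diff(x) * (y[-length(y)] + y[-1]) / 2)

# A tiny valid decomposition object built by hand (for unit tests of the
# FEC / barcode layer that need exact, hand-computable numbers).
toy_decomposition <- function(G, lambda, thresholds, n_significant = NULL) {
  structure(list(G = G, lambda = lambda,
                 singular_values = sqrt(colSums(lambda^2)),
                 gene_ids = rownames(G), sample_ids = rownames(lambda),
                 pseudocount = 1, thresholds = thresholds,
                 n_significant = n_significant),
            class = "surprisal_decomposition")
}
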