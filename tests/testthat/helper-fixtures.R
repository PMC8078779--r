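# Shared fixture builders; everything is generated in code under fixed seeds.

# Minimal split-like object for exercising augmenters directly.
fake_split <- function(expression, stages) {
  list(train = list(expression = expression, stages = as.integer(stages)))
}

# Gaussian stage blobs: per-stage counts, stage s has mean s * delta on every
# gene. Returns a fake split.
blob_split <- function(counts, n_genes = 2, delta = 1, sd = 1, seed = 1) {
  set.seed(seed)
  stages <- rep(seq_along(counts), counts)
  n <- length(stages)
  x <- matrix(rnorm(n * n_genes, mean = stages * delta, sd = sd), n, n_genes,
              dimnames = list(sprintf("S%04d", seq_len(n)),
                              sprintf("g%02d", seq_len(n_genes))))
  fake_split(x, stages)
}

# Tiny cohort wrapper (paired mutation/expression) for split/harness tests.
tiny_cohort <- function(counts = c(6, 6, 6, 6), n_genes = 16,
                        n_informative = 8, seed = 1, ...) {
  make_synthetic_cohort(synthetic_config(stage_counts = counts,
                                         n_genes = n_genes,
                                         n_informative = n_informative,
                                         seed = seed, ...))$cohort
}

# Linearly separable 4-class data: class s puts mean `sep` on its own block of
# genes. 200 samples x 20 genes by default.
separable_set <- function(n_per_class = 50, n_genes = 20, sep = 3, seed = 1) {
  set.seed(seed)
  stages <- rep(1:4, each = n_per_class)
  n <- length(stages)
  x <- matrix(rnorm(n * n_genes), n, n_genes,
              dimnames = list(NULL, sprintf("g%02d", seq_len(n_genes))))
  block <- n_genes %/% 4
  for (s in 1:4) {
    cols <- ((s - 1) * block + 1):(s * block)
    x[stages == s, cols] <- x[stages == s, cols] + sep
  }
  list(expression = x, stages = stages)
}
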