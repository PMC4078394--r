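# Small simulated designs shared across test files. Everything is generated
# in code at test time; nothing is read from disk.

# a modest independent-column design with a known sparse model and phenotype
make_instance <- function(n = 200, p = 400, s = 10, h2 = 0.8, seed = 100,
                          maf = c(0.1, 0.5)) {
  g <- simulate_genotypes(n, p, maf = maf, seed = seed)
  spec <- ensemble_spec("signs", s = s, p = p)
  x <- place_support(draw_coefficients(spec, p, seed = seed + 1), g,
                     seed = seed + 2)
  m <- true_model(x, h2)
  ph <- simulate_phenotype(g, m, seed = seed + 3)
  list(g = g, model = m, ph = ph)
}

# raw dosage matrix guaranteed polymorphic in every column
make_raw <- function(n, p, seed = 1, maf = 0.3) {
  set.seed(seed)
  raw <- matrix(rbinom(n * p, 2L, maf), n, p)
  for (j in seq_len(p)) {
    if (length(unique(raw[, j])) < 2) raw[1:2, j] <- c(0L, 1L)
  }
  raw
}
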