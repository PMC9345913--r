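# Shared test fixtures: hand-built models and an independent brute-force
# forward oracle (naive loops, no shared code path with the package's
# vectorized forward pass).

random_small_anfis <- function(n_inputs = 3, n_mf = 2, family = "gaussmf",
                               seed = 1) {
  set.seed(seed)
  inputs <- lapply(seq_len(n_inputs), function(j) {
    lo <- stats::runif(1, -1, 1)
    fuzzy_input(paste0("x", j), c(lo, lo + stats::runif(1, 0.5, 2)),
                n_mf = n_mf, family = family)
  })
  m <- anfis(inputs)
  m$consequents <- matrix(stats::rnorm(nrow(m$rules) * (n_inputs + 1)),
                          nrow(m$rules))
  m
}

# Layer-by-layer forward computation for a single input vector, written as
# plain loops from the network definition.
brute_force_predict <- function(model, x) {
  k <- length(model$inputs)
  n_rules <- nrow(model$rules)
  w <- numeric(n_rules)
  for (i in seq_len(n_rules)) {
    prod_mu <- 1
    for (j in seq_len(k)) {
      mf <- model$inputs[[j]]$mfs[[model$rules[i, j]]]
      prod_mu <- prod_mu * eval_mf(mf, x[j])
    }
    w[i] <- prod_mu
  }
  s <- max(sum(w), model$min_firing)
  y <- 0
  for (i in seq_len(n_rules)) {
    f_i <- sum(model$consequents[i, seq_len(k)] * x) +
      model$consequents[i, k + 1]
    y <- y + (w[i] / s) * f_i
  }
  y
}

# A one-membership input (below the constructor's minimum) for single-rule
# reduction tests.
single_mf_input <- function(name, domain) {
  structure(list(name = name, domain_min = domain[1], domain_max = domain[2],
                 mfs = list(mf_gauss(diff(domain), mean(domain))),
                 family = "gaussmf"),
            class = "fuzzy_input")
}
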