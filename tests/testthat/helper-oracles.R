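# Independent brute-force oracles, deliberately written as naive loops so
# they share no code path with the package implementations they check.

oracle_loo_r2 <- function(observed, calculated) {
  vapply(seq_along(observed), function(k) {
    xs <- observed[-k]
    ys <- calculated[-k]
    if (stats::sd(xs) == 0 || stats::sd(ys) == 0) NA_real_ else stats::cor(xs, ys)^2
  }, numeric(1L))
}

oracle_cii <- function(observed, calculated) {
  r2 <- stats::cor(observed, calculated)^2
  loo <- oracle_loo_r2(observed, calculated)
  1 - sum(pmax(0, loo - r2), na.rm = TRUE)
}

oracle_cccp <- function(observed, calculated) {
  r2 <- stats::cor(observed, calculated)^2
  loo <- oracle_loo_r2(observed, calculated)
  (sum(loo < r2, na.rm = TRUE) - sum(loo > r2, na.rm = TRUE)) / length(observed)
}

oracle_q2_loo <- function(observed, calculated) {
  n <- length(observed)
  press <- 0
  for (k in seq_len(n)) {
    fit <- stats::lm(y ~ x, data = data.frame(x = calculated[-k], y = observed[-k]))
    pred <- unname(stats::predict(fit, newdata = data.frame(x = calculated[k])))
    press <- press + (observed[k] - pred)^2
  }
  1 - press / sum((observed - mean(observed))^2)
}

# per-occurrence descriptor sum: walks the token list directly
oracle_dcw <- function(smiles, weights, blocked = character()) {
  toks <- smiles_tokenize(smiles)
  lookup <- function(key) {
    if (key %in% blocked) return(0)
    w <- weights[key]
    if (is.na(w)) 0 else unname(w)
  }
  total <- 0
  for (t in toks) total <- total + lookup(attr_key_single(t))
  if (length(toks) > 1L) {
    for (i in seq_len(length(toks) - 1L)) {
      total <- total + lookup(attr_key_pair(toks[i], toks[i + 1L]))
    }
  }
  total
}

# random observed/calculated series with a controlled correlation structure
random_series <- function(n, seed) {
  withr::with_seed(seed, {
    x <- stats::rnorm(n)
    y <- 0.8 * x + stats::rnorm(n, sd = stats::runif(1, 0.2, 1.2))
    list(observed = x, calculated = y)
  })
}

# small synthetic datasets used across test files
tiny_spec <- function(n = 120L, noise_sd = 0.2, seed = 7L) {
  sp <- default_fixture_spec(n_molecules = n, noise_sd = noise_sd, seed = seed)
  sp
}

tiny_cfg <- function(variant = "TF0", epochs_N = 4L, seed = 1L, ...) {
  tf_config(variant = variant, epochs_N = epochs_N, seed = seed, ...)
}
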