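# Small, fast simulation settings shared across test files. The full-size
# default configuration is exercised only in the end-to-end recovery test.

small_config <- function(seed = 7L, ...) {
  sim_config(n_chroms = 2L, chrom_length = 1e6, n_genes = 160L,
             n_enhancers = 30L, seed = seed, ...)
}

# memoised small bundle so several test files can share one simulation
small_bundle <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulate_bundle(small_config())
    cache
  }
})

# brute-force KDE oracle: direct kernel summation at every grid point,
# truncated at five bandwidths like the implementation under test
kde_brute_force <- function(pos, chrom_length, bandwidth, grid_step) {
  n_grid <- as.integer((chrom_length - 1) %/% grid_step + 1)
  x <- (seq_len(n_grid) - 1) * grid_step
  vapply(x, function(xi) {
    d <- xi - pos
    d <- d[abs(d) <= 5 * bandwidth]
    sum(stats::dnorm(d, sd = bandwidth))
  }, numeric(1))
}

# hypergeometric enumeration oracle built from choose() ratios only
fisher_enum <- function(a, b, c, d, alternative) {
  K <- a + b; n <- a + c; N <- a + b + c + d
  support <- max(0, n - (N - K)):min(K, n)
  pmf <- choose(K, support) * choose(N - K, n - support) / choose(N, n)
  obs <- pmf[match(a, support)]
  switch(alternative,
         greater = sum(pmf[support >= a]),
         less = sum(pmf[support <= a]),
         two.sided = sum(pmf[pmf <= obs * (1 + 1e-7)]))
}

# running-sum GSEA oracle: literal loop over ranks
es_brute_force <- function(scores, hit, weight) {
  N <- length(scores)
  m <- sum(hit)
  denom <- sum(abs(scores[hit])^weight)
  run <- 0
  best <- 0
  for (i in seq_len(N)) {
    run <- run + if (hit[i]) {
      if (denom == 0) 1 / m else abs(scores[i])^weight / denom
    } else {
      -1 / (N - m)
    }
    if (abs(run) > abs(best)) best <- run
  }
  best
}
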