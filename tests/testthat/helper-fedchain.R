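# Shared fixtures and independent oracles for the suite.

# Small, fast experiment configuration; override fields as needed.
quick_cfg <- function(...) {
  defaults <- list(n = 240, T_max = 3, sigma = 0, check_budget = FALSE,
                   M = 3, n_miners = 5, seed = 42)
  do.call(fedchain_config, utils::modifyList(defaults, list(...)))
}

# Brute-force multi-KRUM scorer: full pairwise distance matrix, explicit
# per-row sort.  Independent of the package implementation.
brute_krum <- function(pool, f, squared = FALSE) {
  R <- nrow(pool)
  n_nb <- R - f - 2
  sapply(seq_len(R), function(i) {
    d <- apply(pool[-i, , drop = FALSE], 1, function(row)
      sqrt(sum((pool[i, ] - row)^2)))
    if (squared) d <- d^2
    sum(sort(d)[seq_len(n_nb)])
  })
}

# Memoised expensive runs, shared across test files within a session.
.fixture_env <- new.env(parent = emptyenv())
cached <- function(name, expr) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- force(expr)
  .fixture_env[[name]]
}
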