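#' @title Moments accountant for the (subsampled) Gaussian release
#'
#' @description
#' Privacy loss is tracked through the log-moments of the privacy-loss
#' random variable of each noised release.  For a release with sampling
#' probability `q` and noise standard deviation `s`, let `mu0 = N(0, s^2)`,
#' `mu1 = N(shift, s^2)` and `mu = (1-q) mu0 + q mu1`.  The moment of
#' order `lambda` is
#'
#'   `alpha(lambda) = log max(E1, E2)`,
#'   `E1 = E_{x~mu0} (mu0(x)/mu(x))^lambda`,
#'   `E2 = E_{x~mu}  (mu(x)/mu0(x))^lambda`.
#'
#' Moments compose additively across devices and rounds, and the total is
#' converted to a privacy guarantee by the tail bound
#' `delta = min_lambda exp(alpha(lambda) - lambda * epsilon)`, i.e.
#' `epsilon = min_lambda (alpha(lambda) + log(1/delta)) / lambda` over an
#' integer grid of orders (default 1..100; order 0 is vacuous).
#'
#' Two conventions for `s` are supported.  `"paper_printed"` uses the
#' printed formulas verbatim: unit shift and `s = C_t * sigma`, so the
#' moment depends on the current clipping threshold.  `"normalized"` uses
#' unit shift and `s = sigma` (noise expressed relative to sensitivity, as
#' in standard DP-SGD accounting), making the moment independent of
#' `C_t`.  Both are exact computations; they differ only in what `s`
#' means.
#'
#' @param q sampling probability of local training, in \[0, 1\].
#' @param noise_std Gaussian standard deviation `s` (> 0).
#' @param shift mean separation between `mu0` and `mu1` (1 in the printed
#'   formulas).
#' @param mode `"paper_printed"` or `"normalized"` (documentation of how
#'   `noise_std` was formed; the integral itself is the same).
#' @return `mechanism_spec()` returns an object of class `mechanism_spec`.
#' @examples
#' sp <- mechanism_spec(q = 1, noise_std = 4)
#' log_moment(sp, 8)           # = 8 * 9 / 32
#' @export
mechanism_spec <- function(q, noise_std, shift = 1,
                           mode = c("paper_printed", "normalized")) {
  mode <- match.arg(mode)
  if (!is.numeric(q) || q < 0 || q > 1) stop_param("'q' must be in [0, 1]")
  if (!is.numeric(noise_std) || noise_std <= 0)
    stop_param("'noise_std' must be > 0")
  structure(list(q = q, noise_std = noise_std, shift = shift, mode = mode),
            class = "mechanism_spec")
}

# cache: identical (q, s, shift, lambda) moments are reused across rounds
.moment_cache <- new.env(parent = emptyenv())

#' Log-moment of one noised release
#'
#' Evaluates `alpha(lambda) = log max(E1, E2)` by adaptive numerical
#' integration.  Internally the integrals are computed in the standardized
#' coordinate `u = x / s` and in log-space around the integrand's maximum
#' (located on a dense grid first, since for large `lambda / s^2` the
#' integrand can be bimodal), which keeps the quadrature well-conditioned
#' for any noise scale.  Integration failure raises an explicit error
#' rather than returning NaN.
#'
#' @param spec a [mechanism_spec()].
#' @param lam integer moment order (>= 1).
#' @return the non-negative log-moment `alpha`.
#' @export
log_moment <- function(spec, lam) {
  stopifnot(inherits(spec, "mechanism_spec"))
  if (lam < 1 || lam != floor(lam)) stop_param("'lam' must be an integer >= 1")
  q <- spec$q
  if (q == 0) return(0)
  key <- paste(format(c(q, spec$noise_std, spec$shift), digits = 17),
               lam, collapse = "|")
  hit <- .moment_cache[[key]]
  if (!is.null(hit)) return(hit)

  d <- spec$shift / spec$noise_std       # shift in standardized units
  # log mixture-to-null density ratio log(mu(u)/mu0(u))
  Lfun <- function(u) {
    a <- u * d - d^2 / 2
    if (q == 1) return(a)
    m <- pmax(log1p(-q), log(q) + a)
    m + log(exp(log1p(-q) - m) + exp(log(q) + a - m))
  }
  log_int <- function(coef) {          # log of \int phi(u) exp(coef L(u)) du
    g <- function(u) dnorm(u, log = TRUE) + coef * Lfun(u)
    # L is asymptotically linear with slope in [0, d], so g has unit
    # Gaussian curvature around at most two modes: one near 0 (the (1-q)
    # branch) and one near coef * d (the q branch).  Integrate a +-50
    # window around each (merged when they overlap); the mass outside is
    # below exp(-1000).
    centers <- sort(unique(c(0, coef * d)))
    lo <- centers - 50; hi <- centers + 50
    if (length(centers) == 2 && lo[2] <= hi[1]) { lo <- min(lo); hi <- max(hi) }
    pieces <- Map(c, lo, hi)
    gstar <- max(vapply(pieces, function(p)
      max(g(seq(p[1], p[2], length.out = 2001))), 0))
    total <- 0
    for (p in pieces) {
      total <- total + tryCatch(
        integrate(function(u) exp(g(u) - gstar), p[1], p[2],
                  rel.tol = 1e-11, subdivisions = 500L,
                  stop.on.error = TRUE)$value,
        error = function(e) stop_param("moment integration failed: ",
                                       conditionMessage(e)))
    }
    gstar + log(total)
  }
  # E2: outer expectation under mu = integrand mu^(lam+1) mu0^(-lam)
  logE2 <- log_int(lam + 1)              # since mu = mu0 * exp(L)
  logE1 <- log_int(-lam)
  alpha <- max(logE1, logE2)
  if (alpha < 0) {
    if (alpha < -1e-8)
      stop_param("negative log-moment (", alpha, "): integration inaccurate")
    alpha <- 0
  }
  .moment_cache[[key]] <- alpha
  alpha
}

#' @title Composing moments across devices and rounds
#'
#' @description
#' `moment_ledger()` holds accumulated log-moments over an integer grid of
#' orders.  `accumulate_moments()` adds the moments of `rounds` identical
#' rounds, each with `devices` noised releases; in
#' `"sum_over_devices_and_rounds"` mode (the default) the per-release
#' moment is counted once per device per round, while `"rounds_only"`
#' counts one release per round (parallel composition across devices that
#' hold disjoint data).  Totals are non-negative and non-decreasing as
#' entries are added.
#'
#' @param lambdas integer grid of moment orders.
#' @param composition_mode `"sum_over_devices_and_rounds"` or
#'   `"rounds_only"`.
#' @return `moment_ledger()` returns an object of class `moment_ledger`.
#' @export
moment_ledger <- function(lambdas = 1:100,
                          composition_mode = c("sum_over_devices_and_rounds",
                                               "rounds_only")) {
  composition_mode <- match.arg(composition_mode)
  stopifnot(all(lambdas >= 1), all(lambdas == floor(lambdas)))
  structure(list(lambdas = as.integer(lambdas),
                 totals = numeric(length(lambdas)),
                 n_entries = 0L,
                 composition_mode = composition_mode,
                 history = list()),
            class = "moment_ledger")
}

#' @describeIn moment_ledger add `rounds` rounds of `devices` releases
#'   described by `spec` to the ledger.
#' @param ledger a `moment_ledger`.
#' @param spec a [mechanism_spec()] reflecting the round's noise (via
#'   `noise_std`, which in the printed convention is `C_t * sigma`).
#' @param devices,rounds multiplicities.
#' @export
accumulate_moments <- function(ledger, spec, devices = 1, rounds = 1) {
  stopifnot(inherits(ledger, "moment_ledger"))
  alphas <- vapply(ledger$lambdas, function(l) log_moment(spec, l), 0)
  mult <- if (ledger$composition_mode == "sum_over_devices_and_rounds")
    devices else 1
  ledger$totals <- ledger$totals + rounds * mult * alphas
  ledger$n_entries <- ledger$n_entries + as.integer(rounds * devices)
  ledger$history[[length(ledger$history) + 1L]] <-
    list(devices = devices, rounds = rounds, q = spec$q,
         noise_std = spec$noise_std)
  ledger
}

#' @describeIn moment_ledger smallest `epsilon` certified at `delta` by
#'   the tail bound over the grid; 0 for an empty ledger.
#' @param delta target `delta` in (0, 1).
#' @export
epsilon_for_delta <- function(ledger, delta) {
  stopifnot(inherits(ledger, "moment_ledger"))
  if (delta <= 0 || delta >= 1) stop_param("'delta' must be in (0, 1)")
  if (ledger$n_entries == 0L) return(0)
  max(0, min((ledger$totals + log(1 / delta)) / ledger$lambdas))
}

#' @title Privacy budget
#' @description A target `(epsilon, delta)` pair; training halts once the
#'   accountant certifies more than `epsilon` at the target `delta`.
#' @param epsilon privacy budget (>= 0).
#' @param delta tail probability, in (0, 1).
#' @return object of class `privacy_budget`.
#' @export
privacy_budget <- function(epsilon = 3, delta = 1e-4) {
  if (epsilon < 0) stop_param("'epsilon' must be >= 0")
  if (delta <= 0 || delta >= 1) stop_param("'delta' must be in (0, 1)")
  structure(list(epsilon = epsilon, delta = delta),
            class = "privacy_budget")
}

#' @describeIn privacy_budget TRUE once the spent `epsilon` exceeds the
#'   budget.
#' @param budget a `privacy_budget`.
#' @param ledger a [moment_ledger()].
#' @export
is_exhausted <- function(budget, ledger) {
  stopifnot(inherits(budget, "privacy_budget"))
  epsilon_for_delta(ledger, budget$delta) > budget$epsilon
}

#' @export
print.moment_ledger <- function(x, ...) {
  cat(sprintf("<moment_ledger> %d releases, mode=%s, alpha(1)=%.4g\n",
              x$n_entries, x$composition_mode, x$totals[1]))
  invisible(x)
}
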