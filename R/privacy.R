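#' @title Adaptive differential privacy for device updates
#'
#' @description
#' Before uploading, each device clips its per-round update to an L2 ball
#' of radius `C_t` and adds i.i.d. Gaussian noise of standard deviation
#' `C_t * sigma` to every coordinate.  The threshold adapts: a scalar
#' exponential moving average of the squared L2 norm of the previous
#' rounds' global updates serves as prior knowledge `E[g~^2]`, and
#'
#' * while `E[g~^2] <= G` (insufficient prior, e.g. the very first round
#'   where the prior is defined to be 0) the threshold is the fixed
#'   constant `C`;
#' * once `E[g~^2] > G` the threshold becomes `beta * sqrt(E[g~^2])`,
#'   tracking the magnitude of recent global updates.
#'
#' The boundary `E[g~^2] == G` uses the fixed-`C` branch (the conservative
#' early-stage behaviour; the two-sided rule leaves equality open).
#'
#' `clipper_state()` bundles the prior and the hyperparameters; defaults
#' are `G = 1e-6`, `beta = 1.2`, `sigma = 4`, `gamma = 0.1`, `C = 3`.
#'
#' @param prior current prior knowledge `E[g~^2]` (>= 0; 0 before the
#'   first round).
#' @param gamma EMA weight on the newest squared norm, in (0, 1].
#' @param beta clipping factor multiplying `sqrt(prior)`.
#' @param fixed_C fixed threshold used while the prior is insufficient.
#' @param prior_threshold the prior-sufficiency constant `G`.
#' @param sigma noise multiplier (>= 0).
#' @return `clipper_state()` returns an object of class `clipper_state`.
#' @examples
#' st <- clipper_state()
#' clipping_threshold(st)                 # 3, prior insufficient
#' st <- update_prior(st, rep(1, 4))      # |g|^2 = 4
#' clipping_threshold(st)                 # 1.2 * sqrt(0.4)
#' @export
clipper_state <- function(prior = 0, gamma = 0.1, beta = 1.2, fixed_C = 3,
                          prior_threshold = 1e-6, sigma = 4) {
  if (prior < 0) stop_param("'prior' must be >= 0")
  if (gamma <= 0 || gamma > 1) stop_param("'gamma' must be in (0, 1]")
  if (beta <= 0) stop_param("'beta' must be > 0")
  if (fixed_C <= 0) stop_param("'fixed_C' must be > 0")
  if (sigma < 0) stop_param("'sigma' must be >= 0")
  structure(list(prior = prior, gamma = gamma, beta = beta,
                 fixed_C = fixed_C, prior_threshold = prior_threshold,
                 sigma = sigma),
            class = "clipper_state")
}

#' @export
print.clipper_state <- function(x, ...) {
  cat(sprintf(paste0("<clipper_state> prior=%.4g gamma=%.3g beta=%.3g ",
                     "C=%.3g G=%.3g sigma=%.3g -> C_t=%.4g\n"),
              x$prior, x$gamma, x$beta, x$fixed_C, x$prior_threshold,
              x$sigma, clipping_threshold(x)))
  invisible(x)
}

#' @describeIn clipper_state fold the newest global update into the prior:
#'   `prior <- (1 - gamma) * prior + gamma * ||g~||^2`.  A non-finite
#'   global update (a diverged round) leaves the state unchanged with a
#'   warning.
#' @param state a `clipper_state`.
#' @param global_grad the previous round's global update (numeric vector).
#' @export
update_prior <- function(state, global_grad) {
  stopifnot(inherits(state, "clipper_state"))
  if (!all(is.finite(global_grad))) {
    warning("non-finite global gradient; prior left unchanged")
    return(state)
  }
  state$prior <- (1 - state$gamma) * state$prior +
    state$gamma * sum(global_grad^2)
  state
}

#' @describeIn clipper_state the current threshold `C_t` (always > 0).
#' @export
clipping_threshold <- function(state) {
  stopifnot(inherits(state, "clipper_state"))
  if (state$prior <= state$prior_threshold) state$fixed_C
  else state$beta * sqrt(state$prior)
}

#' @describeIn clipper_state L2-clip a vector:
#'   `g / max(1, ||g||_2 / C_t)`.  Leaves vectors inside the ball
#'   untouched; the output norm never exceeds `C_t`.
#' @param g numeric vector (a device's update).
#' @param C_t positive clipping threshold.
#' @export
clip_gradient <- function(g, C_t) {
  if (C_t <= 0) stop_param("'C_t' must be > 0")
  g / max(1, sqrt(sum(g^2)) / C_t)
}

#' @describeIn clipper_state add i.i.d. Gaussian noise with per-coordinate
#'   standard deviation `C_t * sigma` under a named substream derived from
#'   `(seed, device_id, round)`, so each device's noise is reproducible in
#'   isolation.
#' @param g_clipped clipped update.
#' @param sigma noise multiplier.
#' @param seed,device_id,round substream identifiers.
#' @export
add_noise <- function(g_clipped, C_t, sigma, seed = 1,
                      device_id = 0L, round = 0L) {
  if (sigma < 0) stop_param("'sigma' must be >= 0")
  if (sigma == 0) return(g_clipped)
  noise <- with_seed(derive_seed(seed, "dp_noise", device_id, round),
                     rnorm(length(g_clipped), 0, C_t * sigma))
  g_clipped + noise
}
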