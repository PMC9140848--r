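#' Threshold-gated autoregressive model specification
#'
#' Constructs the configuration of a continuous multichannel autoregressive
#' system in which cross-channel coupling is gated by a voltage threshold
#' (a nonlinearity emulating reliable communication through bursting) and
#' the coupling delay is either a fixed lag or a probabilistically jittered
#' lag (a non-Markovian system: no single fixed-lag state determines the
#' next state). Two generative forms are used, chosen by `lag_probs`:
#'
#' * **Recurrence form** (fixed lag `l`): each channel at time `t` is its
#'   own noise draw plus `self * x[i, t - l]` plus, for every other channel
#'   `j`, `cross[i, j] * x[j, t - l]` applied only when `x[j, t - l]`
#'   exceeds `threshold`. The first `l` timepoints are pure noise draws.
#' * **Accumulation form** (jittered lags): every timepoint is initialised
#'   to its noise draw; then, processing source times `t` in increasing
#'   order, each connection adds `coef * x[j, t]` into the target channel
#'   at `t + l` with `l` drawn independently per connection and timepoint
#'   from `lag` with probabilities `lag_probs`. Cross-connections
#'   contribute only when the fully accumulated source value `x[j, t]`
#'   exceeds `threshold`; contributions landing beyond the final timepoint
#'   are discarded.
#'
#' @param n_channels Number of channels (2 or 3).
#' @param self Self-connection coefficient(s); recycled to `n_channels`.
#' @param cross Cross-connection coefficient: a scalar applied to every
#'   ordered pair, or an `n_channels x n_channels` matrix whose `[i, j]`
#'   entry couples source channel `j` into target channel `i` (diagonal
#'   ignored).
#' @param threshold Gating voltage: a cross-connection is active only when
#'   the source voltage strictly exceeds this value. Use `-Inf` for an
#'   always-open gate (a plain linear VAR).
#' @param lag Fixed integer lag, or the integer support of the lag
#'   distribution when `lag_probs` is supplied. All lags must be >= 1.
#' @param lag_probs `NULL` for a fixed lag, else probabilities over `lag`
#'   (must sum to 1); lags are drawn independently for every connection
#'   and timepoint.
#' @param noise_var Variance of the i.i.d. Gaussian innovation on every
#'   channel (mean 0, uncorrelated across channels and time).
#' @param n_timepoints Timepoints per run (must exceed the largest lag).
#' @param n_runs Default number of runs drawn by [simulate.ar_model()].
#' @param burn_in Initial timepoints discarded from each returned run
#'   (default 0).
#' @param guard Abort threshold: simulation stops with an error if any
#'   absolute voltage exceeds this value (catches unstable
#'   misconfiguration; the default regimes are stable).
#'
#' @return An object of class `"ar_model"`.
#'
#' @seealso [ar_model_nonlinear()], [ar_model_nonmarkovian()],
#'   [ar_model_three_channel()] for the standard parameterisations;
#'   [simulate.ar_model()] to draw runs.
#' @examples
#' m <- ar_model_nonlinear(n_timepoints = 2000, n_runs = 2)
#' runs <- simulate(m, seed = 1)
#' dim(runs[[1]])
#' @export
ar_model <- function(n_channels = 2,
                     self = -0.1,
                     cross = 0.9,
                     threshold = 0.9,
                     lag = 10,
                     lag_probs = NULL,
                     noise_var = 0.5,
                     n_timepoints = 20000,
                     n_runs = 10,
                     burn_in = 0,
                     guard = 1e6) {
  n_channels <- as.integer(n_channels)
  if (!n_channels %in% c(2L, 3L))
    stop("n_channels must be 2 or 3")
  self <- rep_len(as.numeric(self), n_channels)

  if (is.matrix(cross)) {
    if (!all(dim(cross) == n_channels))
      stop("cross matrix must be n_channels x n_channels")
    cross_mat <- cross
  } else {
    cross_mat <- matrix(as.numeric(cross), n_channels, n_channels)
  }
  diag(cross_mat) <- 0

  lag <- as.integer(lag)
  if (any(lag < 1L)) stop("all lags must be >= 1")
  if (!is.null(lag_probs)) {
    if (length(lag_probs) != length(lag))
      stop("lag_probs must match lag in length")
    if (abs(sum(lag_probs) - 1) > 1e-8)
      stop("lag_probs must sum to 1")
    form <- "accumulation"
  } else {
    if (length(lag) != 1L) stop("a fixed-lag model takes a single lag")
    form <- "recurrence"
  }
  if (noise_var < 0) stop("noise_var must be >= 0")
  if (n_timepoints <= max(lag))
    stop("n_timepoints must exceed the largest lag")
  if (burn_in < 0 || burn_in >= n_timepoints)
    stop("burn_in must lie in [0, n_timepoints)")

  structure(
    list(n_channels = n_channels, self = self, cross = cross_mat,
         threshold = threshold, lag = lag, lag_probs = lag_probs,
         form = form, noise_var = noise_var,
         n_timepoints = as.integer(n_timepoints),
         n_runs = as.integer(n_runs),
         burn_in = as.integer(burn_in), guard = guard),
    class = "ar_model")
}

#' Standard model parameterisations
#'
#' Presets for the three study systems: the 2-channel nonlinear model
#' (fixed lag 10, gated cross-coupling 0.9), its non-Markovian extension
#' (lags jittered over 9/10/11 with probabilities 0.25/0.5/0.25), and the
#' 3-channel non-Markovian system (all cross-connections 0.4). All use
#' self-coefficients -0.1 (self-inhibition), gate threshold 0.9, Gaussian
#' noise variance 0.5, and default to 10 runs of 20,000 timepoints.
#'
#' @param n_timepoints,n_runs Override the default simulation size.
#' @param ... Further arguments passed to [ar_model()].
#' @return An `"ar_model"` object.
#' @export
ar_model_nonlinear <- function(n_timepoints = 20000, n_runs = 10, ...) {
  ar_model(n_channels = 2, self = -0.1, cross = 0.9, threshold = 0.9,
           lag = 10, noise_var = 0.5,
           n_timepoints = n_timepoints, n_runs = n_runs, ...)
}

#' @rdname ar_model_nonlinear
#' @export
ar_model_nonmarkovian <- function(n_timepoints = 20000, n_runs = 10, ...) {
  ar_model(n_channels = 2, self = -0.1, cross = 0.9, threshold = 0.9,
           lag = c(9L, 10L, 11L), lag_probs = c(0.25, 0.5, 0.25),
           noise_var = 0.5, n_timepoints = n_timepoints, n_runs = n_runs,
           ...)
}

#' @rdname ar_model_nonlinear
#' @export
ar_model_three_channel <- function(n_timepoints = 20000, n_runs = 10, ...) {
  ar_model(n_channels = 3, self = -0.1, cross = 0.4, threshold = 0.9,
           lag = c(9L, 10L, 11L), lag_probs = c(0.25, 0.5, 0.25),
           noise_var = 0.5, n_timepoints = n_timepoints, n_runs = n_runs,
           ...)
}

#' @export
print.ar_model <- function(x, ...) {
  cat(sprintf("Threshold-gated AR model (%d channels, %s form)\n",
              x$n_channels, x$form))
  cat(sprintf("  self coefficients: %s\n",
              paste(format(x$self), collapse = ", ")))
  off <- x$cross[row(x$cross) != col(x$cross)]
  cat(sprintf("  cross coefficients: %s (gate: source > %g)\n",
              paste(format(unique(off)), collapse = ", "), x$threshold))
  if (is.null(x$lag_probs)) {
    cat(sprintf("  lag: %d (fixed)\n", x$lag))
  } else {
    cat(sprintf("  lags: {%s} with probabilities {%s}\n",
                paste(x$lag, collapse = ", "),
                paste(format(x$lag_probs), collapse = ", ")))
  }
  cat(sprintf("  noise variance: %g; %d timepoints x %d runs\n",
              x$noise_var, x$n_timepoints, x$n_runs))
  invisible(x)
}
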