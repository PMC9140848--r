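#' Simulate runs from a threshold-gated AR model
#'
#' Draws `nsim` independent runs of continuous multichannel voltages from
#' an [ar_model()] configuration. Runs are bit-identical across repeated
#' calls with the same `seed`.
#'
#' @param object An `"ar_model"` object.
#' @param nsim Number of runs (defaults to the model's `n_runs`).
#' @param seed Integer seed for the run ensemble, or `NULL` to continue
#'   from the current RNG state.
#' @param condition Free-text condition label attached to every run
#'   (e.g. `"wake-like"`).
#' @param ... Unused.
#'
#' @return A list of `"mc_series"` objects: numeric matrices of dimension
#'   `channels x timepoints` with attributes `run_id`, `condition` and
#'   `seed_used`.
#'
#' @examples
#' runs <- simulate(ar_model_nonlinear(n_timepoints = 1000, n_runs = 2),
#'                  seed = 42)
#' sapply(runs, function(r) var(r[1, ]))
#' @export
simulate.ar_model <- function(object, nsim = object$n_runs, seed = NULL,
                              condition = "model", ...) {
  if (!is.null(seed)) set.seed(seed)
  lapply(seq_len(nsim), function(run) {
    x <- if (object$form == "recurrence") {
      sim_recurrence(object, run)
    } else {
      sim_accumulation(object, run)
    }
    if (object$burn_in > 0L)
      x <- x[, -seq_len(object$burn_in), drop = FALSE]
    mc_series(x, run_id = run, condition = condition, seed_used = seed)
  })
}

mc_series <- function(values, run_id = 1L, condition = "", seed_used = NULL) {
  stopifnot(is.matrix(values))
  structure(values, run_id = as.integer(run_id), condition = condition,
            seed_used = seed_used, class = c("mc_series", "matrix", "array"))
}

#' @export
print.mc_series <- function(x, ...) {
  cat(sprintf("Multichannel series: %d channels x %d timepoints (run %d%s)\n",
              nrow(x), ncol(x), attr(x, "run_id"),
              if (nzchar(attr(x, "condition")))
                paste0(", ", attr(x, "condition")) else ""))
  invisible(x)
}

check_guard <- function(x, guard, run, t_range) {
  bad <- !is.finite(x) | abs(x) > guard
  if (any(bad)) {
    t_bad <- t_range[which(bad, arr.ind = TRUE)[1, 2]]
    stop(sprintf(
      "simulation blow-up: |value| > %g (or non-finite) in run %d at timepoint %d",
      guard, run, t_bad))
  }
}

# Fixed-lag recurrence: x[, t] depends only on x[, t - l], so timepoints are
# advanced in blocks of l columns at a time (block b reads only block b - 1).
sim_recurrence <- function(m, run) {
  n <- m$n_timepoints
  ch <- m$n_channels
  l <- m$lag
  x <- matrix(rnorm(ch * n, sd = sqrt(m$noise_var)), ch, n)
  t0 <- l + 1L
  while (t0 <= n) {
    idx <- t0:min(t0 + l - 1L, n)
    src <- x[, idx - l, drop = FALSE]
    gated <- src * (src > m$threshold)
    x[, idx] <- x[, idx] + m$self * src + m$cross %*% gated
    check_guard(x[, idx, drop = FALSE], m$guard, run, idx)
    t0 <- t0 + l
  }
  x
}

# Jittered-lag accumulation: every timepoint starts as its noise draw and
# source times are processed in increasing order, so a source value is fully
# accumulated before its gate is tested. Because every lag is >= min(lag),
# chunks of min(lag) source times can be processed vectorised: nothing lands
# inside the chunk currently being read.
sim_accumulation <- function(m, run) {
  n <- m$n_timepoints
  ch <- m$n_channels
  support <- m$lag
  x <- matrix(rnorm(ch * n, sd = sqrt(m$noise_var)), ch, n)
  # lag draw per (target, source, timepoint), independent
  ldraw <- array(
    support[sample.int(length(support), ch * ch * n, replace = TRUE,
                       prob = m$lag_probs)],
    dim = c(ch, ch, n))
  chunk <- min(support)
  t0 <- 1L
  while (t0 <= n) {
    tv <- t0:min(t0 + chunk - 1L, n)
    for (j in seq_len(ch)) {
      src <- x[j, tv]
      open <- src > m$threshold
      for (i in seq_len(ch)) {
        coef <- if (i == j) rep(m$self[i], length(tv))
                else m$cross[i, j] * open
        lv <- ldraw[i, j, tv]
        for (l in support) {
          sel <- which(lv == l & coef != 0 & tv + l <= n)
          if (length(sel))
            x[i, tv[sel] + l] <- x[i, tv[sel] + l] + coef[sel] * src[sel]
        }
      }
    }
    check_guard(x[, tv, drop = FALSE], m$guard, run, tv)
    t0 <- t0 + chunk
  }
  x
}
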