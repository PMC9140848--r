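# Synthetic sweep-level generators with known ground truth, used to
# validate the peak-detection stage (the AR models validate the Phi
# stage; these validate the statistics on top of it).

#' Multilevel data on a known parabola in log2 timescale
#'
#' Generates records `y = beta0 + beta1*x + beta2*x^2 + u_subject +
#' u_subject:pair + e` with `x = log2(tau)`, i.i.d. Gaussian random
#' intercepts and residuals — the generating process assumed by
#' [fit_phi_peak()], for checking coefficient recovery.
#'
#' @param beta Length-3 vector of true coefficients (intercept, linear,
#'   quadratic in `x = log2(tau)`).
#' @param tau_grid Timescales at which records are generated.
#' @param n_subjects,n_pairs Grouping structure (one record per subject,
#'   pair and timescale).
#' @param sd_subject,sd_pair,sd_noise Standard deviations of the subject
#'   intercepts, subject:pair intercepts, and residuals.
#' @param response Name of the generated response column.
#' @return Data frame with `subject`, `pair`, `tau` and the response.
#' @export
simulate_parabola_data <- function(beta = c(0.4, 4.4e-2, -9e-3),
                                   tau_grid = default_tau_grid(),
                                   n_subjects = 13, n_pairs = 5,
                                   sd_subject = 0.3, sd_pair = 0.15,
                                   sd_noise = 0.2,
                                   response = "delta_log_phi") {
  stopifnot(length(beta) == 3)
  g <- expand.grid(subject = seq_len(n_subjects), pair = seq_len(n_pairs),
                   tau = tau_grid)
  u_s <- rnorm(n_subjects, 0, sd_subject)
  u_sp <- matrix(rnorm(n_subjects * n_pairs, 0, sd_pair),
                 n_subjects, n_pairs)
  x <- log2(g$tau)
  g[[response]] <- beta[1] + beta[2] * x + beta[3] * x^2 +
    u_s[g$subject] + u_sp[cbind(g$subject, g$pair)] +
    rnorm(nrow(g), 0, sd_noise)
  g
}

#' Two-condition sweep with a planted multiplicative Phi bump
#'
#' Emulates the wake/anaesthesia design at the sweep level: both
#' conditions share a common log-Phi trend over timescale plus subject
#' and subject:pair intercepts, and the wake-like condition additionally
#' carries a multiplicative \eqn{\Phi} bump centred at `tau_star` — a
#' concave-quadratic excess in `log2(tau)`, so the planted
#' `delta_log_phi` surface lies exactly in the model class fitted by
#' [fit_phi_peak()] and its true turning point is `tau_star`.
#'
#' @param tau_star Timescale (same units as `tau_grid`) at which the
#'   planted wake/anaesthesia \eqn{\Phi} ratio peaks.
#' @param amplitude Height of the planted bump in log units at its apex.
#' @param curvature Absolute quadratic coefficient of the bump in
#'   `log2(tau)` units.
#' @param baseline Function of `x = log2(tau)` giving the condition-
#'   common log-Phi trend (default a gentle downward drift).
#' @param sd_condition_noise Residual noise added independently per
#'   condition record.
#' @inheritParams simulate_parabola_data
#' @return List with `wake` and `anesthesia` sweep data frames (columns
#'   `subject`, `pair`, `method`, `tau`, `log_phi`, `phi`) ready for
#'   [delta_log_phi()].
#' @export
simulate_bump_sweep <- function(tau_grid = default_tau_grid(),
                                tau_star = 10, amplitude = 0.5,
                                curvature = 0.05,
                                n_subjects = 13, n_pairs = 5,
                                sd_subject = 0.3, sd_pair = 0.15,
                                sd_condition_noise = 0.15,
                                baseline = function(x) -1 - 0.05 * x) {
  g <- expand.grid(subject = seq_len(n_subjects), pair = seq_len(n_pairs),
                   tau = tau_grid)
  g$method <- "planted"
  g$run <- 1L
  x <- log2(g$tau)
  u_s <- rnorm(n_subjects, 0, sd_subject)
  u_sp <- matrix(rnorm(n_subjects * n_pairs, 0, sd_pair),
                 n_subjects, n_pairs)
  shared <- baseline(x) + u_s[g$subject] + u_sp[cbind(g$subject, g$pair)]
  bump <- amplitude - curvature * (x - log2(tau_star))^2
  mk <- function(lp) {
    d <- g
    d$log_phi <- lp + rnorm(nrow(g), 0, sd_condition_noise)
    d$phi <- exp(d$log_phi)
    structure(d, tau_grid = sort(unique(g$tau)),
              class = c("tau_sweep", "data.frame"))
  }
  list(wake = mk(shared + bump), anesthesia = mk(shared))
}
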