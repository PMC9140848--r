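#' Turning point of a quadratic trend in log2 timescale
#'
#' For a fitted quadratic `b0 + b1*x + b2*x^2` with `x = log2(tau)`, the
#' vertex lies at `x* = -b1 / (2*b2)` and corresponds to the timescale
#' `2^x*` (in whatever units `tau` carried). The vertex is a local
#' maximum exactly when `b2 < 0`.
#'
#' @param beta1,beta2 Linear and quadratic coefficients.
#' @return List with `x_star` (vertex on the log2 axis), `tau`
#'   (`2^x_star`), and `is_local_max`.
#' @examples
#' turning_point(4.441e-2, -9.18e-3)$tau  # about 5.35
#' @export
turning_point <- function(beta1, beta2) {
  if (beta2 == 0) stop("beta2 must be non-zero for a turning point")
  x_star <- -beta1 / (2 * beta2)
  list(x_star = x_star, tau = 2^x_star, is_local_max = beta2 < 0)
}

#' Test for an intermediate-timescale peak by quadratic mixed-effects fit
#'
#' Fits linear and quadratic mixed models in `x = log2(tau)` by maximum
#' likelihood, with random intercepts for subject and subject:pair (the
#' grouping that absorbs within-subject correlation among channel pairs),
#' and compares them with a likelihood-ratio test (the LR statistic is
#' chi-squared with 1 degree of freedom for these nested fits; ML rather
#' than REML because the models differ in fixed effects). The fitted
#' quadratic indicates a peak at an intermediate timescale when its
#' turning point is a local maximum (`beta2 < 0`) and falls strictly
#' inside the observed timescale range.
#'
#' Records with a missing response are dropped listwise. If a grouping
#' factor has fewer than two levels, or a random-effects fit is singular,
#' the affected random term is dropped (down to a fixed-effects `lm` in
#' the degenerate single-group case) and the simplification is flagged.
#'
#' @param data A `"tau_sweep"` / `"delta_sweep"` data frame, or any data
#'   frame with the needed columns.
#' @param response Response column: `"log_phi"` (default for plain
#'   sweeps), `"delta_log_phi"` (default for delta sweeps), or any
#'   numeric column name.
#' @param xvar Timescale column, `"tau"` (samples) or `"tau_ms"`.
#' @param subject,pair Names of the grouping columns.
#' @return Object of class `"phi_peakfit"`: coefficients `beta0..beta2`,
#'   `chi2`/`df`/`p_value` from the likelihood-ratio test, the turning
#'   point (`turning_tau`, same units as `xvar`, with `is_local_max` and
#'   `is_intermediate`), random-effect variances, flags, and the two
#'   fitted models.
#' @seealso [turning_point()], [tau_sweep()], [delta_log_phi()]
#' @export
fit_phi_peak <- function(data, response = NULL, xvar = c("tau", "tau_ms"),
                         subject = "subject", pair = "pair") {
  xvar <- match.arg(xvar)
  if (is.null(response))
    response <- if ("delta_log_phi" %in% names(data)) "delta_log_phi"
                else "log_phi"
  if (!response %in% names(data)) stop("response column not found: ", response)
  if (!xvar %in% names(data)) stop("timescale column not found: ", xvar)

  d <- as.data.frame(data)
  d <- d[!is.na(d[[response]]) & !is.na(d[[xvar]]), , drop = FALSE]
  n_dropped <- nrow(data) - nrow(d)
  if (length(unique(d[[xvar]])) < 3L)
    stop("need >= 3 distinct timescales for a quadratic fit")
  d$.y <- d[[response]]
  d$.x <- log2(d[[xvar]])
  d$.subject <- factor(if (subject %in% names(d)) d[[subject]] else 1L)
  d$.pair <- factor(if (pair %in% names(d)) d[[pair]] else 1L)
  d$.sp <- interaction(d$.subject, d$.pair, drop = TRUE)

  terms <- character(0)
  if (nlevels(d$.subject) >= 2L) terms <- c(terms, "(1 | .subject)")
  if (nlevels(d$.sp) > nlevels(d$.subject)) terms <- c(terms, "(1 | .sp)")
  flags <- character(0)
  if (length(terms) == 0L)
    flags <- c(flags, "single_group_fixed_effects_only")

  fit_pair <- function(terms) {
    if (length(terms) > 0L) {
      fq <- stats::as.formula(paste(".y ~ .x + I(.x^2) +",
                                    paste(terms, collapse = " + ")))
      fl <- stats::as.formula(paste(".y ~ .x +",
                                    paste(terms, collapse = " + ")))
      ctrl <- lme4::lmerControl(optimizer = "bobyqa")
      list(q = lme4::lmer(fq, data = d, REML = FALSE, control = ctrl),
           l = lme4::lmer(fl, data = d, REML = FALSE, control = ctrl))
    } else {
      list(q = stats::lm(.y ~ .x + I(.x^2), data = d),
           l = stats::lm(.y ~ .x, data = d))
    }
  }
  fits <- fit_pair(terms)
  # a singular random-effects fit: drop the variance-zero term and refit
  while (length(terms) > 0L && lme4::isSingular(fits$q, tol = 1e-6)) {
    vc <- as.data.frame(lme4::VarCorr(fits$q))
    vc <- vc[vc$grp != "Residual", , drop = FALSE]
    drop_grp <- vc$grp[which.min(vc$vcov)]
    drop_term <- if (drop_grp == ".subject") "(1 | .subject)" else "(1 | .sp)"
    terms <- setdiff(terms, drop_term)
    flags <- c(flags, paste0("singular_dropped_", drop_grp))
    fits <- fit_pair(terms)
  }

  beta <- if (length(terms) > 0L) lme4::fixef(fits$q) else stats::coef(fits$q)
  names(beta) <- c("beta0", "beta1", "beta2")
  chi2 <- max(0, 2 * (as.numeric(stats::logLik(fits$q)) -
                        as.numeric(stats::logLik(fits$l))))
  p <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  tp <- if (beta[["beta2"]] != 0)
    turning_point(beta[["beta1"]], beta[["beta2"]])
  else list(x_star = NA_real_, tau = NA_real_, is_local_max = FALSE)
  xr <- range(d[[xvar]])
  re_var <- if (length(terms) > 0L) {
    vc <- as.data.frame(lme4::VarCorr(fits$q))
    stats::setNames(vc$vcov, sub("^\\.sp$", "subject:pair",
                                 sub("^\\.subject$", "subject", vc$grp)))
  } else {
    c(Residual = stats::sigma(fits$q)^2)
  }

  structure(
    list(beta = beta, chi2 = chi2, df = 1L, p_value = p,
         turning_x = tp$x_star, turning_tau = tp$tau,
         is_local_max = tp$is_local_max,
         is_intermediate = !is.na(tp$tau) && tp$tau > xr[1] && tp$tau < xr[2],
         xvar = xvar, x_range = xr, response = response,
         random_effect_variances = re_var,
         n_obs = nrow(d), n_dropped = n_dropped, flags = flags,
         model_quadratic = fits$q, model_linear = fits$l, data = d),
    class = "phi_peakfit")
}

#' @export
print.phi_peakfit <- function(x, ...) {
  unit <- if (x$xvar == "tau_ms") "ms" else "samples"
  cat(sprintf("Quadratic peak fit of %s on log2(%s)\n", x$response, x$xvar))
  cat(sprintf("  beta0 = %.4g, beta1 = %.4g, beta2 = %.4g\n",
              x$beta[1], x$beta[2], x$beta[3]))
  cat(sprintf("  LR test vs linear: chi2(%d) = %.2f, p = %.3g\n",
              x$df, x$chi2, x$p_value))
  cat(sprintf("  turning point: %.3g %s (%s%s)\n", x$turning_tau, unit,
              if (x$is_local_max) "local maximum" else "local minimum",
              if (x$is_intermediate) ", intermediate" else ", at the boundary"))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.phi_peakfit <- function(object, ...) {
  print(object)
  cat("\nRandom-effect variances:\n")
  print(object$random_effect_variances)
  cat("\nQuadratic model:\n")
  print(summary(object$model_quadratic), correlation = FALSE)
  invisible(object)
}

#' @export
coef.phi_peakfit <- function(object, ...) object$beta

#' Predicted population-level response at given timescales
#'
#' Evaluates the fitted fixed-effects quadratic at new timescales
#' (random effects set to zero).
#'
#' @param object A `"phi_peakfit"`.
#' @param newdata Data frame with the fit's timescale column, or a
#'   numeric vector of timescales; defaults to the fitted data.
#' @param ... Unused.
#' @return Numeric vector of predicted responses.
#' @export
predict.phi_peakfit <- function(object, newdata = NULL, ...) {
  tau <- if (is.null(newdata)) 2^object$data$.x
         else if (is.data.frame(newdata)) newdata[[object$xvar]]
         else as.numeric(newdata)
  x <- log2(tau)
  as.numeric(object$beta[1] + object$beta[2] * x + object$beta[3] * x^2)
}

#' @export
plot.phi_peakfit <- function(x, ...) {
  d <- x$data
  taus <- sort(unique(2^d$.x))
  m <- vapply(split(d$.y, d$.x), mean, numeric(1))
  xs <- as.numeric(names(m))
  graphics::plot(xs, m, xlab = sprintf("log2(%s)", x$xvar),
                 ylab = x$response, pch = 19, ...)
  grid_x <- seq(min(xs), max(xs), length.out = 200)
  graphics::lines(grid_x,
                  x$beta[1] + x$beta[2] * grid_x + x$beta[3] * grid_x^2)
  if (x$is_local_max)
    graphics::abline(v = x$turning_x, lty = 2)
  invisible(x)
}
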