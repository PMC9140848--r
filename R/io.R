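# Plain-text readers/writers: CSV for series and sweeps, JSON for TPMs
# and fits. Every writer has a reader that round-trips without loss of
# the analysed content.

#' Write / read a multichannel series as CSV
#'
#' One file per run: rows are timepoints, columns are channels
#' (`ch1, ch2, ...`). A JSON sidecar (`<path>.json`) carries the run
#' metadata (run id, condition, seed) so a read restores the
#' `"mc_series"` attributes.
#'
#' @param series A `channels x timepoints` matrix (e.g. `"mc_series"`).
#' @param path CSV file path.
#' @return `write_series_csv` returns `path` invisibly;
#'   `read_series_csv` returns an `"mc_series"`.
#' @export
write_series_csv <- function(series, path) {
  df <- as.data.frame(t(unclass(series)))
  names(df) <- paste0("ch", seq_len(nrow(series)))
  utils::write.csv(df, path, row.names = FALSE)
  meta <- list(run_id = attr(series, "run_id"),
               condition = attr(series, "condition"),
               seed_used = attr(series, "seed_used"))
  jsonlite::write_json(meta[!vapply(meta, is.null, logical(1))],
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_series_csv
#' @export
read_series_csv <- function(path) {
  x <- t(as.matrix(utils::read.csv(path)))
  meta_path <- paste0(path, ".json")
  meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path)
          else list()
  mc_series(x,
            run_id = if (!is.null(meta$run_id)) meta$run_id else 1L,
            condition = if (!is.null(meta$condition)) meta$condition else "",
            seed_used = meta$seed_used)
}

#' Write / read a state-by-node TPM as JSON
#'
#' Serialises probabilities, observation counts, the imputation flags,
#' timescale, method and the state-index convention.
#'
#' @param tpm An `"sbn_tpm"`.
#' @param path JSON file path.
#' @return `write_tpm_json` returns `path` invisibly; `read_tpm_json`
#'   returns the `"sbn_tpm"`.
#' @export
write_tpm_json <- function(tpm, path) {
  stopifnot(inherits(tpm, "sbn_tpm"))
  jsonlite::write_json(
    list(probabilities = tpm$probabilities, counts = tpm$counts,
         imputed = tpm$imputed, tau = tpm$tau, method = tpm$method,
         n_channels = tpm$n_channels,
         state_index_convention = tpm$state_index_convention),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_tpm_json
#' @export
read_tpm_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(probabilities = matrix(as.numeric(x$probabilities),
                                nrow = 2L^x$n_channels),
         counts = as.integer(x$counts), imputed = as.logical(x$imputed),
         tau = as.integer(x$tau), method = x$method,
         n_channels = as.integer(x$n_channels),
         state_index_convention = x$state_index_convention),
    class = "sbn_tpm")
}

#' Write a Phi result as JSON
#'
#' Per-state \eqn{\Phi} keyed by state label (channel 1 first), state
#' frequencies, the frequency-weighted aggregate and the imputed-row
#' fraction.
#'
#' @param phi A `"phi_result"` from [phi_states()].
#' @param path JSON file path.
#' @return `path`, invisibly.
#' @export
write_phi_json <- function(phi, path) {
  stopifnot(inherits(phi, "phi_result"))
  jsonlite::write_json(
    list(phi_per_state = as.list(phi$phi_per_state),
         state_frequencies = as.list(phi$state_frequencies),
         phi_aggregate = phi$phi_aggregate,
         imputed_row_fraction = phi$imputed_row_fraction,
         tau = phi$tau, method = phi$method),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write / read a timescale sweep as tidy CSV
#'
#' @param sweep A `"tau_sweep"` data frame.
#' @param path CSV file path.
#' @return `write_sweep_csv` returns `path` invisibly; `read_sweep_csv`
#'   returns the `"tau_sweep"`.
#' @export
write_sweep_csv <- function(sweep, path) {
  utils::write.csv(as.data.frame(sweep), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sweep_csv
#' @export
read_sweep_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  cls <- if ("delta_log_phi" %in% names(d))
    c("delta_sweep", "tau_sweep", "data.frame") else c("tau_sweep", "data.frame")
  structure(d, tau_grid = sort(unique(d$tau)), class = cls)
}

#' Write a peak fit as JSON
#'
#' @param fit A `"phi_peakfit"`.
#' @param path JSON file path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "phi_peakfit"))
  jsonlite::write_json(
    list(beta = as.list(fit$beta), chi2 = fit$chi2, df = fit$df,
         p_value = fit$p_value, turning_tau = fit$turning_tau,
         is_local_max = fit$is_local_max,
         is_intermediate = fit$is_intermediate, xvar = fit$xvar,
         response = fit$response,
         random_effect_variances = as.list(fit$random_effect_variances),
         n_obs = fit$n_obs, flags = fit$flags),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
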