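#' Default timescale grid
#'
#' Approximately exponentially spaced integer timescales covering 1 to 512
#' samples. The grid deliberately contains non-powers of two (10, 20, 40,
#' 90, 180, 360, ...) so that dynamics with delays such as 10 samples can
#' be resolved exactly.
#'
#' @return Sorted integer vector of timescales.
#' @export
default_tau_grid <- function() {
  c(1L, 2L, 3L, 4L, 5L, 6L, 8L, 10L, 13L, 16L, 20L, 25L, 32L, 40L, 50L,
    64L, 90L, 128L, 180L, 256L, 360L, 512L)
}

#' Sweep integrated information across timescales
#'
#' For every run, channel set and timescale: binarise, build the TPM by
#' the requested method, and compute the frequency-weighted
#' state-aggregate \eqn{\Phi} ([phi_states()]). Channel subsets are
#' analysed without fixing the state of the remaining channels
#' (partial observation with free background conditions).
#'
#' @param runs A list of `channels x timepoints` matrices (e.g. from
#'   [simulate.ar_model()]), or a single matrix.
#' @param method `"skipping"` or `"downsampling"`.
#' @param tau_grid Sorted integer timescales (>= 2 values for a sweep);
#'   values infeasible for the series length are dropped with a warning.
#' @param channels `NULL` to treat all channels as one system, or a list
#'   of integer vectors, one record per subset (e.g.
#'   `list(c(1, 2), c(1, 3), c(2, 3))` for all pairs of three channels).
#' @param condition Condition label stored with every record; defaults to
#'   the label carried by the first run, if any.
#' @param sampling_rate Optional sampling rate in Hz; adds a `tau_ms`
#'   column (`tau / sampling_rate * 1000`).
#' @param subject Subject identifier for all records (grouping factor in
#'   [fit_phi_peak()]); defaults to 1, with `run` kept as its own column.
#'
#' @return A data frame of class `"tau_sweep"` with columns `subject`,
#'   `run`, `pair`, `condition`, `method`, `tau` (and `tau_ms` when a
#'   sampling rate is given), `phi`, `log_phi` (natural log; `NA` with a
#'   `note` when \eqn{\Phi = 0} since the log is undefined), and
#'   `imputed_fraction` (share of TPM rows never observed).
#' @seealso [phi_curve()], [peak_tau()], [delta_log_phi()],
#'   [fit_phi_peak()]
#' @export
tau_sweep <- function(runs, method = c("skipping", "downsampling"),
                      tau_grid = default_tau_grid(), channels = NULL,
                      condition = NULL, sampling_rate = NULL, subject = 1L) {
  method <- match.arg(method)
  if (is.matrix(runs)) runs <- list(runs)
  if (is.null(condition)) {
    condition <- attr(runs[[1]], "condition")
    if (is.null(condition)) condition <- ""
  }
  tau_grid <- sort(unique(as.integer(tau_grid)))
  n <- ncol(runs[[1]])
  feasible <- if (method == "skipping") tau_grid < n else tau_grid <= n %/% 2L
  if (any(!feasible)) {
    warning(sprintf("dropping %d infeasible tau value(s) for series length %d",
                    sum(!feasible), n))
    tau_grid <- tau_grid[feasible]
  }
  if (length(tau_grid) < 1L) stop("no feasible tau values")
  if (is.null(channels)) channels <- list(seq_len(nrow(runs[[1]])))

  rows <- list()
  for (ri in seq_along(runs)) {
    x <- unclass(runs[[ri]])
    run_id <- attr(runs[[ri]], "run_id")
    if (is.null(run_id)) run_id <- ri
    for (chs in channels) {
      sub <- x[chs, , drop = FALSE]
      pair_label <- paste(chs, collapse = "-")
      bin <- if (method == "skipping") binarize_median(sub) else NULL
      for (tau in tau_grid) {
        phi <- NA_real_
        imputed <- NA_real_
        note <- ""
        res <- tryCatch({
          tpm <- if (method == "skipping") tpm_skipping(bin, tau)
                 else tpm_downsampling(sub, tau)
          phi_states(tpm)
        }, error = function(e) e)
        if (inherits(res, "error")) {
          note <- conditionMessage(res)
        } else {
          phi <- res$phi_aggregate
          imputed <- res$imputed_row_fraction
        }
        rows[[length(rows) + 1L]] <- data.frame(
          subject = subject, run = run_id, pair = pair_label,
          condition = condition, method = method, tau = tau,
          phi = phi,
          log_phi = if (!is.na(phi) && phi > 0) log(phi) else NA_real_,
          imputed_fraction = imputed,
          note = if (!is.na(phi) && phi <= 0 && !nzchar(note))
                   "phi_zero_log_undefined" else note,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  if (!is.null(sampling_rate)) {
    if (sampling_rate <= 0) stop("sampling_rate must be > 0")
    out$tau_ms <- out$tau / sampling_rate * 1000
  }
  structure(out, tau_grid = tau_grid, sampling_rate = sampling_rate,
            class = c("tau_sweep", "data.frame"))
}

#' Run-averaged Phi-versus-timescale curve
#'
#' Averages \eqn{\Phi} over all records (runs, and channel subsets if
#' present) at each timescale.
#'
#' @param sweep A `"tau_sweep"` data frame.
#' @param value Column to average (default `"phi"`).
#' @return Data frame with `tau`, `mean`, `sd`, `n`.
#' @export
phi_curve <- function(sweep, value = "phi") {
  v <- sweep[[value]]
  agg <- split(v, sweep$tau)
  taus <- as.integer(names(agg))
  o <- order(taus)
  data.frame(
    tau = taus[o],
    mean = vapply(agg, mean, numeric(1), na.rm = TRUE)[o],
    sd = vapply(agg, stats::sd, numeric(1), na.rm = TRUE)[o],
    n = vapply(agg, function(z) sum(!is.na(z)), numeric(1))[o],
    row.names = NULL)
}

#' Timescale at which the run-averaged curve peaks
#'
#' @inheritParams phi_curve
#' @return The grid timescale (in samples) maximising the run-averaged
#'   value.
#' @export
peak_tau <- function(sweep, value = "phi") {
  cur <- phi_curve(sweep, value)
  cur$tau[which.max(cur$mean)]
}

#' @export
print.tau_sweep <- function(x, ...) {
  cat(sprintf("Timescale sweep: %d records (%s method), tau in [%d, %d]\n",
              nrow(x), paste(unique(x$method), collapse = "+"),
              min(x$tau), max(x$tau)))
  cat(sprintf("  %d run(s) x %d channel set(s) x %d timescale(s); condition: %s\n",
              length(unique(x$run)), length(unique(x$pair)),
              length(unique(x$tau)),
              paste(unique(x$condition), collapse = ", ")))
  if ("phi" %in% names(x) && any(!is.na(x$phi)))
    cat(sprintf("  run-mean Phi peaks at tau = %d\n", peak_tau(x)))
  invisible(x)
}

#' Condition contrast of log-transformed Phi
#'
#' Matches records of two sweeps (wake-like minus anaesthesia-like) on
#' subject, run, channel pair, method and timescale, and returns the
#' difference of natural-log \eqn{\Phi} — equivalently, the log of the
#' wake/anaesthesia \eqn{\Phi} ratio, which cancels trends common to the
#' two conditions (such as the systematic dependence of empirical TPMs on
#' the number of available transitions). Unmatched records are excluded
#' with a message; records whose log is undefined in either condition
#' propagate `NA`.
#'
#' @param wake,anesthesia `"tau_sweep"` data frames with identical units
#'   and grids.
#' @return A data frame of class `c("delta_sweep", "tau_sweep")` with the
#'   matching identifiers and `delta_log_phi`.
#' @export
delta_log_phi <- function(wake, anesthesia) {
  keys <- intersect(c("subject", "run", "pair", "method", "tau"),
                    intersect(names(wake), names(anesthesia)))
  m <- merge(as.data.frame(wake)[c(keys, "log_phi",
                                   intersect("tau_ms", names(wake)))],
             as.data.frame(anesthesia)[c(keys, "log_phi")],
             by = keys, suffixes = c("_wake", "_anesthesia"))
  dropped <- nrow(wake) - nrow(m)
  if (dropped > 0)
    message(sprintf("delta_log_phi: %d unmatched record(s) excluded", dropped))
  m$delta_log_phi <- m$log_phi_wake - m$log_phi_anesthesia
  o <- do.call(order, unname(as.list(m[keys])))
  m <- m[o, , drop = FALSE]
  rownames(m) <- NULL
  structure(m, tau_grid = sort(unique(m$tau)),
            sampling_rate = attr(wake, "sampling_rate"),
            class = c("delta_sweep", "tau_sweep", "data.frame"))
}
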