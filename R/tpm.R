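#' Empirical state-by-node TPM via the skipping method
#'
#' Tallies, for every system state at time `t`, the probability that each
#' channel is "on" at `t + tau`, using all source times
#' `t = 1, ..., n - tau` of the binarised series (the samples themselves
#' are untouched; the timescale is characterised purely by the skip
#' `tau`). The total number of transitions is exactly `n - tau`.
#'
#' States never observed as a source leave their TPM row undetermined;
#' such rows are filled with the maximum-entropy value 0.5 per node and
#' flagged in `imputed`, so downstream results can report the imputed
#' fraction.
#'
#' @param binary A `"binary_series"` (see [binarize_median()]), or a 0/1
#'   matrix `channels x timepoints`.
#' @param tau Integer timescale in samples, `1 <= tau < n`.
#' @return An object of class `"sbn_tpm"`: list with `probabilities`
#'   (`2^n x n`, little-endian row order: channel 1 is the least
#'   significant bit), `counts` (observations per row), `imputed`
#'   (logical per row), `tau`, `method`, `n_channels`.
#' @examples
#' b <- binarize_median(rbind(c(1, 3, 2, 4, 1, 3), c(4, 1, 3, 2, 4, 1)))
#' tpm_skipping(b, tau = 1)
#' @export
tpm_skipping <- function(binary, tau) {
  states <- if (inherits(binary, "binary_series")) binary$states else binary
  stopifnot(is.matrix(states), all(states %in% c(0L, 1L)))
  n <- ncol(states)
  tau <- as.integer(tau)
  if (tau < 1L || tau >= n) stop("tau must satisfy 1 <= tau < n_timepoints")
  idx <- state_index(states)
  src <- idx[seq_len(n - tau)]
  nxt <- states[, (1L + tau):n, drop = FALSE]
  tally_tpm(src, nxt, tau, "skipping", nrow(states))
}

#' Empirical state-by-node TPM via the downsampling method
#'
#' Coarse-grains the continuous series by averaging voltages in
#' consecutive bins of `tau` samples, for every starting offset
#' `0, ..., tau - 1` (a trailing partial bin is discarded). Each offset's
#' coarse series is binarised against its own per-channel median, and
#' transitions between consecutive coarse steps are tallied; the returned
#' TPM pools the tallies over all offsets, so the transition total is
#' comparable to the skipping method's `n - tau` (each offset `o`
#' contributes `floor((n - o) / tau) - 1` transitions). An offset with
#' fewer than two complete bins contributes nothing.
#'
#' @param series Numeric matrix `channels x timepoints` of continuous
#'   voltages (binarisation happens per offset, after averaging).
#' @param tau Integer bin size in samples, `1 <= tau <= n/2`.
#' @return An `"sbn_tpm"` (see [tpm_skipping()]), with `method =
#'   "downsampling"`.
#' @export
tpm_downsampling <- function(series, tau) {
  x <- unclass(series)
  stopifnot(is.matrix(x))
  n <- ncol(x)
  ch <- nrow(x)
  tau <- as.integer(tau)
  if (tau < 1L || tau > n %/% 2L) stop("tau must satisfy 1 <= tau <= n/2")
  S <- 2L^ch
  counts <- integer(S)
  on_counts <- matrix(0L, S, ch)
  for (o in 0:(tau - 1L)) {
    nb <- (n - o) %/% tau
    if (nb < 2L) next
    seg <- x[, (o + 1L):(o + nb * tau), drop = FALSE]
    coarse <- matrix(0, ch, nb)
    for (j in seq_len(ch))
      coarse[j, ] <- colMeans(matrix(seg[j, ], nrow = tau))
    med <- apply(coarse, 1L, stats::median)
    bin <- matrix(0L, ch, nb)
    bin[coarse > med] <- 1L
    idx <- state_index(bin)
    src <- idx[seq_len(nb - 1L)]
    nxt <- bin[, 2:nb, drop = FALSE]
    counts <- counts + tabulate(src, nbins = S)
    agg <- rowsum(t(nxt), group = src)         # rows sorted by group value
    rows <- as.integer(rownames(agg))
    on_counts[rows, ] <- on_counts[rows, , drop = FALSE] + agg
  }
  finalize_tpm(counts, on_counts, tau, "downsampling", ch)
}

tally_tpm <- function(src, nxt, tau, method, ch) {
  S <- 2L^ch
  counts <- tabulate(src, nbins = S)
  on_counts <- matrix(0L, S, ch)
  agg <- rowsum(t(nxt), group = src)           # rows sorted by group value
  on_counts[as.integer(rownames(agg)), ] <- agg
  finalize_tpm(counts, on_counts, tau, method, ch)
}

finalize_tpm <- function(counts, on_counts, tau, method, ch) {
  S <- 2L^ch
  probs <- matrix(0.5, S, ch)
  seen <- counts > 0L
  probs[seen, ] <- on_counts[seen, , drop = FALSE] / counts[seen]
  structure(
    list(probabilities = probs, counts = counts, imputed = !seen,
         tau = as.integer(tau), method = method, n_channels = ch,
         state_index_convention = "little-endian"),
    class = "sbn_tpm")
}

#' @export
print.sbn_tpm <- function(x, ...) {
  cat(sprintf(
    "State-by-node TPM (%s, tau = %d): %d states x %d channels, %d transitions\n",
    x$method, x$tau, nrow(x$probabilities), x$n_channels, sum(x$counts)))
  if (any(x$imputed))
    cat(sprintf("  %d unobserved row(s) imputed at 0.5\n", sum(x$imputed)))
  rn <- vapply(seq_len(nrow(x$probabilities)), state_label,
               character(1), n = x$n_channels)
  m <- cbind(x$probabilities, count = x$counts)
  rownames(m) <- rn
  colnames(m) <- c(paste0("p(ch", seq_len(x$n_channels), "=1)"), "count")
  print(round(m, 4))
  invisible(x)
}

#' Expand a state-by-node TPM to state-by-state form
#'
#' Under conditional independence of the channels given the current system
#' state, the probability of the full next state factorises over channels:
#' `p(s' | s) = prod_j p_j(s)^{s'_j} (1 - p_j(s))^{1 - s'_j}`. Rows of the
#' result sum to 1.
#'
#' @param tpm An `"sbn_tpm"`.
#' @return An object of class `"sbs_tpm"`: list with `probabilities`
#'   (`2^n x 2^n`) and the metadata of the input.
#' @export
sbn_to_sbs <- function(tpm) {
  stopifnot(inherits(tpm, "sbn_tpm"))
  p <- tpm$probabilities
  S <- nrow(p)
  ch <- tpm$n_channels
  out <- matrix(1, S, S)
  for (s2 in seq_len(S)) {
    bits <- state_bits(s2, ch)
    for (j in seq_len(ch))
      out[, s2] <- out[, s2] * (if (bits[j] == 1L) p[, j] else 1 - p[, j])
  }
  structure(
    list(probabilities = out, counts = tpm$counts, imputed = tpm$imputed,
         tau = tpm$tau, method = tpm$method, n_channels = ch,
         state_index_convention = "little-endian"),
    class = "sbs_tpm")
}

# Marginalise a state-by-state TPM back to state-by-node form:
# p_j(s) = sum_{s'} P(s' | s) s'_j. Exact for conditionally independent
# TPMs (the only kind produced here); the integrated-information engine
# assumes conditional independence, as IIT 3.0 does.
sbs_to_sbn_matrix <- function(P, ch) {
  S <- nrow(P)
  sapply(seq_len(ch), function(j) {
    bit <- vapply(seq_len(S), function(s) state_bits(s, ch)[j], integer(1))
    as.numeric(P %*% bit)
  })
}
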