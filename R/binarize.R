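#' Binarise a multichannel series at each channel's median
#'
#' Each channel is thresholded at its own median within the run: an entry
#' becomes 1 when the voltage strictly exceeds the channel median and 0
#' otherwise (ties go to 0; for continuous data ties have measure zero).
#' A constant channel therefore becomes all-zero and a warning is issued,
#' since its state space is degenerate.
#'
#' @param x Numeric matrix `channels x timepoints` (e.g. an `"mc_series"`).
#' @return An object of class `"binary_series"`: a list with `states`
#'   (0/1 integer matrix, `channels x timepoints`) and `medians` (the
#'   per-channel thresholds used).
#' @examples
#' binarize_median(rbind(c(1, 2, 3, 4)))$states
#' @export
binarize_median <- function(x) {
  if (!is.matrix(x)) stop("x must be a channels x timepoints matrix")
  if (ncol(x) < 2L) stop("need at least 2 timepoints per channel")
  med <- apply(x, 1L, stats::median)
  if (any(apply(x, 1L, function(v) all(v == v[1L]))))
    warning("constant channel: binarised to all zeros (degenerate state space)")
  states <- matrix(0L, nrow(x), ncol(x))
  states[x > med] <- 1L
  structure(list(states = states, medians = med), class = "binary_series")
}

#' @export
print.binary_series <- function(x, ...) {
  cat(sprintf("Binary series: %d channels x %d timepoints; medians: %s\n",
              nrow(x$states), ncol(x$states),
              paste(signif(x$medians, 4), collapse = ", ")))
  invisible(x)
}

# Little-endian system-state index (channel 1 = least significant bit),
# 1-based: state (s1, ..., sn) -> 1 + sum_j s_j 2^(j-1).
state_index <- function(states) {
  1L + as.integer(colSums(states * 2^(seq_len(nrow(states)) - 1L)))
}

# Decode 1-based state index to 0/1 vector of length n (little-endian).
state_bits <- function(index, n) {
  as.integer(bitwAnd(bitwShiftR(index - 1L, seq_len(n) - 1L), 1L))
}

# "01"-style label, channel 1 first.
state_label <- function(index, n) {
  paste(state_bits(index, n), collapse = "")
}
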