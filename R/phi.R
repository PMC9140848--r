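# R-facing surface of the integrated-information engine.

# Accept an sbn_tpm, an sbs_tpm, or a bare matrix (2^n x n state-by-node, or
# 2^n x 2^n state-by-state) and return the state-by-node probability matrix.
as_sbn_matrix <- function(tpm) {
  if (inherits(tpm, "sbn_tpm")) return(tpm$probabilities)
  if (inherits(tpm, "sbs_tpm"))
    return(sbs_to_sbn_matrix(tpm$probabilities, tpm$n_channels))
  if (is.matrix(tpm)) {
    if (nrow(tpm) == ncol(tpm) && nrow(tpm) >= 4L) {
      if (any(abs(rowSums(tpm) - 1) > 1e-9))
        stop("state-by-state TPM rows must sum to 1")
      n <- as.integer(round(log2(nrow(tpm))))
      if (2L^n != nrow(tpm)) stop("state-by-state TPM must have 2^n rows")
      return(sbs_to_sbn_matrix(tpm, n))
    }
    if (nrow(tpm) == 2L^ncol(tpm)) return(tpm)
    stop("matrix is neither 2^n x n (state-by-node) nor 2^n x 2^n")
  }
  stop("tpm must be an sbn_tpm, sbs_tpm, or matrix")
}

tpm_channels <- function(tpm) {
  if (inherits(tpm, c("sbn_tpm", "sbs_tpm"))) return(tpm$n_channels)
  as.integer(round(log2(nrow(as_sbn_matrix(tpm)))))
}

#' Earth mover's distance between binary-state distributions
#'
#' Exact EMD between two probability distributions over the states of a
#' set of binary nodes, with the Hamming distance between states as the
#' ground metric, solved as a transportation problem.
#'
#' @param p,q Numeric probability vectors of equal length `2^k` (state
#'   order little-endian), with equal total mass.
#' @return The EMD (a non-negative scalar).
#' @examples
#' emd_hamming(c(1, 0, 0, 0), c(0, 0, 0, 1))  # move all mass 2 bits
#' @export
emd_hamming <- function(p, q) {
  if (abs(sum(p) - sum(q)) > 1e-9)
    stop("p and q must have equal total mass")
  cpp_emd_hamming(as.numeric(p), as.numeric(q))
}

#' Cause or effect repertoire of a mechanism
#'
#' The cause repertoire is the Bayesian posterior over the purview's past
#' states given the mechanism's current state (uniform prior; non-purview
#' past nodes marginalised uniformly; each mechanism node's constraint is
#' computed independently and the constraints multiplied and renormalised).
#' The effect repertoire is the distribution over the purview's next
#' states given the mechanism's current state, with non-mechanism current
#' nodes marginalised uniformly. An empty mechanism gives the
#' unconstrained repertoire. A conditioning event of probability zero
#' (possible under a deterministic TPM) yields a uniform repertoire with a
#' warning.
#'
#' @param tpm A TPM (`"sbn_tpm"`, `"sbs_tpm"`, or matrix; see
#'   [tpm_skipping()]).
#' @param state 0/1 vector: current state of the full system (channel 1
#'   first).
#' @param mechanism Integer vector of node indices (possibly
#'   `integer(0)` for the empty mechanism).
#' @param purview Non-empty integer vector of node indices.
#' @param direction `"cause"` or `"effect"`.
#' @return Probability vector over purview states (little-endian over the
#'   purview nodes in ascending order).
#' @export
repertoire <- function(tpm, state, mechanism, purview,
                       direction = c("cause", "effect")) {
  direction <- match.arg(direction)
  r <- cpp_repertoire(as_sbn_matrix(tpm), as.integer(state),
                      as.integer(mechanism), as.integer(purview), direction)
  if (attr(r, "zero_conditioning") > 0)
    warning("conditioning event has probability zero; uniform repertoire returned")
  attr(r, "zero_conditioning") <- NULL
  r
}

#' Concept of a mechanism: maximally irreducible cause and effect
#'
#' Searches all purviews and, within each, all admissible partitions of
#' (mechanism, purview) into two parts; the integration of a direction is
#' the maximum over purviews of the minimum over partitions of the earth
#' mover's distance between the whole repertoire and the product of the
#' part repertoires. The mechanism's `small_phi` is the minimum of the
#' cause and effect integration values.
#'
#' @inheritParams repertoire
#' @param mechanism Non-empty integer vector of node indices.
#' @return List with `small_phi`, `phi_cause`, `phi_effect`, the core
#'   `cause_purview` / `effect_purview`, the repertoires at those
#'   purviews, and the minimum-information partitions (`cause_mip`,
#'   `effect_mip`).
#' @export
mechanism_concept <- function(tpm, state, mechanism) {
  if (length(mechanism) == 0L) stop("mechanism must be non-empty")
  out <- cpp_mechanism_concept(as_sbn_matrix(tpm), as.integer(state),
                               as.integer(mechanism))
  if (out$zero_conditioning > 0)
    warning("zero-probability conditioning encountered; uniform repertoire substituted")
  out$zero_conditioning <- NULL
  names(out)[names(out) == "phi"] <- "small_phi"
  out
}

#' System-level integrated information for one state
#'
#' Computes IIT 3.0 \eqn{\Phi}: the constellation of all irreducible
#' concepts is built for the intact system and for every unidirectional
#' bipartition cut (connections from part A into part B noised to maximum
#' entropy); \eqn{\Phi} is the minimum over cuts of the extended earth
#' mover's distance between the intact and cut constellations (concept
#' small-phi is the transported mass; surplus mass pays its distance to
#' the unconstrained null concept).
#'
#' @inheritParams repertoire
#' @param state 0/1 vector: the system state to evaluate.
#' @return An object of class `"system_phi"`: list with `phi`, the
#'   minimal cut (`cut_from` severed into `cut_to`), and the
#'   `constellation` (a data frame of concepts: mechanism, small phi,
#'   core purviews).
#' @examples
#' # two independent maximally noisy nodes integrate nothing
#' tpm <- matrix(0.5, 4, 2)
#' system_phi(tpm, c(0, 0))$phi
#' @export
system_phi <- function(tpm, state) {
  res <- cpp_system_phi(as_sbn_matrix(tpm), as.integer(state))
  if (res$zero_conditioning > 0)
    warning("zero-probability conditioning encountered; uniform repertoire substituted")
  conc <- res$concepts
  constellation <- data.frame(
    mechanism = vapply(conc, function(c)
      paste(c$mechanism, collapse = ","), character(1)),
    small_phi = vapply(conc, function(c) c$phi, numeric(1)),
    phi_cause = vapply(conc, function(c) c$phi_cause, numeric(1)),
    phi_effect = vapply(conc, function(c) c$phi_effect, numeric(1)),
    cause_purview = vapply(conc, function(c)
      paste(c$cause_purview, collapse = ","), character(1)),
    effect_purview = vapply(conc, function(c)
      paste(c$effect_purview, collapse = ","), character(1)),
    stringsAsFactors = FALSE)
  structure(list(phi = res$phi, cut_from = res$cut_from,
                 cut_to = res$cut_to, state = as.integer(state),
                 constellation = constellation, concepts = conc),
            class = "system_phi")
}

#' @export
print.system_phi <- function(x, ...) {
  cat(sprintf("System Phi = %.6g at state %s\n", x$phi,
              paste(x$state, collapse = "")))
  cat(sprintf("  minimal cut: {%s} -> {%s}\n",
              paste(x$cut_from, collapse = ","),
              paste(x$cut_to, collapse = ",")))
  cat(sprintf("  %d concept(s), sum of small phi = %.6g\n",
              nrow(x$constellation), sum(x$constellation$small_phi)))
  invisible(x)
}

#' Integrated information over the observed states of a TPM
#'
#' Computes \eqn{\Phi} for every system state observed as a transition
#' source (rows of the TPM with non-zero counts) and aggregates them by
#' the empirical source-state frequencies. The fraction of TPM rows that
#' had to be filled at maximum entropy (never observed) is reported so
#' downstream analyses can judge estimate quality.
#'
#' @param tpm An `"sbn_tpm"` with observation counts (from
#'   [tpm_skipping()] or [tpm_downsampling()]), or any TPM accepted by
#'   [system_phi()] (then all states are evaluated with equal weights).
#' @return An object of class `"phi_result"`: list with `phi_per_state`
#'   (named by state label, channel 1 first), `state_frequencies`,
#'   `phi_aggregate` (frequency-weighted mean), `minimal_cuts`,
#'   `imputed_row_fraction`, and the TPM's `tau`/`method` metadata.
#' @export
phi_states <- function(tpm) {
  mat <- as_sbn_matrix(tpm)
  ch <- tpm_channels(tpm)
  S <- 2L^ch
  if (inherits(tpm, c("sbn_tpm", "sbs_tpm")) && !is.null(tpm$counts)) {
    counts <- tpm$counts
    observed <- which(counts > 0L)
    freqs <- counts[observed] / sum(counts)
    imputed_frac <- mean(tpm$imputed)
  } else {
    observed <- seq_len(S)
    freqs <- rep(1 / S, S)
    imputed_frac <- 0
  }
  res <- cpp_phi_states(mat, as.integer(observed - 1L))
  labels <- vapply(observed, state_label, character(1), n = ch)
  phi <- res$phi
  names(phi) <- labels
  names(freqs) <- labels
  structure(
    list(phi_per_state = phi,
         state_frequencies = freqs,
         phi_aggregate = sum(freqs * phi),
         minimal_cuts = stats::setNames(res$cuts, labels),
         n_concepts = stats::setNames(res$n_concepts, labels),
         imputed_row_fraction = imputed_frac,
         tau = if (inherits(tpm, c("sbn_tpm", "sbs_tpm"))) tpm$tau else NA_integer_,
         method = if (inherits(tpm, c("sbn_tpm", "sbs_tpm"))) tpm$method else NA_character_),
    class = "phi_result")
}

#' @export
print.phi_result <- function(x, ...) {
  cat(sprintf("Phi over %d observed state(s)%s\n", length(x$phi_per_state),
              if (!is.na(x$tau))
                sprintf(" (%s, tau = %d)", x$method, x$tau) else ""))
  df <- data.frame(state = names(x$phi_per_state),
                   frequency = round(x$state_frequencies, 4),
                   phi = round(x$phi_per_state, 6), row.names = NULL)
  print(df)
  cat(sprintf("Frequency-weighted Phi = %.6g", x$phi_aggregate))
  if (x$imputed_row_fraction > 0)
    cat(sprintf("  [%.0f%% of TPM rows imputed]",
                100 * x$imputed_row_fraction))
  cat("\n")
  invisible(x)
}
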