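# Independent brute-force reference implementation of IIT 3.0 for small
# binary systems, used only as a test oracle against the package engine.
# Deliberately different construction: single-node cause constraints via
# explicit Bayes tables over full past states (marginalised afterwards),
# repertoire products assembled over node identities, and every earth
# mover's distance solved as an explicit linear program (boot::simplex) --
# no pruning, no caching, no analytic shortcuts.

orc_bit <- function(s, node) bitwAnd(bitwShiftR(s, node - 1L), 1L)

# index (0-based) of full state s within the space of `nodes` (ascending)
orc_subindex <- function(s, nodes) {
  if (length(nodes) == 0L) return(0L)
  sum(vapply(seq_along(nodes), function(k)
    bitwShiftL(orc_bit(s, nodes[k]), k - 1L), integer(1)))
}

orc_hamming <- function(a, b) {
  x <- bitwXor(a, b)
  bits <- 0L
  while (x > 0L) { bits <- bits + bitwAnd(x, 1L); x <- bitwShiftR(x, 1L) }
  bits
}

# exact transportation LP: min sum c_ij x_ij, row sums = supply, col sums
# = demand, x >= 0
orc_transport <- function(supply, demand, cost) {
  m <- length(supply); n <- length(demand)
  nv <- m * n
  A3 <- matrix(0, m + n, nv)
  for (i in seq_len(m)) A3[i, ((i - 1L) * n + 1L):(i * n)] <- 1
  for (j in seq_len(n)) A3[m + j, seq(j, nv, by = n)] <- 1
  b3 <- c(supply, demand)
  keep <- seq_len(m + n - 1L)  # last constraint redundant (totals equal)
  res <- boot::simplex(a = as.vector(t(cost)), A3 = A3[keep, , drop = FALSE],
                       b3 = b3[keep], maxi = FALSE)
  unname(res$value)
}

orc_emd <- function(p, q) {
  S <- length(p)
  if (sum(abs(p - q)) < 1e-14) return(0)
  cost <- outer(0:(S - 1L), 0:(S - 1L),
                Vectorize(function(a, b) orc_hamming(a, b)))
  orc_transport(p, q, cost)
}

orc_cause_rep <- function(tpm, state_bits, mech, purview) {
  n <- ncol(tpm); S <- 2L^n
  PS <- 2L^length(purview)
  if (length(mech) == 0L) return(rep(1 / PS, PS))
  pidx <- vapply(0:(S - 1L), orc_subindex, integer(1), nodes = purview)
  joint <- rep(1, PS)
  for (i in mech) {
    lik <- if (state_bits[i] == 1L) tpm[, i] else 1 - tpm[, i]
    if (sum(lik) < 1e-15) {
      marg <- rep(1 / PS, PS)
    } else {
      post <- lik / sum(lik)               # Bayes with uniform prior
      marg <- vapply(0:(PS - 1L), function(u) sum(post[pidx == u]),
                     numeric(1))
    }
    joint <- joint * marg
  }
  if (sum(joint) < 1e-15) rep(1 / PS, PS) else joint / sum(joint)
}

orc_effect_rep <- function(tpm, state_bits, mech, purview) {
  n <- ncol(tpm); S <- 2L^n
  PS <- 2L^length(purview)
  if (length(purview) == 0L) return(1)
  sel <- vapply(0:(S - 1L), function(s)
    all(vapply(mech, function(i) orc_bit(s, i) == state_bits[i],
               logical(1))), logical(1))
  q <- colMeans(tpm[sel, , drop = FALSE])
  vapply(0:(PS - 1L), function(u) {
    prod(vapply(seq_along(purview), function(k) {
      if (bitwAnd(bitwShiftR(u, k - 1L), 1L) == 1L) q[purview[k]]
      else 1 - q[purview[k]]
    }, numeric(1)))
  }, numeric(1))
}

orc_rep <- function(tpm, state_bits, mech, purview, direction) {
  if (direction == "cause") orc_cause_rep(tpm, state_bits, mech, purview)
  else orc_effect_rep(tpm, state_bits, mech, purview)
}

# product of part repertoires assembled over node identities
orc_combine <- function(r1, P1, r2, P2, purview) {
  PS <- 2L^length(purview)
  vapply(0:(PS - 1L), function(u) {
    full <- sum(vapply(seq_along(purview), function(k)
      bitwShiftL(bitwAnd(bitwShiftR(u, k - 1L), 1L), purview[k] - 1L),
      integer(1)))
    v <- 1
    if (length(P1) > 0L) v <- v * r1[orc_subindex(full, P1) + 1L]
    if (length(P2) > 0L) v <- v * r2[orc_subindex(full, P2) + 1L]
    v
  }, numeric(1))
}

orc_subsets <- function(v) {
  out <- list()
  for (m in 0:(2L^length(v) - 1L))
    out[[m + 1L]] <- v[bitwAnd(bitwShiftR(m, seq_along(v) - 1L), 1L) == 1L]
  out
}

orc_phi_mip <- function(tpm, state_bits, mech, purview, direction) {
  whole <- orc_rep(tpm, state_bits, mech, purview, direction)
  best <- Inf
  for (M1 in orc_subsets(mech)) {
    M2 <- setdiff(mech, M1)
    for (P1 in orc_subsets(purview)) {
      P2 <- setdiff(purview, P1)
      if ((length(M1) == 0L && length(P1) == 0L) ||
          (length(M2) == 0L && length(P2) == 0L)) next
      r1 <- orc_rep(tpm, state_bits, M1, P1, direction)
      r2 <- orc_rep(tpm, state_bits, M2, P2, direction)
      part <- orc_combine(r1, P1, r2, P2, purview)
      best <- min(best, orc_emd(whole, part))
    }
  }
  best
}

# all non-empty subsets of 1:n ordered by (size, mask) -- the package's
# fixed purview/mechanism enumeration order, so tie-breaks agree
orc_ordered_subsets <- function(n) {
  subs <- Filter(length, orc_subsets(seq_len(n)))
  masks <- vapply(subs, function(s) sum(2L^(s - 1L)), numeric(1))
  subs[order(lengths(subs), masks)]
}

orc_mice <- function(tpm, state_bits, mech, direction) {
  n <- ncol(tpm)
  best <- list(phi = -1)
  for (P in orc_ordered_subsets(n)) {
    phi <- orc_phi_mip(tpm, state_bits, mech, P, direction)
    if (phi > best$phi + 1e-13)
      best <- list(phi = phi, purview = P,
                   rep = orc_rep(tpm, state_bits, mech, P, direction))
  }
  best
}

orc_expand_cause <- function(rep, purview, n) {
  S <- 2L^n
  vapply(0:(S - 1L), function(s)
    rep[orc_subindex(s, purview) + 1L] / 2^(n - length(purview)),
    numeric(1))
}

orc_expand_effect <- function(rep, purview, n, tpm) {
  S <- 2L^n
  uq <- colMeans(tpm)
  rest <- setdiff(seq_len(n), purview)
  vapply(0:(S - 1L), function(s) {
    v <- rep[orc_subindex(s, purview) + 1L]
    for (j in rest) v <- v * (if (orc_bit(s, j) == 1L) uq[j] else 1 - uq[j])
    v
  }, numeric(1))
}

orc_concept <- function(tpm, state_bits, mech) {
  n <- ncol(tpm)
  cause <- orc_mice(tpm, state_bits, mech, "cause")
  effect <- orc_mice(tpm, state_bits, mech, "effect")
  list(mech = mech, phi = min(cause$phi, effect$phi),
       phi_cause = cause$phi, phi_effect = effect$phi,
       cause_purview = cause$purview, effect_purview = effect$purview,
       cause_full = orc_expand_cause(cause$rep, cause$purview, n),
       eff_full = orc_expand_effect(effect$rep, effect$purview, n, tpm))
}

orc_constellation <- function(tpm, state_bits) {
  Filter(function(c) c$phi > 1e-10,
         lapply(orc_ordered_subsets(ncol(tpm)),
                function(m) orc_concept(tpm, state_bits, m)))
}

orc_null_concept <- function(tpm) {
  n <- ncol(tpm); S <- 2L^n
  list(cause_full = rep(1 / S, S),
       eff_full = orc_expand_effect(1, integer(0), n, tpm))
}

orc_concept_dist <- function(a, b) {
  orc_emd(a$cause_full, b$cause_full) + orc_emd(a$eff_full, b$eff_full)
}

orc_ces_dist <- function(C1, C2, null_c) {
  phi1 <- vapply(C1, `[[`, numeric(1), "phi")
  phi2 <- vapply(C2, `[[`, numeric(1), "phi")
  if (sum(phi1) + sum(phi2) < 1e-15) return(0)
  supply <- c(phi1, sum(phi2))
  demand <- c(phi2, sum(phi1))
  n1 <- length(C1); n2 <- length(C2)
  cost <- matrix(0, n1 + 1L, n2 + 1L)
  for (i in seq_len(n1)) {
    for (j in seq_len(n2)) cost[i, j] <- orc_concept_dist(C1[[i]], C2[[j]])
    cost[i, n2 + 1L] <- orc_concept_dist(C1[[i]], null_c)
  }
  for (j in seq_len(n2)) cost[n1 + 1L, j] <- orc_concept_dist(null_c, C2[[j]])
  orc_transport(supply, demand, cost)
}

# unidirectional cut A -> B: inputs from A into B-nodes are averaged out
orc_cut_tpm <- function(tpm, A) {
  n <- ncol(tpm); S <- 2L^n
  B <- setdiff(seq_len(n), A)
  keep <- setdiff(seq_len(n), A)          # conditioning bits kept for B-nodes
  T2 <- tpm
  for (j in B) {
    for (s in 0:(S - 1L)) {
      same <- vapply(0:(S - 1L), function(s2)
        orc_subindex(s2, keep) == orc_subindex(s, keep), logical(1))
      T2[s + 1L, j] <- mean(tpm[same, j])
    }
  }
  T2
}

orc_big_phi <- function(tpm, state_bits) {
  n <- ncol(tpm)
  C <- orc_constellation(tpm, state_bits)
  if (length(C) == 0L) return(list(phi = 0, constellation = C))
  null_c <- orc_null_concept(tpm)
  best <- Inf
  for (Amask in 1:(2L^n - 2L)) {
    A <- which(bitwAnd(bitwShiftR(Amask, seq_len(n) - 1L), 1L) == 1L)
    C2 <- orc_constellation(orc_cut_tpm(tpm, A), state_bits)
    best <- min(best, orc_ces_dist(C, C2, null_c))
  }
  list(phi = max(best, 0), constellation = C)
}
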