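# Median binarisation and empirical TPM construction.

test_that("median binarisation follows the strict-majority rule", {
  b <- binarize_median(rbind(c(1, 2, 3, 4)))
  expect_equal(as.vector(b$states), c(0L, 0L, 1L, 1L))
  expect_equal(b$medians, 2.5)
  expect_warning(bc <- binarize_median(rbind(c(5, 5, 5, 5), c(1, 2, 3, 4))),
                 "constant")
  expect_equal(as.vector(bc$states[1, ]), rep(0L, 4))
})

test_that("continuous even-length channels split exactly in half", {
  set.seed(2)
  for (rep in 1:20) {
    n <- 2L * sample(5:200, 1)
    x <- matrix(rnorm(2 * n), 2, n)
    b <- binarize_median(x)
    expect_equal(rowSums(b$states), c(n / 2, n / 2))
  }
})

test_that("skipping TPM equals hand-counted transition frequencies", {
  states <- rbind(X = c(0L, 1L, 0L, 1L, 0L, 1L),
                  Y = c(0L, 0L, 1L, 1L, 0L, 0L))
  tpm <- tpm_skipping(states, tau = 1)
  # independent tally: enumerate the 5 (state, next-node) pairs directly
  counts <- integer(4); on1 <- numeric(4); on2 <- numeric(4)
  for (t in 1:5) {
    s <- 1 + states[1, t] + 2 * states[2, t]
    counts[s] <- counts[s] + 1
    on1[s] <- on1[s] + states[1, t + 1]
    on2[s] <- on2[s] + states[2, t + 1]
  }
  seen <- counts > 0
  expect_equal(tpm$counts, counts)
  expect_equal(tpm$probabilities[seen, 1], on1[seen] / counts[seen])
  expect_equal(tpm$probabilities[seen, 2], on2[seen] / counts[seen])
  expect_equal(sum(tpm$counts), 5L)
})

test_that("a single-state series yields one observed row and imputed rest", {
  states <- matrix(0L, 2, 50)
  tpm <- expect_warning(tpm_skipping(states, tau = 3), NA)
  expect_equal(tpm$probabilities[1, ], c(0, 0))
  expect_true(all(tpm$probabilities[2:4, ] == 0.5))
  expect_equal(tpm$imputed, c(FALSE, TRUE, TRUE, TRUE))
  expect_equal(sum(tpm$counts), 50L - 3L)
})

test_that("skipping transition totals are n - tau for every tau", {
  set.seed(3)
  states <- matrix(as.integer(runif(2 * 400) > 0.5), 2, 400)
  for (tau in c(1L, 2L, 7L, 99L, 399L))
    expect_equal(sum(tpm_skipping(states, tau)$counts), 400L - tau)
  expect_error(tpm_skipping(states, 400), "tau")
})

test_that("downsampling bin means match manual averaging over offsets", {
  x <- rbind(c(1, 2, 4, 8, 16, 32, 64, 128),
             c(8, 7, 6, 5, 4, 3, 2, 1))
  # offset 0: bins (1,2)(4,8)(16,32)(64,128) -> 4 coarse samples
  # offset 1: bins (2,4)(8,16)(32,64)       -> 3 coarse samples
  tpm <- tpm_downsampling(x, tau = 2)
  expect_equal(sum(tpm$counts), (4L - 1L) + (3L - 1L))
  # reproduce the pooled tally by hand
  man_counts <- integer(4)
  for (off in 0:1) {
    nb <- (8 - off) %/% 2
    co <- sapply(seq_len(nb), function(k)
      rowMeans(x[, (off + 2 * k - 1):(off + 2 * k)]))
    bin <- (co > apply(co, 1, median)) * 1L
    idx <- 1 + bin[1, ] + 2 * bin[2, ]
    for (t in seq_len(nb - 1)) man_counts[idx[t]] <- man_counts[idx[t]] + 1L
  }
  expect_equal(tpm$counts, man_counts)
})

test_that("downsampling at tau = 1 coincides with skipping at tau = 1", {
  set.seed(4)
  x <- matrix(rnorm(2 * 300), 2, 300)
  a <- tpm_downsampling(x, 1)
  b <- tpm_skipping(binarize_median(x), 1)
  expect_equal(a$probabilities, b$probabilities)
  expect_equal(a$counts, b$counts)
})

test_that("downsampling pooled transition count lies in [n - 2 tau, n - tau]", {
  set.seed(5)
  x <- matrix(rnorm(2 * 1000), 2, 1000)
  for (tau in c(1L, 3L, 7L, 16L, 50L, 137L, 500L)) {
    tot <- sum(tpm_downsampling(x, tau)$counts)
    expect_gte(tot, 1000L - 2L * tau)
    expect_lte(tot, 1000L - tau)
    # exact per-offset bookkeeping
    expect_equal(tot, sum(sapply(0:(tau - 1), function(o)
      max((1000L - o) %/% tau - 1L, 0L))))
  }
})

test_that("reversing channel order permutes TPM rows and columns consistently", {
  set.seed(6)
  x <- matrix(rnorm(3 * 500), 3, 500)
  b <- binarize_median(x)
  tpm <- tpm_skipping(b, tau = 4)
  tpm_rev <- tpm_skipping(b$states[3:1, ], tau = 4)
  # row for state (s1,s2,s3) maps to the row for (s3,s2,s1)
  perm <- sapply(0:7, function(s) {
    bits <- as.integer(intToBits(s))[1:3]
    1 + sum(rev(bits) * 2^(0:2))
  })
  expect_equal(tpm_rev$probabilities[perm, 3:1, drop = FALSE],
               tpm$probabilities, ignore_attr = TRUE)
  expect_equal(tpm_rev$counts[perm], tpm$counts)
})

test_that("state-by-state expansion is the product over per-node probabilities", {
  set.seed(7)
  p <- matrix(runif(8), 4, 2)
  tpm <- structure(list(probabilities = p, counts = rep(1L, 4),
                        imputed = rep(FALSE, 4), tau = 1L,
                        method = "skipping", n_channels = 2L,
                        state_index_convention = "little-endian"),
                   class = "sbn_tpm")
  sbs <- sbn_to_sbs(tpm)
  expect_equal(rowSums(sbs$probabilities), rep(1, 4))
  for (s in 1:4) {
    pr <- p[s, ]
    # state order 00, 10, 01, 11 (channel 1 least significant)
    expect_equal(sbs$probabilities[s, ],
                 c((1 - pr[1]) * (1 - pr[2]), pr[1] * (1 - pr[2]),
                   (1 - pr[1]) * pr[2], pr[1] * pr[2]))
  }
  # deterministic row selects one state; maximum-entropy row is uniform
  mk <- function(row)
    structure(list(probabilities = matrix(row, 4, 2, byrow = TRUE),
                   counts = rep(1L, 4), imputed = rep(FALSE, 4), tau = 1L,
                   method = "skipping", n_channels = 2L,
                   state_index_convention = "little-endian"),
              class = "sbn_tpm")
  expect_equal(sbn_to_sbs(mk(c(1, 0)))$probabilities[1, ], c(0, 1, 0, 0))
  expect_equal(sbn_to_sbs(mk(c(0.5, 0.5)))$probabilities[1, ], rep(0.25, 4))
})
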