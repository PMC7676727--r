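test_that("interval rules assign the documented behavioral types", {
  # TFT-like: high p(C|CC), unresolved difference vs DC, clear vs CD and DD
  expect_equal(classify_from_intervals(pcc = c(0.7, 0.9), d_dc = c(-0.2, 0.1),
                                       d_cd = c(0.3, 0.6), d_dd = c(0.4, 0.7)),
               1L)
  # non-cooperative: p(C|CC) interval not above 0.5, any differences
  expect_equal(classify_from_intervals(pcc = c(0.2, 0.45), d_dc = c(0.5, 0.9),
                                       d_cd = c(0.5, 0.9), d_dd = c(0.5, 0.9)),
               4L)
  # WSLS-like: clear differences vs DC and CD, DD unconstrained
  expect_equal(classify_from_intervals(pcc = c(0.6, 0.8), d_dc = c(0.1, 0.3),
                                       d_cd = c(0.1, 0.4), d_dd = c(-0.5, 0.5)),
               2L)
  # remaining patterns fall through to type 3
  expect_equal(classify_from_intervals(pcc = c(0.6, 0.8), d_dc = c(-0.1, 0.3),
                                       d_cd = c(-0.1, 0.4), d_dd = c(0.1, 0.3)),
               3L)
})

test_that("boundary intervals count as not-greater", {
  # lower bound exactly at the cutoff resolves to 'not greater'
  expect_equal(classify_from_intervals(pcc = c(0.5, 0.9), d_dc = c(0.1, 0.3),
                                       d_cd = c(0.1, 0.3), d_dd = c(0.1, 0.3)),
               4L)
  expect_equal(classify_from_intervals(pcc = c(0.6, 0.9), d_dc = c(0, 0.3),
                                       d_cd = c(0.1, 0.3), d_dd = c(0.1, 0.3)),
               1L)
})

test_that("every interval configuration maps to exactly one type", {
  set.seed(60)
  for (i in 1:500) {
    pcc <- sort(runif(2))
    mk <- function() sort(runif(2, -1, 1))
    type <- classify_from_intervals(pcc, mk(), mk(), mk())
    expect_true(type %in% 1:4)
  }
})

test_that("classify_types agrees with the interval rule applied by hand", {
  tab <- simulate_direct(game_config("direct", n_participants = 8, seed = 61),
                         build_population(8))
  fit <- fit_quick("OPA", tab, seed = 62)
  ind <- individual_probs(fit)
  a <- classify_types(ind)
  expect_equal(nrow(a), 8)
  expect_true(all(a$type %in% 1:4))
  for (k in seq_len(8)) {
    expect_equal(a$type[k],
                 classify_from_intervals(c(a$pcc_lo[k], a$pcc_hi[k]),
                                         c(a$d_dc_lo[k], a$d_dc_hi[k]),
                                         c(a$d_cd_lo[k], a$d_cd_hi[k]),
                                         c(a$d_dd_lo[k], a$d_dd_hi[k])))
  }
  expect_error(classify_types(individual_probs(fit_quick("PA", tab, seed = 63,
                                                         iter = 600,
                                                         warmup = 300))),
               "CC, DC, CD, DD")
})

test_that("type counts cross-tabulate games with fixed row sums", {
  a1 <- structure(data.frame(participant_id = 1:6, type = c(1, 1, 2, 3, 4, 4)),
                  class = c("type_assignment", "data.frame"))
  a2 <- structure(data.frame(participant_id = 1:6, type = c(4, 4, 4, 4, 1, 3)),
                  class = c("type_assignment", "data.frame"))
  tc <- type_counts(direct = a1, generalized = a2)
  expect_equal(unname(rowSums(tc)), c(6, 6))
  expect_equal(unname(tc["direct", ]), c(2, 1, 1, 2))
  expect_equal(unname(tc["generalized", ]), c(1, 0, 1, 4))
  expect_equal(unname(attr(tc, "proportions")["generalized", 4]), 4 / 6)
  expect_error(type_counts(a1, a2), "named")
})

test_that("the exact contingency test matches hypergeometric hand values", {
  # perfect independence
  even <- matrix(10, nrow = 2, ncol = 4)
  expect_equal(exact_type_test(even), 1)
  # 2x2 diagonal table: only the two extreme tables are as or more extreme,
  # each with probability 1/choose(10,5)
  diag2 <- matrix(c(5, 0, 0, 5), 2, 2)
  expect_equal(exact_type_test(diag2), 2 / choose(10, 5))
})

test_that("the exact test agrees with a Monte-Carlo margin-conditional oracle", {
  counts <- matrix(c(8, 4, 15, 13, 8, 1, 4, 27), nrow = 2, byrow = TRUE)
  p_exact <- exact_type_test(counts)
  # sample tables with the observed margins (Patefield algorithm) and use
  # the probability-ordering criterion
  log_prob <- function(m) {
    sum(lgamma(rowSums(m) + 1)) + sum(lgamma(colSums(m) + 1)) -
      lgamma(sum(m) + 1) - sum(lgamma(m + 1))
  }
  set.seed(64)
  Nmc <- 20000
  sims <- r2dtable(Nmc, rowSums(counts), colSums(counts))
  lp_obs <- log_prob(counts)
  hits <- vapply(sims, function(m) log_prob(m) <= lp_obs + 1e-7, logical(1))
  p_mc <- mean(hits)
  se <- sqrt(p_mc * (1 - p_mc) / Nmc)
  expect_lt(abs(p_exact - p_mc), 3 * se)
})

test_that("degenerate contingency input is handled explicitly", {
  expect_error(exact_type_test(matrix(c(-1, 2, 3, 4), 2)), "nonnegative")
  expect_error(exact_type_test(matrix(c(0, 0, 3, 4), nrow = 2, byrow = TRUE)),
               "margin")
  # all observations in one type column: no evidence against independence
  expect_equal(exact_type_test(matrix(c(0, 0, 3, 4), nrow = 2)), 1)
  # empty type columns are dropped rather than breaking the test
  with_zero <- matrix(c(5, 3, 0, 0, 2, 6), nrow = 2)
  expect_equal(exact_type_test(with_zero),
               fisher.test(matrix(c(5, 3, 2, 6), nrow = 2))$p.value)
})
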