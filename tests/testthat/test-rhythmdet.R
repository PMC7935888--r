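test_that("reference waveforms cover the period window and de-duplicate", {
  tp <- seq(0, 21, by = 3)

  # single 24 h period: 8 phase-shifted references, all distinct
  r24 <- reference_waveforms(tp, c(24, 24))
  expect_equal(r24$n_distinct, 8)
  expect_equal(nrow(unique(r24$ranks)), 8)

  # default window tests periods 12, 15, 18, 21, 24
  r <- reference_waveforms(tp, c(12, 24))
  expect_equal(sort(unique(r$params$period)), c(12, 15, 18, 21, 24))

  # a phase equal to the period aliases phase 0 (periodicity)
  v0 <- round(cos(2 * pi * (tp - 0) / 24), 9)
  v24 <- round(cos(2 * pi * (tp - 24) / 24), 9)
  expect_identical(rank(v0), rank(v24))
  # and duplicated rank vectors are removed across the grid
  expect_lte(r$n_distinct, nrow(r$params))
  expect_equal(r$n_distinct, nrow(unique(r$ranks)))

  # window outside [2 * delta, span + delta] is rejected
  expect_error(reference_waveforms(tp, c(4, 8)), "window")
  expect_error(reference_waveforms(tp, c(12, 48)), "window")
})

test_that("exact Kendall null matches brute-force enumeration (n <= 6)", {
  cases <- list(
    c(1, 2, 3),             # n=3 untied
    c(1, 2, 3, 4),          # n=4 untied
    c(1, 1, 2, 2, 3),       # n=5 tie pattern (2,2,1)
    c(1, 1, 1, 2, 2, 3),    # n=6 tie pattern (3,2,1)
    c(1, 2, 2, 3, 4, 4)     # n=6 tie pattern (1,2,1,2)
  )
  for (ref in cases) {
    exact <- kendall_exact_null(ref, as_ranks = TRUE)
    bf <- brute_force_kendall_null(ref)
    # total variation distance over the union support
    pe <- setNames(exact$prob, exact$S)
    pb <- setNames(bf$prob, bf$S)
    supp <- union(names(pe), names(pb))
    tv <- sum(abs(ifelse(is.na(pe[supp]), 0, pe[supp]) -
                    ifelse(is.na(pb[supp]), 0, pb[supp]))) / 2
    expect_lt(tv, 1e-12)
    # symmetry about 0 and unit mass
    expect_equal(sum(exact$prob), 1, tolerance = 1e-12)
    expect_equal(exact$prob, rev(exact$prob), tolerance = 1e-12)
  }
  # frozen spot values: n=3 untied mass pattern, n=4 mass at S=6
  d3 <- kendall_exact_null(c(1, 1, 1))
  expect_equal(d3$prob, c(1, 2, 2, 1) / 6)
  d4 <- kendall_exact_null(c(1, 1, 1, 1))
  expect_equal(d4$prob[d4$S == 6], 1 / 24)
})

test_that("rhythm test recovers planted cosines and rejects constants", {
  tp <- seq(0, 69, by = 3)
  refs <- reference_waveforms(tp)

  # constant series: p = 1, amplitude 0, not rhythmic
  const <- rhythm_test(matrix(5, 1, length(tp)), refs)
  expect_equal(const$p_value, 1)
  expect_equal(const$amplitude, 0)
  expect_false(const$rhythmic)

  # noiseless cos with acrophase 18: period 24, acrophase 18, tiny exact p
  x <- matrix(cos(2 * pi * (tp - 18) / 24), 1)
  call <- rhythm_test(x, refs)
  expect_equal(call$period, 24)
  expect_equal(call$acrophase, 18)
  expect_lt(call$p_value, 1e-4)
  expect_equal(call$amplitude, 1, tolerance = 1e-9)

  # acrophase recovery across the whole phase grid, exact at noise 0
  phases <- seq(0, 21, by = 3)
  grid <- t(vapply(phases, function(ph) cos(2 * pi * (tp - ph) / 24),
                   numeric(length(tp))))
  rownames(grid) <- paste0("ph", phases)
  calls <- rhythm_test(grid, refs)
  expect_equal(calls$acrophase, phases)
  expect_equal(calls$period, rep(24, 8))
})

test_that("rank statistic is invariant under strictly monotone transforms", {
  tp <- seq(0, 45, by = 3)
  refs <- reference_waveforms(tp)
  set.seed(19)
  x <- matrix(exp(rnorm(5 * length(tp))) +
                rep(cos(2 * pi * tp / 24), each = 5), 5)
  base <- rhythm_test(x, refs)
  for (f in list(function(v) exp(v), function(v) v^3, function(v) 10 + 2 * v)) {
    tr <- rhythm_test(t(apply(x, 1, f)), refs)
    expect_equal(tr$p_value, base$p_value)
    expect_equal(tr$period, base$period)
    expect_equal(tr$acrophase, base$acrophase)
  }
})

test_that("replicate columns are handled by repeated reference ranks", {
  tp <- rep(seq(0, 21, by = 3), each = 2)  # two replicates per timepoint
  refs <- reference_waveforms(tp)
  x <- matrix(cos(2 * pi * (tp - 6) / 24), 1)
  call <- rhythm_test(x, refs)
  expect_equal(call$acrophase, 6)
  expect_equal(call$period, 24)
  expect_true(call$p_value < 0.05)
})

test_that("BH q-values equal the spec step-up formula", {
  # hand-computed example
  expect_equal(adjust_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(adjust_fdr(0.01), 0.01)
  expect_equal(adjust_fdr(rep(1, 5)), rep(1, 5))
  expect_identical(adjust_fdr(numeric(0)), numeric(0))

  # independent step-up implementation on random p-values
  set.seed(4)
  p <- runif(50)
  o <- order(p)
  m <- length(p)
  q_manual <- numeric(m)
  q_sorted <- rev(cummin(rev(m * p[o] / seq_len(m))))
  q_manual[o] <- pmin(1, q_sorted)
  expect_equal(adjust_fdr(p), q_manual)
  # monotone in p
  expect_true(all(diff(adjust_fdr(p)[o]) >= -1e-12))
})
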