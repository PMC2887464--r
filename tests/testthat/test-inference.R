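test_that("the chi-square statistic behaves as a Pearson statistic should", {
  m <- genetic_model(2, "recessive")
  e <- expected_seed_set(m, 678)
  fit <- chisq_gof(c(171, 507), e)
  # identity: observed equal to expected
  same <- chisq_gof(c(151, 527), c(151, 527))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  # swapping both categories together leaves the statistic unchanged
  swapped <- chisq_gof(c(507, 171), c(e$category_b, e$category_a))
  expect_equal(swapped$statistic, fit$statistic)
  # p is the upper tail of chi-square with 1 df; critical value 3.84 at 0.05
  expect_equal(fit$df, 1L)
  expect_lt(abs(stats::pchisq(3.84, 1, lower.tail = FALSE) - 0.05), 0.001)
  # p strictly decreasing in the statistic, via fits of increasing distortion
  obs <- list(c(155, 523), c(165, 513), c(175, 503), c(195, 483))
  fits <- lapply(obs, chisq_gof, expected = e)
  expect_true(all(diff(vapply(fits, `[[`, double(1), "statistic")) > 0))
  expect_true(all(diff(vapply(fits, `[[`, double(1), "p_value")) < 0))
})

test_that("chi-square on unrounded expectations is required to match the table", {
  m <- genetic_model(2, "recessive")
  unrounded <- chisq_gof(c(171, 507), expected_seed_set(m, 678))$statistic
  rounded <- chisq_gof(c(171, 507), c(151, 527))$statistic
  expect_equal(unrounded, 3.53, tolerance = 0.01)
  # rounding the expectations first visibly distorts the statistic
  expect_lt(rounded, 3.45)
})

test_that("chi-square rejects bad inputs but allows zero observed cells", {
  m <- genetic_model(3, "recessive")
  # a progeny test can legitimately observe zero sensitive seedlings
  fit <- chisq_gof(c(208, 0), expected_progeny(m, 208))
  expect_false(fit$rejected)
  # zero expected cells are undefined
  expect_error(chisq_gof(c(10, 0), c(10, 0)), "Zero")
  # totals must agree
  expect_error(chisq_gof(c(170, 507), expected_seed_set(m, 678)),
               "does not match")
  expect_error(chisq_gof(c(-1, 679), expected_seed_set(m, 678)),
               "non-negative")
})

test_that("model fitting singles out the duplex-recessive model", {
  fits <- fit_all_models(published_observed("tetraploid_a"))
  expect_s3_class(fits, "seg_fit_tbl")
  expect_identical(fits$label[fits$best], "Duplex, recessive")
  expect_identical(fits$label[fits$accepted], "Duplex, recessive")
  best <- fits[fits$best, ]
  expect_equal(best$chisq_seed, 3.53, tolerance = 0.005)
  expect_equal(best$chisq_progeny, 0.34, tolerance = 0.02)
  # every other candidate is overwhelmingly rejected on at least one assay
  expect_true(all(fits$max_chisq[!fits$best] > 89))
})

test_that("confirmation groups are not rejected under their own models", {
  # the simplex group mixes conventions per assay: seed set with double
  # reduction, progeny without, so the two tests are run directly
  seed_fit <- chisq_gof(
    c(16, 250), expected_seed_set(genetic_model(1, "recessive"), 266))
  expect_equal(seed_fit$statistic, 2.27, tolerance = 0.01)
  expect_false(seed_fit$rejected)
  prog_fit <- chisq_gof(
    c(321, 86), expected_progeny(genetic_model(1, "recessive", alpha = 0), 407))
  expect_equal(prog_fit$statistic, 3.25, tolerance = 0.01)
  expect_false(prog_fit$rejected)

  triplex <- fit_all_models(
    published_observed("triplex_b"),
    candidates = list(genetic_model(3, "recessive"))
  )
  expect_equal(triplex$chisq_seed, 1.89, tolerance = 0.01)
  expect_true(triplex$accepted)
  expect_lt(triplex$chisq_progeny, 3.84)
})

test_that("a single true candidate is returned as best", {
  truth <- genetic_model(2, "recessive")
  sim <- simulate_selfing(truth, n_ovules = 678, n_genotyped = 352,
                          n_fg_scored = 0, seed = 42)
  fits <- fit_all_models(sim$counts, candidates = list(truth))
  expect_identical(fits$label[fits$best], truth$label)
  expect_error(fit_all_models(sim$counts, candidates = list()),
               "at least one")
})

test_that("tidy and glance summarise fits", {
  fits <- fit_all_models(published_observed("tetraploid_a"))
  long <- tidy(fits)
  expect_identical(nrow(long), 12L)  # 6 models x 2 assays
  expect_true(all(long$p_value >= 0 & long$p_value <= 1))
  g <- glance(fits)
  expect_identical(g$best_model, "Duplex, recessive")
  expect_identical(g$n_accepted, 1L)
  f <- chisq_gof(c(171, 507),
                 expected_seed_set(genetic_model(2, "recessive"), 678))
  expect_identical(nrow(tidy(f)), 1L)
  expect_identical(glance(f)$df, 1L)
})

test_that("transmission efficiency estimates are plain progeny ratios", {
  expect_equal(estimate_te(0, 50), 0)
  expect_equal(estimate_te(5, 50), 0.1)
  expect_equal(estimate_te(10, 10), 1)
  expect_error(estimate_te(5, 0), "positive")
  expect_error(estimate_te(-1, 10), "non-negative")
})

test_that("triplex:duplex ratio inversion recovers the male class-2 weight", {
  # closed form at alpha = 1/6: ratio r(w) = 130 w / (13 w + 100),
  # derived by hand from the convolution; inverse w = 100 r / (13 (10 - r))
  ratio_closed <- function(w) 130 * w / (13 * w + 100)
  for (w_true in c(0.05, 0.1, 0.5, 0.9)) {
    r <- ratio_closed(w_true)
    # feed the ratio as large pseudo-counts
    w_hat <- estimate_te_from_triplex_ratio(round(r * 1e6), 1e6)
    expect_equal(w_hat, w_true, tolerance = 1e-3)
  }
  # no triplex offspring observed: weight 0
  expect_equal(estimate_te_from_triplex_ratio(0, 100), 0)
  # unattainable ratio clamps to the boundary with a warning
  expect_warning(w <- estimate_te_from_triplex_ratio(500, 100), "maximum")
  expect_equal(as.numeric(w), 1)
  expect_error(estimate_te_from_triplex_ratio(5, 0), "positive")
})

test_that("weight recovery round-trips through a large simulated progeny", {
  m <- genetic_model(3, "recessive")  # male class-2 weight 0.1
  od <- offspring_dosage_distribution(m)
  set.seed(11)
  draw <- stats::rmultinom(1, 1e5, od$prob)[, 1]
  w_hat <- estimate_te_from_triplex_ratio(draw[4], draw[3])
  expect_lt(abs(w_hat - 0.1), 0.02)
})
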