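test_that("mixture_prior validates its parameters", {
  expect_s3_class(mixture_prior(0.5, 0.5), "mixture_prior")
  expect_error(mixture_prior(-0.1, 0.5), "\\[0, 1\\]")
  expect_error(mixture_prior(0.5, 0), "> 0")
  expect_error(laplace_marginal_density(1, -1), "> 0")
})

test_that("Laplace marginal matches quadrature, is symmetric, and survives deep tails", {
  # frozen value from the quadrature oracle
  expect_equal(laplace_marginal_density(0, 0.5), 0.17481, tolerance = 1e-4)
  expect_equal(laplace_marginal_density(0, 0.5), oracle_marginal(0, 0.5),
               tolerance = 1e-10)
  # tail agreement, relative
  for (z in c(3, 6, 12)) for (a in c(0.1, 0.5, 2)) {
    expect_equal(laplace_marginal_density(z, a), oracle_marginal(z, a),
                 tolerance = 1e-8)
  }
  z <- c(0.3, 1.7, 5, 9)
  expect_equal(laplace_marginal_density(z, 0.7),
               laplace_marginal_density(-z, 0.7))
  # the naive e^{a^2/2} e^{az} form overflows here; ours must not
  expect_true(is.finite(laplace_marginal_density(40, 2)))
  expect_gt(laplace_marginal_density(40, 2), 0)
})

test_that("posterior nonzero probability has the mixture form and is monotone", {
  expect_equal(posterior_nonzero_prob(2, mixture_prior(0, 0.5)), 0)
  expect_equal(posterior_nonzero_prob(2, mixture_prior(1, 0.5)), 1)
  expect_equal(posterior_nonzero_prob(0, mixture_prior(0.5, 0.5)), 0.30465,
               tolerance = 1e-4)
  for (w in c(0.05, 0.5)) for (a in c(0.2, 1)) {
    p <- posterior_nonzero_prob(seq(0, 12, 0.25), mixture_prior(w, a))
    expect_true(all(diff(p) >= -1e-12))
    expect_true(all(p >= 0 & p <= 1))
  }
})

test_that("posterior median: zeros, oracle agreement, antisymmetry, monotonicity", {
  pr <- mixture_prior(0.3, 0.8)
  expect_identical(posterior_median(0, pr), 0)
  # sub-threshold observation maps exactly to zero
  expect_identical(posterior_median(1, mixture_prior(0.05, 0.5)), 0)
  # oracle agreement at a strong observation
  m <- posterior_median(4, mixture_prior(0.5, 0.5))
  expect_equal(m, oracle_posterior_median(4, 0.5, 0.5), tolerance = 1e-6)
  expect_gt(4 - m, 0)
  expect_lte(4 - m, 0.5 + 1)
  z <- seq(-8, 8, 0.5)
  med <- posterior_median(z, pr)
  expect_equal(med, -rev(med))               # antisymmetry
  expect_true(all(diff(med) >= -1e-12))      # monotone in z
  expect_true(all(abs(med) <= abs(z) + 1e-12))
  expect_true(all(sign(med) %in% c(0, sign(z))))
})

test_that("shrinkage is bounded: z - estimate stabilizes in the far tail", {
  for (a in c(0.1, 0.5, 2)) {
    pr <- mixture_prior(0.3, a)
    s20 <- 20 - posterior_median(20, pr)
    s40 <- 40 - posterior_median(40, pr)
    expect_gt(s20, 0)
    expect_lt(abs(s40 - s20), 1e-3)
  }
})

test_that("selection threshold separates zero from nonzero medians", {
  pr <- mixture_prior(0.5, 0.5)
  t50 <- selection_threshold(pr)
  expect_identical(posterior_median(t50 - 1e-6, pr), 0)
  expect_gt(posterior_median(t50 + 1e-6, pr), 0)
  # monotone nonincreasing in w; edge cases
  expect_gt(selection_threshold(mixture_prior(0.01, 0.5)), t50)
  expect_lt(selection_threshold(mixture_prior(1, 0.5)), 1e-6)
  expect_identical(selection_threshold(mixture_prior(0, 0.5)), Inf)
  # estimate == 0 exactly iff |z| <= t, on a grid around the threshold
  for (w in c(0.05, 0.5)) {
    p <- mixture_prior(w, 1)
    tt <- selection_threshold(p)
    off <- seq(-0.5, 0.5, 0.05)
    off <- off[abs(off) > 1e-3]    # skip the knife-edge point itself
    z <- tt + off
    expect_equal(posterior_median(z, p) > 0, z > tt)
  }
})

test_that("conditional mode of w follows the (hyper)Beta closed forms", {
  expect_error(conditional_mode_w(numeric(0)), "non-empty")
  beta <- c(rep(0, 95), rnorm(5))
  expect_equal(conditional_mode_w(beta), 0.05)
  expect_equal(conditional_mode_w(beta, hyper = c(2, 2)), 6 / 102,
               tolerance = 1e-12)
  # all-zero clamps at w_min
  expect_equal(conditional_mode_w(rep(0, 100)), 1 / 100)
  expect_equal(conditional_mode_w(rep(0, 100), w_min = 1e-6), 1e-6)
  # all-nonzero clamps at w_max
  expect_equal(conditional_mode_w(rep(1, 10), w_max = 1 - 1e-6), 1 - 1e-6)
})

test_that("conditional mode of a is k/S, clamped, with k = 0 pass-through", {
  expect_equal(conditional_mode_a(c(0.5, 1.5, 0)), 2 / 2.0)
  expect_equal(conditional_mode_a(rep(0, 5), a_prev = 0.77), 0.77)
  expect_equal(conditional_mode_a(c(0.01, 0.01)), 3)        # clamp at a_max
  expect_equal(conditional_mode_a(c(100, 100)), 0.05)       # clamp at a_min
  # sigma scales the coefficients
  expect_equal(conditional_mode_a(c(1, 3), sigma = 2), 2 / 2)
  # Gamma hyperprior shifts the maximizer
  expect_equal(conditional_mode_a(c(1, 1), hyper = c(2, 1)), 3 / 3)
})

test_that("conditional modes agree with dense grid search of the log-density", {
  set.seed(42)
  for (rep in 1:10) {
    p <- sample(20:80, 1)
    beta <- rnorm(p) * rbinom(p, 1, 0.3)
    k <- sum(beta != 0)
    # w: maximize k log w + (p-k) log(1-w)
    wg <- seq(1e-4, 1 - 1e-4, length.out = 20001)
    w_grid <- wg[which.max(k * log(wg) + (p - k) * log(1 - wg))]
    expect_lt(abs(conditional_mode_w(beta, w_min = 1e-6) - w_grid), 1e-4)
    if (k > 0) {
      S <- sum(abs(beta[beta != 0]))
      ag <- seq(0.05, 3, length.out = 40001)
      a_grid <- ag[which.max(k * log(ag) - ag * S)]
      a_hat <- conditional_mode_a(beta)
      if (a_hat > 0.05 && a_hat < 3)
        expect_lt(abs(a_hat - a_grid), 1e-4)
    }
  }
})
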