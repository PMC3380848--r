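test_that("dilute-solution map and its inverse are exact", {
  expect_equal(mu_from_concentration(-50, 1), -50)
  expect_equal(mu_from_concentration(-50, exp(1)), -50 + rt_energy())
  # RT ln(1e-3) = 2.4790 * (-6.9078) evaluated independently
  expect_equal(mu_from_concentration(-100, 1e-3), -117.124, tolerance = 1e-3 / 117)
  expect_error(mu_from_concentration(-100, 0), class = "gibbscape_domain_error")

  expect_equal(concentration_from_mu(-50, -50), 1)
  expect_equal(concentration_from_mu(-100, -117.124), 1.000e-3, tolerance = 1e-3)
  for (c0 in 10^seq(-6, 0)) {
    mu <- mu_from_concentration(-123.4, c0)
    expect_equal(concentration_from_mu(-123.4, mu), c0, tolerance = 1e-10)
  }
  expect_error(concentration_from_mu(0, 1e6), class = "gibbscape_domain_error")

  # strict monotonicity
  cs <- 10^seq(-6, 0, length.out = 20)
  expect_true(all(diff(mu_from_concentration(-10, cs)) > 0))
  mus <- seq(-150, -50, length.out = 20)
  expect_true(all(diff(concentration_from_mu(-100, mus)) > 0))
})

test_that("prior boxes follow the concentration data, the decade rule and clamps", {
  net <- reaction_network(matrix(c(-1, 1, 0, 0, -1, 1), 3, 2),
                          metabolite_ids = c("h2o", "X", "Y"),
                          reaction_ids = c("r1", "r2"))
  tab <- data.frame(metabolite_id = c("h2o", "X", "Y"),
                    dGf0 = c(-237.2, -200, -150),
                    conc_center = c(NA, NA, 1e-3),
                    conc_sd = c(NA, NA, 2.5e-4),
                    clamp = c(TRUE, FALSE, FALSE))
  pr <- build_prior(net, tab)
  # clamped water: halfwidth zero, fixed at its center
  expect_true(pr$clamp[1])
  expect_equal(pr$mu_halfwidth[1], 0)
  # dGf0-only metabolite spans four concentration decades:
  # halfwidth = 2 RT ln 10 = 11.4166 kJ/mol (computed independently)
  expect_equal(pr$mu_halfwidth[2], 2 * rt_energy() * log(10), tolerance = 1e-12)
  expect_equal(pr$mu_halfwidth[2], 11.4166, tolerance = 1e-4)
  expect_equal(pr$mu_center[2], mu_from_concentration(-200, 1e-3))
  # concentration-backed metabolite: endpoints at c +/- 2 sd through the map
  lo <- mu_from_concentration(-150, 5e-4)
  hi <- mu_from_concentration(-150, 1.5e-3)
  expect_equal(pr$mu_halfwidth[3], (hi - lo) / 2)
  expect_equal(pr$mu_center[3], mu_from_concentration(-150, 1e-3))

  # degenerate range: center - 2 sd <= 0
  tab$conc_sd[3] <- 6e-4
  expect_error(build_prior(net, tab), "Y", class = "gibbscape_domain_error")

  # uncovered metabolite is an error naming it, unless the policy covers it
  tab2 <- tab[1:2, ]
  expect_error(build_prior(net, tab2), "Y",
               class = "gibbscape_validation_error")
  pr2 <- build_prior(net, tab2, policy = list(unknown_center = -100))
  expect_equal(pr2$mu_center[3], -100)
})

test_that("prior sampling is deterministic per seed and stays inside its box", {
  net <- generate_network(6, 8, seed = 3)
  tab <- data.frame(metabolite_id = net$metabolite_ids,
                    dGf0 = seq(-300, -50, length.out = 6),
                    clamp = c(TRUE, rep(FALSE, 5)))
  pr <- build_prior(net, tab)
  s1 <- sample_prior(pr, seed = 4)
  s2 <- sample_prior(pr, seed = 4)
  expect_identical(as.numeric(s1), as.numeric(s2))
  expect_identical(as.numeric(s1)[1], pr$mu_center[1])  # clamped at center

  draws <- replicate(500, as.numeric(sample_prior(pr)))
  for (i in 1:6) {
    expect_true(all(draws[i, ] >= pr$mu_center[i] - pr$mu_halfwidth[i] - 1e-12))
    expect_true(all(draws[i, ] <= pr$mu_center[i] + pr$mu_halfwidth[i] + 1e-12))
  }
  # uniform-draw statistics: sample mean within 3 standard errors of center
  se <- pr$mu_halfwidth[2] / sqrt(3) / sqrt(500)
  expect_lt(abs(mean(draws[2, ]) - pr$mu_center[2]), 3 * se)

  # all-zero halfwidths return the centers exactly
  pr0 <- pr; pr0$mu_halfwidth[] <- 0
  expect_equal(as.numeric(sample_prior(pr0, seed = 1)), pr0$mu_center)
})

test_that("boundedness check finds recession rays exactly when they exist", {
  net <- net_ab()
  # translation invariance: uniform shift is always a ray without clamps
  res <- boundedness_check(net, 1L)
  expect_equal(res$status, "UNBOUNDED")
  ray <- res$ray
  expect_gt(max(abs(ray)), 0)
  expect_lte(ray[2] - ray[1], 1e-9)  # ray satisfies the homogeneous constraint

  # a full box bound on both potentials compactifies
  res2 <- boundedness_check(net, 1L, bounds = cbind(c(-1, -1), c(1, 1)))
  expect_equal(res2$status, "BOUNDED")

  # clamping A leaves mu_B free to run to -Inf
  res3 <- boundedness_check(net, 1L, clamped = c(TRUE, FALSE))
  expect_equal(res3$status, "UNBOUNDED")
  expect_equal(unname(res3$ray[1]), 0)
  expect_lt(res3$ray[2], 0)

  # ray validity: adding the ray to a feasible point keeps it feasible
  mu_feas <- c(1, 0)
  for (scale in c(0.5, 2, 10)) {
    v <- gibbs_changes(net, mu_feas + scale * res$ray)
    expect_lte(v[1], gibbs_changes(net, mu_feas)[1] + 1e-9)
  }
})
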