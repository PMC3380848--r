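test_that("a single MinOver step moves potentials against the worst constraint", {
  net <- net_ab()
  mu1 <- minover_step(net, 1L, c(0, 0), r0 = 1, lam = 0.01)
  expect_equal(as.numeric(mu1), c(0.01, -0.01))
  expect_equal(unname(gibbs_changes(net, mu1)), -0.02)

  # clamped substrate stays put
  mu2 <- minover_step(net, 1L, potential_vector(c(0, 0), clamped = c(TRUE, FALSE)),
                      r0 = 1, lam = 0.01)
  expect_equal(as.numeric(mu2), c(0, -0.01))

  # two steps = one step of twice the size (fixed r0)
  mu3 <- minover_step(net, 1L, minover_step(net, 1L, c(0, 0), 1, 0.01), 1, 0.01)
  expect_equal(as.numeric(mu3),
               as.numeric(minover_step(net, 1L, c(0, 0), 1, 0.02)))

  # fully clamped column cannot improve
  expect_error(minover_step(net, 1L,
                            potential_vector(c(0, 0), clamped = c(TRUE, TRUE)),
                            1, 0.01),
               class = "gibbscape_stall_error")
  expect_error(minover_step(net, 0L, c(0, 0), 1, 0.01),
               class = "gibbscape_validation_error")
})

test_that("MinOver solves a chain, certifiably stalls on a cycle, exits early when feasible", {
  net <- net_chain()
  res <- minover_solve(net, c(1L, 1L), rep(0, 3), control = ctrl_small())
  expect_equal(res$status, "FEASIBLE")
  mu <- as.numeric(res$mu)
  expect_true(mu[1] > mu[2] && mu[2] > mu[3])
  dg <- gibbs_changes(net, res$mu)
  expect_true(all(dg <= -res$control$eps + 1e-9))

  cyc <- net_cycle3()
  res2 <- minover_solve(cyc, c(1L, 1L, 1L), rep(0, 3), control = ctrl_small())
  expect_equal(res2$status, "MAX_ITERS")
  expect_setequal(unique(res2$r0_tail), 1:3)

  # already feasible start: zero iterations, untouched potentials
  mu0 <- c(2, 1, 0)
  res3 <- minover_solve(net, c(1L, 1L), mu0, control = ctrl_small())
  expect_equal(res3$status, "FEASIBLE")
  expect_equal(res3$iterations, 0)
  expect_equal(as.numeric(res3$mu), mu0)
})

test_that("relaxation steps are violation-proportional; alpha=1 lands on the boundary", {
  net <- net_ab()
  ctrl <- solver_control(eps = 0, alpha = 1, max_iters = 50, window = 10)
  res <- relaxation_solve(net, 1L, c(0, 1), control = ctrl)
  expect_equal(as.numeric(res$mu), c(0.5, 0.5), tolerance = 1e-12)
  expect_equal(unname(gibbs_changes(net, res$mu)), 0, tolerance = 1e-12)

  # alpha = 2 overshoots to the mirror image
  step1 <- relaxation_solve(net, 1L, c(0, 1),
                            control = solver_control(eps = 0, alpha = 1.999999,
                                                     max_iters = 1, window = 1))
  expect_equal(as.numeric(step1$mu), c(1, 0), tolerance = 1e-4)

  # feasible start: zero iterations
  res0 <- relaxation_solve(net, 1L, c(1, 0),
                           control = solver_control(alpha = 1))
  expect_equal(res0$iterations, 0)

  # convergence on a planted instance for several alphas
  inst <- random_instance(11, "feasible")
  for (al in c(0.5, 1, 1.5)) {
    r <- relaxation_solve(inst$network, inst$sigma, rep(0, nrow(inst$network$S)),
                          control = ctrl_small(alpha = al))
    expect_equal(r$status, "FEASIBLE")
  }
})

test_that("penalty method projects the prior onto the feasible half-space", {
  net <- net_ab()
  eps <- 1e-6
  res <- penalty_solve(net, 1L, c(0, 1), control = solver_control(eps = eps))
  expect_equal(res$status, "FEASIBLE")
  expect_equal(as.numeric(res$mu), c((1 + eps) / 2, (1 - eps) / 2),
               tolerance = 1e-4)

  # feasible prior center: returned unchanged with zero iterations
  res0 <- penalty_solve(net, 1L, c(1, 0), control = solver_control())
  expect_equal(res0$status, "FEASIBLE")
  expect_equal(res0$iterations, 0)
  expect_equal(as.numeric(res0$mu), c(1, 0))
})

test_that("all solvers certify their FEASIBLE claims and conserve clamps", {
  for (seed in c(3, 17, 29)) {
    inst <- random_instance(seed, "feasible")
    M <- nrow(inst$network$S)
    clamped <- c(TRUE, rep(FALSE, M - 1))
    # clamp the first potential at the planted witness value so the clamped
    # system provably stays feasible
    mu0 <- potential_vector(c(as.numeric(inst$mu_star)[1], runif(M - 1, -5, 5)),
                            clamped = clamped)
    for (solver in list(minover_solve, relaxation_solve, penalty_solve)) {
      # the penalty descent needs its full default iteration budget
      ctl <- if (identical(solver, penalty_solve)) solver_control()
             else ctrl_small()
      res <- solver(inst$network, inst$sigma, mu0, control = ctl)
      expect_equal(res$status, "FEASIBLE")
      v <- as.numeric(inst$sigma) * gibbs_changes(inst$network, res$mu)
      expect_true(all(v[inst$sigma != 0] <= -res$control$eps + 1e-9))
      expect_identical(as.numeric(res$mu)[1],
                       as.numeric(inst$mu_star)[1])  # bit-identical clamp
    }
  }
})

test_that("box bounds are enforced through synthetic constraint rows", {
  net <- net_ab()
  bounds <- cbind(c(-2, -2), c(2, 2))
  res <- minover_solve(net, 1L, c(0, 0), control = ctrl_small(),
                       bounds = bounds)
  expect_equal(res$status, "FEASIBLE")
  mu <- as.numeric(res$mu)
  expect_true(all(mu >= -2 - 1e-9 & mu <= 2 + 1e-9))
  expect_lt(mu[2] - mu[1], 0)
})

test_that("fit_potentials wraps the solvers with the standard S3 surface", {
  inst <- random_instance(5, "feasible")
  prior_tab <- data.frame(metabolite_id = inst$network$metabolite_ids,
                          dGf0 = rep(-100, nrow(inst$network$S)))
  prior <- build_prior(inst$network, prior_tab)
  fit <- fit_potentials(inst$network, inst$sigma, prior = prior, seed = 2,
                        control = ctrl_small())
  expect_s3_class(fit, "gibbs_fit")
  expect_equal(fit$result$status, "FEASIBLE")
  expect_length(coef(fit), nrow(inst$network$S))
  r <- residuals(fit)
  expect_true(all(r[inst$sigma != 0] <= -1e-6 + 1e-9))
  expect_output(print(fit), "FEASIBLE")
  expect_output(print(summary(fit)), "constrained reactions")
  sols <- simulate(fit, nsim = 3, seed = 9)
  expect_length(sols, 3)
  expect_true(all(attr(sols, "status") == "FEASIBLE"))
  # same seed, same draw: deterministic end-to-end
  fit2 <- fit_potentials(inst$network, inst$sigma, prior = prior, seed = 2,
                         control = ctrl_small())
  expect_identical(coef(fit), coef(fit2))
})

test_that("iteration counts shrink with the planted margin and any lambda converges", {
  # paired design: the same seed gives the same network at both margins, so
  # the margin effect is isolated from instance-to-instance variability
  diffs <- sapply(1:200, function(s) {
    its <- sapply(c(0.1, 1), function(c_margin) {
      inst <- random_instance(1000 + s, "feasible", margin = c_margin)
      res <- minover_solve(inst$network, inst$sigma,
                           rep(0, nrow(inst$network$S)), control = ctrl_small())
      expect_equal(res$status, "FEASIBLE")
      res$iterations
    })
    its[2] - its[1]
  })
  expect_lte(mean(diffs), 0)  # deeper planted margin, no extra iterations
  for (lam in c(0.01, 0.1, 1)) {
    inst <- random_instance(77, "feasible")
    res <- minover_solve(inst$network, inst$sigma, rep(0, nrow(inst$network$S)),
                         control = ctrl_small(lam = lam))
    expect_equal(res$status, "FEASIBLE")
  }
})
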