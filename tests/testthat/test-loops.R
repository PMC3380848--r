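test_that("certificate verification checks positivity and column cancellation", {
  cyc <- net_cycle3()
  good <- loop_certificate(1:3, c(1, 1, 1), c(1L, 1L, 1L), network = cyc)
  expect_true(verify_loop_certificate(cyc, good))

  flipped <- loop_certificate(1:3, c(1, 1, 1), c(1L, -1L, 1L), network = cyc)
  expect_false(verify_loop_certificate(cyc, flipped))

  chain <- net_chain()
  pair <- loop_certificate(1:2, c(1, 2), c(1L, 1L), network = chain)
  expect_false(verify_loop_certificate(chain, pair))

  expect_error(loop_certificate(1L, 1, 1L), class = "gibbscape_validation_error")
  expect_error(loop_certificate(1:2, c(1, -1), c(1L, 1L)),
               class = "gibbscape_validation_error")
})

test_that("find_loop recovers a planted cycle and rejects acyclic candidates", {
  inst <- random_instance(21, "loop", loop_k = 3)
  net <- inst$network; sigma <- inst$sigma
  planted <- inst$certificate$reactions

  cert <- find_loop(net, sigma, planted, k_max = 6)
  expect_false(is.null(cert))
  expect_setequal(cert$reactions, planted)
  expect_equal(cert$gamma / max(cert$gamma), rep(1, 3))
  expect_true(verify_loop_certificate(net, cert))

  # chain members mixed into the candidates are excluded from the certificate
  extra <- setdiff(which(sigma != 0), planted)[1:2]
  cert2 <- find_loop(net, sigma, c(planted, extra), k_max = 6)
  expect_setequal(cert2$reactions, planted)

  # acyclic candidate set: no certificate
  feas <- random_instance(22, "feasible")
  cands <- which(feas$sigma != 0)[1:6]
  expect_null(find_loop(feas$network, feas$sigma, cands, k_max = 6))

  # exhausted budget is an error distinct from "none found"
  cands_all <- which(feas$sigma != 0)
  expect_error(find_loop(feas$network, feas$sigma, cands_all, k_max = 10,
                         budget = 5),
               class = "gibbscape_budget_error")
})

test_that("the visit-count shortcut certifies a pure cycle without enumeration", {
  cyc <- net_cycle3()
  counts <- c(400, 400, 400)
  cert <- find_loop(cyc, c(1L, 1L, 1L), 1:3, k_max = 2,  # k_max too small to enumerate a 3-loop
                    counts = counts)
  expect_false(is.null(cert))
  expect_equal(cert$reactions, 1:3)
})

test_that("LP oracle decides feasibility and produces verified certificates", {
  chain <- net_chain()
  res <- lp_feasibility_oracle(chain, c(1L, 1L))
  expect_equal(res$status, "FEASIBLE")
  dg <- gibbs_changes(chain, res$mu)
  expect_true(all(dg < 0))

  cyc <- net_cycle3()
  res2 <- lp_feasibility_oracle(cyc, c(1L, 1L, 1L))
  expect_equal(res2$status, "INFEASIBLE")
  expect_true(verify_loop_certificate(cyc, res2$certificate))

  expect_error(lp_feasibility_oracle(chain, c(0L, 0L)),
               class = "gibbscape_validation_error")
})

test_that("MinOver classification agrees with the LP oracle on random instances", {
  agree <- 0L
  n <- 60
  for (s in 1:n) {
    kind <- if (s %% 2) "feasible" else "loop"
    inst <- random_instance(3000 + s, kind,
                            margin = c(0.1, 1)[1 + s %% 2],
                            loop_k = 2 + (s %% 5))
    mo <- minover_classify(inst$network, inst$sigma)
    orc <- lp_feasibility_oracle(inst$network, inst$sigma)
    if (mo$verdict == orc$status) agree <- agree + 1L
    if (mo$verdict == "INFEASIBLE")
      expect_true(verify_loop_certificate(inst$network, mo$certificate))
  }
  expect_equal(agree, n)
})

test_that("find_loop is complete and minimal at small scale (vs LP oracle and brute force)", {
  n_done <- 0
  for (s in 1:40) {
    set.seed(4000 + s)
    M <- sample(4:8, 1); N <- sample(5:12, 1)
    net <- generate_network(M, N, density = 0.4)
    sigma <- sample(c(-1L, 1L), N, replace = TRUE)
    orc <- lp_feasibility_oracle(net, sigma)
    cert <- tryCatch(
      find_loop(net, sigma, seq_len(N), k_max = N),
      gibbscape_budget_error = function(e) NULL)
    if (orc$status == "INFEASIBLE") {
      expect_false(is.null(cert))
      expect_true(verify_loop_certificate(net, cert))
      # minimality: no strictly smaller subset certifies (brute force)
      k_found <- length(cert$reactions)
      if (k_found > 2) {
        smaller <- combn(seq_len(N), k_found - 1)
        any_smaller <- FALSE
        for (j in seq_len(ncol(smaller))) {
          sub <- smaller[, j]
          B <- net$S[, sub, drop = FALSE] * rep(as.numeric(sigma[sub]), each = M)
          g <- gibbscape:::.positive_nullvector(B)
          if (!is.null(g)) { any_smaller <- TRUE; break }
        }
        expect_false(any_smaller)
      }
    } else {
      expect_null(cert)
    }
    n_done <- n_done + 1
  }
  expect_equal(n_done, 40)
})

test_that("remove_loop flips exactly one reversible member, uniformly", {
  cyc <- net_cycle3(reversible = c(FALSE, TRUE, TRUE))
  cert <- loop_certificate(1:3, c(1, 1, 1), c(1L, 1L, 1L), network = cyc)
  sigma <- c(1L, 1L, 1L)
  out <- remove_loop(sigma, cert, cyc$reversible, seed = 5)
  expect_equal(sum(out != sigma), 1L)
  expect_true(which(out != sigma) %in% 2:3)

  picks <- vapply(1:2000, function(s)
    which(remove_loop(sigma, cert, cyc$reversible, seed = s) != sigma),
    integer(1))
  f2 <- mean(picks == 2L)
  expect_lt(abs(f2 - 0.5), 0.05)  # binomial CI at n = 2000

  all_irrev <- net_cycle3(reversible = c(FALSE, FALSE, FALSE))
  err <- tryCatch(remove_loop(sigma, cert, all_irrev$reversible, seed = 1),
                  gibbscape_irreversible_loop = function(e) e)
  expect_s3_class(err, "gibbscape_irreversible_loop")
  expect_s3_class(err$certificate, "loop_certificate")
})

test_that("correct_directions repairs planted loops touching only reversible members", {
  inst <- random_instance(31, "loop", loop_k = 3, loop_reversible = c(TRUE, FALSE, FALSE))
  rep1 <- correct_directions(inst$network, inst$sigma, control = ctrl_small(),
                             seed = 8)
  expect_equal(rep1$status, "FEASIBLE")
  expect_equal(sum(rep1$sigma != inst$sigma), 1L)
  # only reversible reactions were touched
  changed <- which(rep1$sigma != inst$sigma)
  expect_true(all(inst$network$reversible[changed]))
  orc <- lp_feasibility_oracle(inst$network, rep1$sigma)
  expect_equal(orc$status, "FEASIBLE")
  expect_length(rep1$certificates, 1)

  # feasible input returns unchanged with an empty certificate list
  feas <- random_instance(32, "feasible")
  rep2 <- correct_directions(feas$network, feas$sigma, control = ctrl_small())
  expect_equal(unname(rep2$sigma), unname(as.integer(feas$sigma)))
  expect_length(rep2$certificates, 0)

  # two disjoint planted loops: both certified and removed
  base <- random_instance(33, "feasible")
  aug1 <- plant_loop(base$network, base$sigma, k = 3, reversible = TRUE)
  aug2 <- plant_loop(aug1$network, aug1$sigma, k = 4, reversible = TRUE)
  rep3 <- correct_directions(aug2$network, aug2$sigma, control = ctrl_small(),
                             seed = 10)
  expect_equal(rep3$status, "FEASIBLE")
  expect_length(rep3$certificates, 2)
  expect_equal(lp_feasibility_oracle(aug2$network, rep3$sigma)$status,
               "FEASIBLE")

  # an all-irreversible loop is surfaced as an unrepairable error
  bad <- random_instance(34, "loop", loop_k = 3, loop_reversible = FALSE)
  expect_error(correct_directions(bad$network, bad$sigma, control = ctrl_small()),
               class = "gibbscape_irreversible_loop")
})

test_that("catalogue deduplicates loops and measures the feasible fraction", {
  # loop-free network: empty catalogue, fraction 1
  feas <- random_instance(41, "feasible")
  cat1 <- catalogue_loops(feas$network, 30, control = ctrl_small(), seed = 3)
  expect_length(cat1$loops, 0)
  expect_equal(cat1$feasible_fraction, 1)

  # a 2-loop triggered only half the time: r_f (irreversible, A -> B) and
  # r_b (reversible, B -> A) close a cycle exactly when the draw runs r_b
  # forward, which happens with probability 1/2
  S <- matrix(c(-1, 1, 1, -1), 2, 2,
              dimnames = list(c("A", "B"), c("r_f", "r_b")))
  net <- reaction_network(S, reversible = c(FALSE, TRUE))
  cat2 <- catalogue_loops(net, 100, control = ctrl_small(), seed = 7)
  expect_length(cat2$loops, 1)
  expect_equal(length(cat2$loops[[1]]$reactions), 2)
  expect_gt(cat2$loops[[1]]$occurrences, 1)  # found repeatedly, counted once
  expect_lt(abs(cat2$feasible_fraction - 0.5), 0.15)
  expect_equal(cat2$feasible_fraction,
               mean(cat2$statuses == "feasible"))
})
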