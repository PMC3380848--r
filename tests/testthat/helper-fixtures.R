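# Shared tiny fixtures, built in code.

# A -> B
net_ab <- function() {
  reaction_network(matrix(c(-1, 1), 2, 1,
                          dimnames = list(c("A", "B"), "r1")))
}

# chain A -> B -> C, both irreversible
net_chain <- function() {
  reaction_network(matrix(c(-1, 1, 0, 0, -1, 1), 3, 2,
                          dimnames = list(c("A", "B", "C"), c("r1", "r2"))))
}

# 3-cycle A -> B -> C -> A; reversibility configurable per reaction
net_cycle3 <- function(reversible = c(FALSE, TRUE, TRUE)) {
  reaction_network(matrix(c(-1, 1, 0, 0, -1, 1, 1, 0, -1), 3, 3,
                          dimnames = list(c("A", "B", "C"),
                                          c("r1", "r2", "r3"))),
                   reversible = reversible)
}

# short solver config for small instances
ctrl_small <- function(...) solver_control(max_iters = 20000, window = 2000, ...)

# classify an instance the MinOver way: solve; on non-convergence look for a
# certificate in the tail (escalating to all visited constraints once)
minover_classify <- function(net, sigma, control = ctrl_small(), k_max = 8) {
  res <- minover_solve(net, sigma, rep(0, nrow(net$S)), control = control)
  if (res$status == "FEASIBLE") return(list(verdict = "FEASIBLE", solve = res))
  cert <- find_loop(net, sigma, sort(unique(res$r0_tail)), k_max = k_max,
                    counts = res$tail_counts)
  if (is.null(cert))
    cert <- find_loop(net, sigma, which(res$counts_total > 0), k_max = k_max,
                      counts = res$counts_total)
  list(verdict = if (is.null(cert)) "UNDECIDED" else "INFEASIBLE",
       certificate = cert, solve = res)
}
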