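#' Solver configuration
#'
#' Collects the tunable constants shared by the inequality solvers.
#' All energies are in kJ/mol.
#'
#' @param lam fixed MinOver step constant (> 0). Scale-sensitive: it should be
#'   small relative to the spread of the prior.
#' @param eps feasibility margin: a constraint counts as satisfied when
#'   sigma_r DeltaG_r <= -eps. Floating point cannot certify the strict
#'   inequality sigma_r DeltaG_r < 0, and the convergence guarantee assumes a
#'   solution with positive margin, so a small positive eps is used.
#' @param max_iters iteration cap; `NULL` means 10 * N * 1000, chosen at solve
#'   time.
#' @param window length of the stored tail of least-satisfied reaction
#'   indices, used by the loop finder; `NULL` means `min(1e4, max_iters)`.
#' @param alpha relaxation factor in (0, 2) for [relaxation_solve()]: the step
#'   is proportional to the current violation; `alpha = 1` lands the targeted
#'   constraint exactly on its boundary.
#' @param eta,beta0,beta_step penalty-method constants: descent rate, initial
#'   penalty weight and its increment each time an inner minimum is found
#'   while violations remain.
#' @param tol inner-convergence tolerance on the step norm (penalty method).
#' @return list of class `solver_control`.
#' @export
solver_control <- function(lam = 0.1, eps = 1e-6, max_iters = NULL,
                           window = NULL, alpha = 1, eta = 1e-3,
                           beta0 = 1, beta_step = 1, tol = 1e-8) {
  stopifnot(lam > 0, eps >= 0, alpha > 0, alpha < 2,
            eta > 0, beta0 > 0, beta_step > 0, tol > 0)
  if (!is.null(max_iters)) stopifnot(max_iters >= 1)
  if (!is.null(window)) stopifnot(window >= 1)
  structure(list(lam = lam, eps = eps, max_iters = max_iters, window = window,
                 alpha = alpha, eta = eta, beta0 = beta0,
                 beta_step = beta_step, tol = tol),
            class = "solver_control")
}

.control_resolve <- function(control, n_reactions) {
  if (is.null(control)) control <- solver_control()
  stopifnot(inherits(control, "solver_control"))
  if (is.null(control$max_iters)) control$max_iters <- 10 * n_reactions * 1000
  if (is.null(control$window))
    control$window <- min(1e4, control$max_iters)
  if (control$window > control$max_iters)
    stop_gibbscape("window cannot exceed max_iters", "gibbscape_validation_error")
  control
}

## Augment a system with box constraints L_i <= mu_i <= U_i, encoded as extra
## single-variable inequality rows: one reference metabolite clamped at 1 and
## one synthetic column per finite bound, so every solver handles bounds with
## its unmodified update rule.
.augment_bounds <- function(network, sigma, mu, bounds) {
  if (is.null(bounds))
    return(list(network = network, sigma = as.integer(sigma), mu = mu,
                n_orig_m = nrow(network$S), n_orig_r = ncol(network$S)))
  stopifnot(is.matrix(bounds), nrow(bounds) == nrow(network$S), ncol(bounds) == 2)
  M <- nrow(network$S); N <- ncol(network$S)
  cols <- list(); ids <- character(0)
  for (i in seq_len(M)) {
    L <- bounds[i, 1]; U <- bounds[i, 2]
    if (is.finite(U)) {  # mu_i - U <= 0
      col <- numeric(M + 1); col[i] <- 1; col[M + 1] <- -U
      cols <- c(cols, list(col)); ids <- c(ids, paste0("..up_", network$metabolite_ids[i]))
    }
    if (is.finite(L)) {  # L - mu_i <= 0
      col <- numeric(M + 1); col[i] <- -1; col[M + 1] <- L
      cols <- c(cols, list(col)); ids <- c(ids, paste0("..lo_", network$metabolite_ids[i]))
    }
  }
  if (!length(cols))
    return(list(network = network, sigma = as.integer(sigma), mu = mu,
                n_orig_m = M, n_orig_r = N))
  S2 <- rbind(network$S, 0)
  S2 <- cbind(S2, do.call(cbind, cols))
  mids <- c(network$metabolite_ids, "..bound_ref")
  rids <- c(network$reaction_ids, ids)
  net2 <- reaction_network(S2, reversible = c(network$reversible,
                                              rep(FALSE, length(cols))),
                           metabolite_ids = mids, reaction_ids = rids)
  mu2 <- potential_vector(c(as.numeric(mu), 1),
                          clamped = c(clamp_mask(mu), TRUE),
                          metabolite_ids = mids)
  list(network = net2, sigma = c(as.integer(sigma), rep(1L, length(cols))),
       mu = mu2, n_orig_m = M, n_orig_r = N)
}

.core_call <- function(network, sigma, mu0, control, mode, bounds = NULL) {
  sigma <- as.integer(sigma)
  mu0 <- .as_potential(mu0, network)
  if (all(sigma == 0))
    stop_gibbscape("no constrained reactions: all directions are unassigned",
                   "gibbscape_validation_error")
  aug <- .augment_bounds(network, sigma, mu0, bounds)
  net <- aug$network; sig <- aug$sigma; mu <- aug$mu
  control <- .control_resolve(control, ncol(network$S))
  cl <- clamp_mask(mu)
  Smask <- net$S
  Smask[cl, ] <- 0
  G <- crossprod(Smask)
  offset <- as.numeric(sig) *
    drop(crossprod(net$S[cl, , drop = FALSE], as.numeric(mu)[cl]))
  res <- .minover_core(Smask, G, sig, offset, as.numeric(mu),
                       control$lam, control$eps, control$alpha,
                       control$max_iters, as.integer(control$window),
                       as.integer(mode))
  if (res$status == 2L) {
    r0 <- res$tail[length(res$tail)]
    stop_gibbscape(sprintf(
      "stall: least satisfied constraint '%s' involves only clamped metabolites and cannot improve",
      net$reaction_ids[r0]), "gibbscape_stall_error")
  }
  mu_out <- potential_vector(res$mu[seq_len(aug$n_orig_m)],
                             clamped = clamp_mask(mu0),
                             metabolite_ids = network$metabolite_ids)
  tail_idx <- res$tail
  tail_counts <- tabulate(tail_idx, nbins = ncol(net$S))
  viol <- setNames(res$violations, net$reaction_ids)
  structure(list(
    status = if (res$status == 0L) "FEASIBLE" else "MAX_ITERS",
    mu = mu_out,
    iterations = res$iterations,
    r0_tail = tail_idx,
    tail_counts = tail_counts,
    counts_total = res$counts_total,
    violations = viol,
    reaction_ids = net$reaction_ids,
    n_reactions = aug$n_orig_r,
    control = control,
    mode = c("minover", "relaxation")[mode + 1L]
  ), class = "gibbs_solve")
}

#' @export
print.gibbs_solve <- function(x, ...) {
  cat(sprintf("%s solve: %s after %g iterations\n", x$mode, x$status,
              x$iterations))
  worst <- suppressWarnings(max(x$violations, na.rm = TRUE))
  cat(sprintf("  worst constraint value sigma*dG = %.6g kJ/mol (feasible <= -eps)\n",
              worst))
  invisible(x)
}

#' Single MinOver update step
#'
#' Moves the potentials against the least satisfied constraint `r0`:
#' mu_i <- mu_i - lam * sigma_r0 * S_i,r0 on unclamped metabolites. The
#' updated constraint value decreases by exactly
#' lam * ||S^(r0)||^2 restricted to unclamped rows.
#'
#' @inheritParams least_satisfied
#' @param r0 index of the reaction to reinforce (sigma_r0 != 0).
#' @param lam step constant (> 0), kJ/mol.
#' @return updated [potential_vector()].
#' @export
minover_step <- function(network, sigma, mu, r0, lam = 0.1) {
  stopifnot(inherits(network, "reaction_network"), lam > 0,
            r0 >= 1, r0 <= ncol(network$S))
  sigma <- as.integer(sigma)
  if (sigma[r0] == 0L)
    stop_gibbscape("cannot update an unconstrained reaction (sigma = 0)",
                   "gibbscape_validation_error")
  mu <- .as_potential(mu, network)
  cl <- clamp_mask(mu)
  col <- network$S[, r0]
  col[cl] <- 0
  if (all(col == 0))
    stop_gibbscape(sprintf(
      "stall: reaction '%s' involves only clamped metabolites",
      network$reaction_ids[r0]), "gibbscape_stall_error")
  potential_vector(as.numeric(mu) - lam * sigma[r0] * col,
                   clamped = cl, metabolite_ids = network$metabolite_ids)
}

#' Solve the thermodynamic inequality system by MinOver
#'
#' Iterates: find the least satisfied constraint r0 = argmax sigma_r DeltaG_r;
#' if its value is <= -eps every constraint holds and the potentials are
#' thermodynamically consistent; otherwise take a fixed-size reinforcement
#' step against r0 and repeat. Convergence to a solution, when one with
#' positive margin exists, is guaranteed for any lam > 0. When the directions
#' hide an infeasible loop the least satisfied constraint cycles along the
#' loop forever; the returned tail of r0 indices then feeds [find_loop()].
#'
#' @inheritParams least_satisfied
#' @param mu0 starting potentials (clamp mask respected throughout).
#' @param control a [solver_control()].
#' @param bounds optional M x 2 matrix of per-metabolite box bounds
#'   (use -Inf/Inf for one-sided); encoded internally as extra
#'   single-variable inequality rows handled by the unmodified update.
#' @return object of class `gibbs_solve`: `status` ("FEASIBLE"/"MAX_ITERS"),
#'   `mu`, `iterations`, `r0_tail`, `tail_counts`, `counts_total`,
#'   `violations` (final sigma_r DeltaG_r per constrained reaction).
#' @export
#' @examples
#' net <- reaction_network(matrix(c(-1, 1, 0, 0, -1, 1), 3, 2,
#'                         dimnames = list(c("A", "B", "C"), c("r1", "r2"))))
#' fit <- minover_solve(net, c(1, 1), rep(0, 3))
#' fit$status  # FEASIBLE: a chain is always orientable
minover_solve <- function(network, sigma, mu0, control = solver_control(),
                          bounds = NULL) {
  .core_call(network, sigma, mu0, control, mode = 0L, bounds = bounds)
}

#' Solve by the Agmon-Motzkin relaxation method
#'
#' Same sweep as [minover_solve()] but the step size is proportional to the
#' amount by which the least satisfied constraint is violated:
#' mu <- mu - alpha * (sigma_r0 DeltaG_r0 / ||S^(r0)||^2) * sigma_r0 * S^(r0)
#' over unclamped rows. With alpha = 1 the targeted constraint lands exactly
#' on its boundary; alpha in (0, 2) guarantees convergence when a solution
#' exists.
#'
#' @inheritParams minover_solve
#' @export
relaxation_solve <- function(network, sigma, mu0, control = solver_control(),
                             bounds = NULL) {
  .core_call(network, sigma, mu0, control, mode = 1L, bounds = bounds)
}

#' Solve by a distance-penalty method
#'
#' Minimizes ||mu - mu0||^2 + beta * sum over violated reactions of
#' sigma_r DeltaG_r by gradient descent on the unclamped potentials,
#' restarting with beta <- beta + beta_step each time an inner minimum is
#' reached while violations remain. The returned solution is (up to the
#' descent tolerance) the Euclidean projection of the prior center mu0 onto
#' the feasible region — the distance-minimizing feasible potential vector,
#' against which MinOver's solutions are benchmarked.
#'
#' Constant-step subgradient descent chatters across the feasibility
#' boundary, so the step is halved whenever the iterate's feasibility status
#' oscillates; this diminishing-step schedule converges to the projection.
#'
#' @inheritParams minover_solve
#' @param mu0 the prior center; also the starting point.
#' @return object of class `gibbs_solve` (mode "penalty"), with `beta_final`.
#' @export
penalty_solve <- function(network, sigma, mu0, control = solver_control(),
                          bounds = NULL) {
  sigma_in <- as.integer(sigma)
  mu0 <- .as_potential(mu0, network)
  if (all(sigma_in == 0))
    stop_gibbscape("no constrained reactions: all directions are unassigned",
                   "gibbscape_validation_error")
  aug <- .augment_bounds(network, sigma_in, mu0, bounds)
  net <- aug$network; sig <- aug$sigma; mu0a <- aug$mu
  control <- .control_resolve(control, ncol(network$S))
  cl <- clamp_mask(mu0a)
  S <- net$S
  eps <- control$eps; eta0 <- control$eta
  beta <- control$beta0
  mu <- as.numeric(mu0a); mu0n <- as.numeric(mu0a)
  eta <- eta0
  t <- 0
  prev_violated <- NULL
  overflow <- 1e12 * max(1, sqrt(sum(mu0n^2)))
  repeat {
    v <- as.numeric(sig) * drop(crossprod(S, mu))
    violated <- sig != 0L & v > -eps
    feas_now <- !any(violated)
    grad <- (mu - mu0n)
    if (!feas_now)
      grad <- grad + beta * drop(S[, violated, drop = FALSE] %*%
                                   as.numeric(sig[violated]))
    grad[cl] <- 0
    step <- eta * grad
    step_norm <- sqrt(sum(step^2))
    if (step_norm < control$tol) {
      if (feas_now) { status <- "FEASIBLE"; break }
      # inner minimum reached while violations remain: raise the penalty
      beta <- beta + control$beta_step
      eta <- eta0
      prev_violated <- NULL
      t <- t + 1
      if (t >= control$max_iters) { status <- "MAX_ITERS"; break }
      next
    }
    if (t >= control$max_iters) { status <- "MAX_ITERS"; break }
    # the cost is piecewise smooth: whenever the active (violated) set flips,
    # the iterate straddles a hinge of the penalty term, and a constant step
    # would chatter there forever; a diminishing step converges instead
    if (!is.null(prev_violated) && any(violated != prev_violated))
      eta <- max(eta / 2, 1e-14)
    prev_violated <- violated
    mu <- mu - step
    if (sqrt(sum(mu^2)) > overflow)
      stop_gibbscape("penalty descent diverged; reduce eta",
                     "gibbscape_divergence_error")
    t <- t + 1
  }
  v <- as.numeric(sig) * drop(crossprod(S, mu))
  viol <- ifelse(sig == 0L, NA_real_, v)
  if (status == "MAX_ITERS" && !any(sig != 0L & v > -eps))
    status <- "FEASIBLE"
  mu_out <- potential_vector(mu[seq_len(aug$n_orig_m)],
                             clamped = clamp_mask(mu0),
                             metabolite_ids = network$metabolite_ids)
  structure(list(status = status, mu = mu_out, iterations = t,
                 r0_tail = integer(0), tail_counts = integer(ncol(net$S)),
                 counts_total = numeric(ncol(net$S)),
                 violations = setNames(viol, net$reaction_ids),
                 reaction_ids = net$reaction_ids,
                 n_reactions = aug$n_orig_r,
                 control = control, beta_final = beta, mode = "penalty"),
            class = "gibbs_solve")
}
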