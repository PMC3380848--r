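#' Fit thermodynamically consistent chemical potentials
#'
#' The main user-facing entry point: given a network, a direction assignment
#' and (optionally) a biochemical prior, draws a starting potential vector
#' from the prior and solves the second-law inequality system
#' sigma_r DeltaG_r <= -eps by the requested method. The result is a classed
#' fit object supporting `print`, `summary`, `coef` (the potentials),
#' `residuals` (the constraint values sigma_r DeltaG_r), `simulate`
#' (solutions from fresh prior draws) and `plot`.
#'
#' @param network a [reaction_network()].
#' @param sigma a [direction_assignment()] or plain -1/0/+1 vector.
#' @param prior optional [build_prior()] table; when given, the start is a
#'   uniform draw from the per-metabolite prior boxes and clamps are honored.
#' @param mu0 explicit starting potentials (overrides `prior`); default zeros.
#' @param method one of "minover", "relaxation", "penalty".
#' @param control a [solver_control()].
#' @param bounds optional M x 2 box-bound matrix, see [minover_solve()].
#' @param seed optional integer; makes the prior draw reproducible.
#' @return object of class `gibbs_fit`.
#' @export
#' @examples
#' net <- reaction_network(matrix(c(-1, 1, 0, 0, -1, 1), 3, 2,
#'                         dimnames = list(c("A", "B", "C"), c("r1", "r2"))))
#' fit <- fit_potentials(net, c(1, 1), seed = 1)
#' coef(fit)        # mu_A > mu_B > mu_C: energy decreases down the chain
#' residuals(fit)   # all <= -eps
fit_potentials <- function(network, sigma, prior = NULL, mu0 = NULL,
                           method = c("minover", "relaxation", "penalty"),
                           control = solver_control(), bounds = NULL,
                           seed = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(network, "reaction_network"))
  if (is.null(mu0)) {
    mu0 <- if (!is.null(prior)) sample_prior(prior, seed = seed)
           else potential_vector(numeric(nrow(network$S)),
                                 metabolite_ids = network$metabolite_ids)
  } else mu0 <- .as_potential(mu0, network)
  solver <- switch(method, minover = minover_solve,
                   relaxation = relaxation_solve, penalty = penalty_solve)
  res <- solver(network, sigma, mu0, control = control, bounds = bounds)
  structure(list(network = network, sigma = as.integer(sigma), prior = prior,
                 mu0 = mu0, method = method, result = res,
                 distance = distance_to_prior(res$mu, mu0), seed = seed),
            class = "gibbs_fit")
}

#' @export
print.gibbs_fit <- function(x, ...) {
  cat(sprintf("gibbs_fit (%s): %s\n", x$method, x$result$status))
  cat(sprintf("  %d metabolites, %d reactions (%d constrained)\n",
              nrow(x$network$S), ncol(x$network$S), sum(x$sigma != 0)))
  cat(sprintf("  iterations: %g; distance to prior: %.4g kJ/mol\n",
              x$result$iterations, x$distance))
  invisible(x)
}

#' @export
summary.gibbs_fit <- function(object, ...) {
  res <- object$result
  viol <- res$violations[seq_len(res$n_reactions)]
  out <- list(method = object$method, status = res$status,
              iterations = res$iterations, distance = object$distance,
              n_constrained = sum(object$sigma != 0),
              worst = suppressWarnings(max(viol, na.rm = TRUE)),
              mu_range = range(as.numeric(res$mu)),
              eps = res$control$eps)
  class(out) <- "summary.gibbs_fit"
  out
}

#' @export
print.summary.gibbs_fit <- function(x, ...) {
  cat(sprintf("Thermodynamic potential fit (%s)\n", x$method))
  cat(sprintf("  status: %s after %g iterations\n", x$status, x$iterations))
  cat(sprintf("  constrained reactions: %d; worst sigma*dG: %.6g kJ/mol (target <= -%g)\n",
              x$n_constrained, x$worst, x$eps))
  cat(sprintf("  potentials in [%.4g, %.4g] kJ/mol; distance to prior %.4g kJ/mol\n",
              x$mu_range[1], x$mu_range[2], x$distance))
  invisible(x)
}

#' @export
coef.gibbs_fit <- function(object, ...) object$result$mu

#' Constraint values of a fitted potential vector
#'
#' Returns sigma_r DeltaG_r per reaction (kJ/mol); negative means the second
#' law is respected for that reaction, `NA` marks unassigned reactions.
#' @param object a `gibbs_fit`.
#' @param ... unused.
#' @export
residuals.gibbs_fit <- function(object, ...) {
  res <- object$result
  res$violations[seq_len(res$n_reactions)]
}

#' Draw further solutions from fresh prior initializations
#'
#' Re-runs the solver `nsim` times from independent prior draws; the spread of
#' the resulting ensemble is the fit's picture of the solution space near the
#' prior (feed it to [potential_correlations()]).
#'
#' @param object a `gibbs_fit` fitted with a prior.
#' @param nsim number of solutions.
#' @param seed optional integer seed.
#' @param ... unused.
#' @return list of [potential_vector()]s (only FEASIBLE runs are kept; an
#'   attribute `status` records each run's outcome).
#' @export
simulate.gibbs_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (is.null(object$prior))
    stop_gibbscape("simulate needs a fit constructed with a prior",
                   "gibbscape_validation_error")
  seeds <- with_seed(seed, sample.int(.Machine$integer.max, nsim))
  runs <- lapply(seeds, function(s)
    fit_potentials(object$network, object$sigma, prior = object$prior,
                   method = object$method, control = object$result$control,
                   seed = s))
  status <- vapply(runs, function(f) f$result$status, character(1))
  sols <- lapply(runs[status == "FEASIBLE"], coef)
  attr(sols, "status") <- status
  sols
}

#' @export
plot.gibbs_fit <- function(x, ...) {
  dg <- gibbs_changes(x$network, coef(x))
  constrained <- x$sigma != 0
  graphics::plot(seq_along(dg), dg, pch = ifelse(constrained, 19, 1),
                 xlab = "reaction index", ylab = expression(Delta * G[r] ~ "(kJ/mol)"),
                 main = sprintf("Gibbs energy changes (%s fit)", x$method), ...)
  graphics::abline(h = 0, lty = 2)
  invisible(x)
}
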