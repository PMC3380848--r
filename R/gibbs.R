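#' Chemical potential vector
#'
#' Chemical potentials mu_i (kJ/mol), one per metabolite, with a clamp mask.
#' Clamped entries are held fixed by every solver (clamping sets the energy
#' scale and can bound the solution space).
#'
#' @param mu numeric vector of potentials, kJ/mol.
#' @param clamped logical vector, same length (default: nothing clamped).
#' @param metabolite_ids optional names.
#' @return numeric vector of class `potential_vector` with attribute `clamped`.
#' @export
potential_vector <- function(mu, clamped = NULL, metabolite_ids = NULL) {
  mu <- as.numeric(mu)
  if (!all(is.finite(mu)))
    stop_gibbscape("chemical potentials must be finite", "gibbscape_validation_error")
  if (is.null(clamped)) clamped <- rep(FALSE, length(mu))
  clamped <- as.logical(clamped)
  if (length(clamped) != length(mu) || anyNA(clamped))
    stop_gibbscape("clamp mask must be a logical vector matching mu",
                   "gibbscape_validation_error")
  if (!is.null(metabolite_ids)) names(mu) <- metabolite_ids
  structure(mu, clamped = clamped, class = "potential_vector")
}

#' @export
print.potential_vector <- function(x, ...) {
  cat(sprintf("potential_vector: %d metabolites (%d clamped), kJ/mol\n",
              length(x), sum(clamp_mask(x))))
  print(setNames(as.numeric(x), names(x)), ...)
  invisible(x)
}

#' Clamp mask of a potential vector
#' @param mu a [potential_vector()] or plain numeric (treated as unclamped).
#' @return logical vector.
#' @export
clamp_mask <- function(mu) {
  cl <- attr(mu, "clamped")
  if (is.null(cl)) rep(FALSE, length(mu)) else cl
}

.as_potential <- function(mu, network = NULL) {
  if (!inherits(mu, "potential_vector"))
    mu <- potential_vector(mu, metabolite_ids = names(mu))
  if (!is.null(network) && length(mu) != nrow(network$S))
    stop_gibbscape("potential vector length does not match number of metabolites",
                   "gibbscape_validation_error")
  mu
}

#' Gibbs energy changes of all reactions
#'
#' DeltaG_r = sum_i S_ir mu_i for every reaction r; linear in mu. At steady
#' state the second law requires sigma_r DeltaG_r < 0 for every operating
#' reaction, and for any steady-state flux vector v (S v = 0) the flux-weighted
#' sum of DeltaG vanishes (the "loop law").
#'
#' @param network a [reaction_network()].
#' @param mu chemical potentials (length M), kJ/mol.
#' @return named numeric vector of length N, kJ/mol.
#' @export
#' @examples
#' net <- reaction_network(matrix(c(-1, 1), 2, 1,
#'                                dimnames = list(c("A", "B"), "r1")))
#' gibbs_changes(net, c(5, 3))   # -2: A -> B is downhill
gibbs_changes <- function(network, mu) {
  stopifnot(inherits(network, "reaction_network"))
  if (length(mu) != nrow(network$S))
    stop_gibbscape("dimension mismatch between network and potentials",
                   "gibbscape_validation_error")
  drop(crossprod(network$S, as.numeric(mu)))
}

#' Least satisfied thermodynamic constraint
#'
#' Over the constrained reactions (sigma_r != 0), returns the index attaining
#' the largest sigma_r DeltaG_r — the constraint farthest from (or least deep
#' into) satisfaction. Unassigned reactions are excluded: their constraints
#' are absent. Ties go to the lowest reaction index, so reruns are
#' deterministic.
#'
#' @inheritParams gibbs_changes
#' @param sigma direction assignment (length N, in -1/0/+1).
#' @return list with `index` (integer), `reaction` (id) and `value`
#'   (sigma_r DeltaG_r, kJ/mol).
#' @export
least_satisfied <- function(network, sigma, mu) {
  dg <- gibbs_changes(network, mu)
  v <- as.numeric(sigma) * dg
  v[sigma == 0] <- -Inf
  if (all(sigma == 0))
    stop_gibbscape("no constrained reactions: all directions are unassigned",
                   "gibbscape_validation_error")
  r0 <- as.integer(which.max(v))  # first (lowest-index) maximum
  list(index = r0, reaction = network$reaction_ids[r0],
       value = unname(v[r0]))
}

#' Euclidean distance between a solution and its prior
#'
#' Computed over unclamped entries only (clamped potentials never move, so
#' they carry no information about how far the solver deformed the prior).
#'
#' @param mu,mu0 potential vectors of equal length; the clamp mask is taken
#'   from `mu`.
#' @return nonnegative scalar, kJ/mol.
#' @export
distance_to_prior <- function(mu, mu0) {
  if (length(mu) != length(mu0))
    stop_gibbscape("potential vectors differ in length", "gibbscape_validation_error")
  free <- !clamp_mask(mu)
  sqrt(sum((as.numeric(mu)[free] - as.numeric(mu0)[free])^2))
}

#' Empirical covariance of chemical potentials across solutions
#'
#' The connected correlations C_ij = <mu_i mu_j> - <mu_i><mu_j> estimated
#' from an ensemble of solutions (one per prior draw). The reinforcement
#' updates couple the potentials of metabolites sharing reactions, so the
#' ensemble covariance is an empirical diagnostic of how the network's
#' stoichiometry structures the solution space around the prior.
#'
#' @param solutions list of potential vectors of equal length (>= 2).
#' @return symmetric M x M covariance matrix.
#' @export
potential_correlations <- function(solutions) {
  if (!is.list(solutions) || length(solutions) < 2L)
    stop_gibbscape("need at least two solutions", "gibbscape_validation_error")
  lens <- lengths(solutions)
  if (length(unique(lens)) != 1L)
    stop_gibbscape("solutions differ in length", "gibbscape_validation_error")
  X <- do.call(rbind, lapply(solutions, as.numeric))
  C <- cov(X)
  (C + t(C)) / 2
}
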