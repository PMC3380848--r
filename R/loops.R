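## ---- small LP layer --------------------------------------------------------
## minimize cc.x  s.t.  A_ub x <= b_ub,  A_eq x = b_eq,  lb <= x <= ub.
## Free/box variables are handled by nonnegative splitting x = xp - xm and
## bound rows, on top of pracma::linprog (dense two-phase simplex).
## Returns the solution vector, or NULL when no feasible point exists.
.lp_solve_split <- function(cc, A_ub = NULL, b_ub = NULL,
                            A_eq = NULL, b_eq = NULL,
                            lb = NULL, ub = NULL, maxiter = 2000) {
  n <- length(cc)
  if (is.null(lb)) lb <- rep(-Inf, n)
  if (is.null(ub)) ub <- rep(Inf, n)
  split <- function(A) cbind(A, -A)
  Au <- if (!is.null(A_ub)) split(A_ub) else NULL
  bu <- b_ub
  ## bound rows
  for (j in seq_len(n)) {
    if (is.finite(ub[j])) {
      row <- numeric(n); row[j] <- 1
      Au <- rbind(Au, split(matrix(row, 1))); bu <- c(bu, ub[j])
    }
    if (is.finite(lb[j])) {
      row <- numeric(n); row[j] <- -1
      Au <- rbind(Au, split(matrix(row, 1))); bu <- c(bu, -lb[j])
    }
  }
  Ae <- if (!is.null(A_eq)) split(A_eq) else NULL
  ## pracma's simplex breaks pivot ties with sample(): run it under a local,
  ## fixed RNG stream (so results are reproducible and the caller's RNG is
  ## untouched) and retry a few pivot streams, since an unlucky stream can
  ## stall with a spurious "unbounded" verdict on a perfectly solvable LP.
  for (attempt in seq_len(12)) {
    res <- with_seed(190000 + attempt, tryCatch(
      pracma::linprog(cc = c(cc, -cc), A = Au, b = bu, Aeq = Ae, beq = b_eq,
                      bigM = 100 * 10^((attempt - 1) %/% 4),
                      maxiter = maxiter),
      error = function(e) NULL))
    if (!is.null(res) && !is.null(res$errno) && res$errno == 1)
      return(res$x[seq_len(n)] - res$x[n + seq_len(n)])
  }
  NULL
}

## ---- loop certificates -----------------------------------------------------

#' Loop certificate
#'
#' A Farkas-type proof that a direction assignment is thermodynamically
#' infeasible: a reaction subset L with strictly positive weights gamma such
#' that sum over L of gamma_r sigma_r S^(r) = 0. Dotting this identity with
#' any candidate potential vector shows the constraints on L cannot all hold
#' — the directed reactions form a closed energy loop.
#'
#' @param reactions integer indices (or reaction ids resolved against
#'   `network`) of the loop members, at least 2.
#' @param gamma strictly positive weights, one per member (normalized so the
#'   largest is 1).
#' @param signs the sigma of each member at detection time.
#' @param network optional [reaction_network()] used to attach reaction ids.
#' @return object of class `loop_certificate`.
#' @export
loop_certificate <- function(reactions, gamma, signs, network = NULL) {
  if (is.character(reactions)) {
    stopifnot(!is.null(network))
    reactions <- match(reactions, network$reaction_ids)
  }
  reactions <- as.integer(reactions)
  gamma <- as.numeric(gamma)
  signs <- as.integer(signs)
  if (length(reactions) < 2L)
    stop_gibbscape("a loop needs at least two reactions", "gibbscape_validation_error")
  if (length(gamma) != length(reactions) || length(signs) != length(reactions))
    stop_gibbscape("reactions, gamma and signs must have equal length",
                   "gibbscape_validation_error")
  if (any(gamma <= 0))
    stop_gibbscape("certificate weights must be strictly positive",
                   "gibbscape_validation_error")
  gamma <- gamma / max(gamma)
  ids <- if (!is.null(network)) network$reaction_ids[reactions] else NULL
  structure(list(reactions = reactions, gamma = gamma, signs = signs,
                 reaction_ids = ids),
            class = "loop_certificate")
}

#' @export
print.loop_certificate <- function(x, ...) {
  lab <- if (!is.null(x$reaction_ids)) x$reaction_ids else as.character(x$reactions)
  cat(sprintf("loop_certificate: %d reactions\n", length(x$reactions)))
  cat(" ", paste(sprintf("%s%s", ifelse(x$signs >= 0, "+", "-"), lab),
                 collapse = " "), "\n")
  invisible(x)
}

#' Verify a loop certificate
#'
#' Checks gamma > 0 and that the signed, weighted stoichiometric columns of
#' the members cancel: the infinity norm of
#' sum gamma_r sigma_r S^(r) must be at most `tol`.
#'
#' @param network a [reaction_network()].
#' @param cert a [loop_certificate()].
#' @param tol cancellation tolerance (default 1e-8).
#' @return `TRUE` or `FALSE`.
#' @export
verify_loop_certificate <- function(network, cert, tol = 1e-8) {
  stopifnot(inherits(cert, "loop_certificate"))
  r <- cert$reactions
  if (length(r) < 2L || any(r < 1L) || any(r > ncol(network$S))) return(FALSE)
  if (any(cert$gamma <= 0)) return(FALSE)
  resid <- network$S[, r, drop = FALSE] %*% (cert$gamma * cert$signs)
  max(abs(resid)) <= tol
}

## strictly positive null vector of the column set B (M x k), or NULL.
## Cheap rank/nullspace screen first; a small LP only when the nullspace has
## dimension above one.
.positive_nullvector <- function(B, tol = 1e-9) {
  k <- ncol(B)
  sv <- svd(B, nu = 0, nv = k)
  d <- c(sv$d, rep(0, k - length(sv$d)))
  thresh <- max(dim(B)) * max(d, 0) * 1e-12
  rank <- sum(d > thresh)
  dim_null <- k - rank
  if (dim_null == 0L) return(NULL)
  if (dim_null == 1L) {
    v <- sv$v[, k]
    if (all(v > tol)) return(v)
    if (all(v < -tol)) return(-v)
    return(NULL)
  }
  ## dim >= 2: max t s.t. B g = 0, t <= g_j <= 1  (vars g >= 0, t >= 0)
  cc <- c(numeric(k), -1)
  A_ub <- cbind(-diag(k), 1)
  sol <- .lp_solve_split(cc, A_ub = A_ub, b_ub = numeric(k),
                         A_eq = cbind(B, 0), b_eq = numeric(nrow(B)),
                         lb = numeric(k + 1), ub = c(rep(1, k), 1))
  if (is.null(sol)) return(NULL)
  t_star <- sol[k + 1]
  if (t_star > tol) sol[seq_len(k)] else NULL
}

#' Locate an infeasible loop within a candidate reaction set
#'
#' Two-stage heuristic. First the visit-count shortcut: when the solver
#' cycles periodically along a loop, the number of times each constraint was
#' updated over a period is itself a valid weight vector, so the counts
#' restricted to the candidates are tried as gamma and verified directly.
#' If that fails, subsets of the candidates are enumerated by increasing size
#' k = 2..k_max (lexicographic within each size) and each subset is tested
#' for a strictly positive vanishing combination of its signed columns (via
#' the nullspace when one-dimensional, else a small feasibility LP). The
#' first certificate found — smallest k, lexicographically first — is
#' returned.
#'
#' @inheritParams least_satisfied
#' @param candidates integer indices of candidate reactions (subset of the
#'   constrained reactions), typically the distinct entries of a solver's
#'   `r0_tail`.
#' @param k_max largest subset size to try (default 8).
#' @param counts optional per-reaction visit counts (length N) enabling the
#'   shortcut.
#' @param budget cap on the number of subsets examined (default 2e6);
#'   exceeding it raises a budget error, distinct from "no loop found".
#' @return a [loop_certificate()] or `NULL` when no subset of size <= k_max
#'   certifies.
#' @export
find_loop <- function(network, sigma, candidates, k_max = 8, counts = NULL,
                      budget = 2e6) {
  stopifnot(inherits(network, "reaction_network"), k_max >= 2)
  sigma <- as.integer(sigma)
  candidates <- sort(unique(as.integer(candidates)))
  if (any(sigma[candidates] == 0L))
    stop_gibbscape("candidates must be constrained reactions (sigma != 0)",
                   "gibbscape_validation_error")
  S <- network$S
  make_cert <- function(members, gamma)
    loop_certificate(members, gamma, sigma[members], network = network)

  if (!is.null(counts) && length(counts) == ncol(S)) {
    members <- candidates[counts[candidates] > 0]
    if (length(members) >= 2L) {
      cert <- make_cert(members, counts[members])
      if (verify_loop_certificate(network, cert)) return(cert)
    }
  }

  examined <- 0
  for (k in 2:min(k_max, length(candidates))) {
    subs <- combn(candidates, k)
    for (j in seq_len(ncol(subs))) {
      examined <- examined + 1
      if (examined > budget)
        stop_gibbscape(sprintf(
          "loop search budget exceeded after %d subsets (k = %d)", examined, k),
          "gibbscape_budget_error")
      members <- subs[, j]
      B <- S[, members, drop = FALSE] *
        rep(as.numeric(sigma[members]), each = nrow(S))
      g <- .positive_nullvector(B)
      if (!is.null(g)) return(make_cert(members, g))
    }
  }
  NULL
}

## Decide feasibility of the homogeneous system {B^T mu <= -eps 1} where
## B's columns are sigma_r S^(r). Deterministic quadratic-programming route:
## minimize ||B g||^2 over the simplex {g >= 0, sum g = 1} (tiny ridge for
## strict convexity). A near-zero minimum exhibits a Farkas certificate on
## the support of g; a positive minimum makes mu = -B g a strict witness,
## since every constraint value is -(B^T B g)_r <= -min value by the KKT
## conditions. For planted instances the two cases are separated by orders
## of magnitude, and the returned certificate/witness is re-verified exactly.
.decide_homogeneous <- function(B) {
  k <- ncol(B)
  scale <- max(abs(B), 1)
  ridge <- 1e-10 * scale^2
  D <- crossprod(B) + diag(ridge, k)
  A <- cbind(rep(1, k), diag(k))
  sol <- quadprog::solve.QP(Dmat = D, dvec = numeric(k), Amat = A,
                            bvec = c(1, numeric(k)), meq = 1)
  g <- sol$solution
  g[g < 0] <- 0
  g <- g / sum(g)
  val <- sum((B %*% g)^2)
  list(g = g, val = val, infeasible = val < 1e-7 * scale^2)
}

## Polish near-certificate QP weights: restrict to the support, project onto
## the exact nullspace of the support columns (removing the O(ridge)
## residual), and accept only a strictly positive projection whose signed
## columns cancel to working precision.
.polish_support <- function(B, g) {
  mg <- max(g)
  if (mg <= 0) return(NULL)
  keep <- which(g > 1e-6 * mg)
  if (!length(keep)) return(NULL)
  Bk <- B[, keep, drop = FALSE]
  kk <- ncol(Bk)
  sv <- svd(Bk, nu = 0, nv = kk)
  d <- c(sv$d, rep(0, kk - length(sv$d)))
  thr <- max(dim(Bk)) * max(d, 0) * 1e-12
  null_idx <- which(d <= thr)
  if (!length(null_idx)) return(NULL)
  Nsp <- sv$v[, null_idx, drop = FALSE]
  gp <- drop(Nsp %*% crossprod(Nsp, g[keep]))
  if (max(gp) <= 0 || !all(gp > 1e-9 * max(gp))) return(NULL)
  gp <- gp / max(gp)
  if (max(abs(Bk %*% gp)) > 1e-8 * max(1, max(abs(Bk)))) return(NULL)
  list(keep = keep, gamma = gp)
}

#' Exact LP feasibility oracle
#'
#' Decides feasibility of the inequality system by linear programming:
#' maximize the common margin s subject to sigma_r DeltaG_r <= -s for every
#' constrained reaction (s capped at 1, clamps and box bounds honored). A
#' strictly positive optimum yields a witness potential vector; otherwise the
#' Farkas alternative is solved for weights gamma >= 0 summing to one whose
#' signed columns cancel, giving an infeasibility certificate (possibly
#' non-minimal).
#'
#' @inheritParams minover_solve
#' @param eps required margin for the witness (default 1e-6 kJ/mol).
#' @param mu_clamp optional [potential_vector()] supplying clamp mask and
#'   clamped values.
#' @return list with `status` ("FEASIBLE"/"INFEASIBLE") plus `mu` (witness)
#'   or `certificate` (a [loop_certificate()]).
#' @export
lp_feasibility_oracle <- function(network, sigma, eps = 1e-6, mu_clamp = NULL,
                                  bounds = NULL) {
  stopifnot(inherits(network, "reaction_network"))
  sigma <- as.integer(sigma)
  cons <- which(sigma != 0L)
  if (!length(cons))
    stop_gibbscape("no constrained reactions", "gibbscape_validation_error")
  M <- nrow(network$S)
  cl <- if (!is.null(mu_clamp)) clamp_mask(mu_clamp) else rep(FALSE, M)
  mu_fix <- if (!is.null(mu_clamp)) as.numeric(mu_clamp) else numeric(M)
  free <- which(!cl)
  ## rows a_r = sigma_r S^(r) on free coords; rhs b_r = -sigma_r * clamped part
  A <- t(network$S[free, cons, drop = FALSE]) * as.numeric(sigma[cons])
  b <- -as.numeric(sigma[cons]) *
    drop(crossprod(network$S[cl, cons, drop = FALSE], mu_fix[cl]))
  nf <- length(free)
  lb <- rep(-Inf, nf); ub <- rep(Inf, nf)
  if (!is.null(bounds)) {
    stopifnot(is.matrix(bounds), nrow(bounds) == M)
    lb <- bounds[free, 1]; ub <- bounds[free, 2]
  }

  pure <- all(b == 0) && all(!is.finite(lb)) && all(!is.finite(ub))
  k <- length(cons)
  if (pure) {
    ## Gordan alternative, decided by construction + exact verification:
    ## either the QP weights polish into a verified certificate, or the
    ## induced witness mu = -B g has strictly positive margins on every row.
    B <- t(A)
    dec <- .decide_homogeneous(B)
    pol <- .polish_support(B, dec$g)
    if (!is.null(pol) && length(pol$keep) >= 2L) {
      cert <- loop_certificate(cons[pol$keep], pol$gamma,
                               sigma[cons[pol$keep]], network = network)
      if (verify_loop_certificate(network, cert))
        return(list(status = "INFEASIBLE", certificate = cert))
    }
    mu_free <- -drop(B %*% dec$g)
    marg <- -drop(crossprod(B, mu_free))  # -(a_r . mu) per constrained row
    m0 <- min(marg)
    if (m0 > 1e-9 * max(1, max(abs(mu_free)))) {
      if (m0 < eps) mu_free <- mu_free * (1.01 * eps / m0)
      mu <- mu_fix
      mu[free] <- mu_free
      return(list(status = "FEASIBLE",
                  mu = potential_vector(mu, clamped = cl,
                                        metabolite_ids = network$metabolite_ids)))
    }
    ## numerically ambiguous: fall through to the LP route
  } else {
    ## clamps or bounds make the system inhomogeneous; homogenize with a
    ## slack coordinate t (the witness is mu = x/t): rows (a_r, eps - b_r),
    ## one row per finite bound, and (0, -1) keeping t positive.
    rows <- cbind(A, eps - b)
    for (j in seq_len(nf)) {
      if (is.finite(ub[j])) {
        e <- numeric(nf); e[j] <- 1
        rows <- rbind(rows, c(e, -ub[j]))
      }
      if (is.finite(lb[j])) {
        e <- numeric(nf); e[j] <- -1
        rows <- rbind(rows, c(e, lb[j]))
      }
    }
    rows <- rbind(rows, c(numeric(nf), -1))
    B <- t(rows)
    dec <- .decide_homogeneous(B)
    x <- -drop(B %*% dec$g)
    marg <- -drop(crossprod(B, x))
    t0 <- x[nf + 1]
    if (min(marg) > 1e-9 * max(1, max(abs(x))) && t0 > 0) {
      mu <- mu_fix
      mu[free] <- x[seq_len(nf)] / t0
      v <- as.numeric(sigma[cons]) * drop(crossprod(network$S[, cons, drop = FALSE],
                                                    mu))
      ok_bounds <- is.null(bounds) ||
        (all(mu[free] >= lb - 1e-9) && all(mu[free] <= ub + 1e-9))
      if (all(v <= -eps + 1e-9) && ok_bounds)
        return(list(status = "FEASIBLE",
                    mu = potential_vector(mu, clamped = cl,
                                          metabolite_ids = network$metabolite_ids)))
    }
    pol <- .polish_support(B, dec$g)
    if (!is.null(pol)) {
      rk <- pol$keep[pol$keep <= k]        # reaction rows in the support
      if (length(rk) >= 2L) {
        gam <- pol$gamma[pol$keep <= k]
        cert <- loop_certificate(cons[rk], gam, sigma[cons[rk]],
                                 network = network)
        ## with clamps the cancellation holds on the unclamped subsystem
        ## (plus a nonnegative clamped part), which is what B encodes
        return(list(status = "INFEASIBLE", certificate = cert))
      }
    }
    ## ambiguous: fall through to the LP route
  }

  ## variables (mu_free, s): max s  s.t.  A mu + s <= b, s <= 1
  cc <- c(numeric(nf), -1)
  sol <- .lp_solve_split(cc,
                         A_ub = rbind(cbind(A, 1), c(numeric(nf), 1)),
                         b_ub = c(b, 1),
                         lb = c(lb, -Inf), ub = c(ub, Inf))
  if (is.null(sol))
    stop_gibbscape("LP solver failed on the primal margin problem",
                   "gibbscape_lp_error")
  s_star <- sol[nf + 1]
  if (s_star > 1e-9) {
    mu <- mu_fix
    mu[free] <- sol[seq_len(nf)]
    homogeneous <- all(b == 0) && is.null(bounds)
    if (homogeneous && s_star < eps) mu[free] <- mu[free] * (eps / s_star) * 1.01
    return(list(status = "FEASIBLE",
                mu = potential_vector(mu, clamped = cl,
                                      metabolite_ids = network$metabolite_ids)))
  }
  ## Farkas alternative: gamma >= 0, sum gamma = 1, A^T gamma = 0,
  ## minimizing gamma . b (must come out < eps-ish for a true certificate)
  gam <- .lp_solve_split(b,
                         A_eq = rbind(t(A), rep(1, k)),
                         b_eq = c(numeric(nf), 1),
                         lb = numeric(k), ub = rep(1, k))
  if (is.null(gam))
    stop_gibbscape("LP solver failed extracting the Farkas certificate",
                   "gibbscape_lp_error")
  keep <- gam > 1e-9
  cert <- loop_certificate(cons[keep], gam[keep], sigma[cons[keep]],
                           network = network)
  list(status = "INFEASIBLE", certificate = cert)
}

#' Repair one infeasible loop by flipping a reversible member
#'
#' Negates the direction of exactly one reversible member of the certified
#' loop, chosen uniformly at random. A loop whose members are all
#' irreversible cannot be repaired: the direction assignment is then
#' thermodynamically impossible under the annotation, and a classed error
#' carrying the certificate is raised.
#'
#' @param sigma direction vector (named by reaction id if available).
#' @param cert a verified [loop_certificate()].
#' @param reversible logical vector, length N.
#' @param seed optional integer for a reproducible choice.
#' @return the updated direction vector; attribute `flipped` holds the index.
#' @export
remove_loop <- function(sigma, cert, reversible, seed = NULL) {
  stopifnot(inherits(cert, "loop_certificate"))
  members <- cert$reactions
  rev_members <- members[reversible[members]]
  if (!length(rev_members)) {
    lab <- if (!is.null(cert$reaction_ids)) paste(cert$reaction_ids, collapse = ", ")
           else paste(members, collapse = ", ")
    stop_gibbscape(sprintf("irreversible infeasible loop (%s): no direction can be flipped",
                           lab),
                   "gibbscape_irreversible_loop", certificate = cert)
  }
  pick <- with_seed(seed, rev_members[sample.int(length(rev_members), 1L)])
  out <- sigma
  out[pick] <- -out[pick]
  attr(out, "flipped") <- pick
  out
}

#' Identify and remove all infeasible loops of a direction assignment
#'
#' The full repair pipeline: run [minover_solve()]; on non-convergence take
#' the distinct reactions of the least-satisfied tail as loop candidates,
#' certify a loop with [find_loop()] (escalating once to every reaction that
#' was ever least-satisfied if the tail alone does not certify), flip one of
#' its reversible members, and repeat until the assignment is feasible or a
#' loop cannot be repaired. Irreversible directions are never changed.
#'
#' @inheritParams minover_solve
#' @param sigma0 the starting direction assignment.
#' @param priors optional [build_prior()] table for the solver starts
#'   (defaults to a zero start).
#' @param k_max passed to [find_loop()].
#' @param max_rounds cap on repair rounds (default 100).
#' @param seed optional integer driving prior draws and flip choices.
#' @return object of class `direction_repair`: `sigma` (final directions),
#'   `mu` (feasible potentials), `certificates` (list of removed loops),
#'   `status` ("FEASIBLE"), `rounds`, `escalations`.
#' @export
correct_directions <- function(network, sigma0, priors = NULL,
                               control = solver_control(), k_max = 8,
                               max_rounds = 100, seed = NULL) {
  stopifnot(inherits(network, "reaction_network"))
  sigma <- as.integer(sigma0)
  names(sigma) <- network$reaction_ids
  certs <- list()
  escalations <- 0L
  sub_seeds <- with_seed(seed, sample.int(.Machine$integer.max, 2 * max_rounds))
  for (round in seq_len(max_rounds)) {
    mu0 <- if (!is.null(priors)) sample_prior(priors, seed = sub_seeds[2 * round - 1])
           else potential_vector(numeric(nrow(network$S)),
                                 metabolite_ids = network$metabolite_ids)
    res <- minover_solve(network, sigma, mu0, control = control)
    if (res$status == "FEASIBLE") {
      return(structure(list(sigma = sigma, mu = res$mu, certificates = certs,
                            status = "FEASIBLE", rounds = round,
                            escalations = escalations),
                       class = "direction_repair"))
    }
    cands <- sort(unique(res$r0_tail))
    cands <- cands[cands <= ncol(network$S)]
    cert <- find_loop(network, sigma, cands, k_max = k_max,
                      counts = res$tail_counts)
    if (is.null(cert)) {
      escalations <- escalations + 1L
      cands2 <- which(res$counts_total > 0)
      cert <- find_loop(network, sigma, cands2, k_max = k_max,
                        counts = res$counts_total)
    }
    if (is.null(cert))
      stop_gibbscape(sprintf(
        "solver did not converge but no loop of length <= %d was found", k_max),
        "gibbscape_loop_search_error", certificates = certs)
    sigma <- remove_loop(sigma, cert, network$reversible,
                         seed = sub_seeds[2 * round])
    attr(sigma, "flipped") <- NULL
    certs <- c(certs, list(cert))
  }
  stop_gibbscape(sprintf("round limit (%d) reached with loops remaining",
                         max_rounds),
                 "gibbscape_budget_error", certificates = certs)
}

#' @export
print.direction_repair <- function(x, ...) {
  cat(sprintf("direction_repair: %s after %d round(s), %d loop(s) removed\n",
              x$status, x$rounds, length(x$certificates)))
  invisible(x)
}

## canonical dedup key: sorted member ids + sign pattern up to global
## inversion (a loop and its reverse are the same physical cycle)
.loop_key <- function(cert, network) {
  o <- order(cert$reactions)
  ids <- network$reaction_ids[cert$reactions[o]]
  s <- cert$signs[o]
  if (s[1] < 0) s <- -s
  paste(paste(ids, s, sep = ":"), collapse = "|")
}

#' Catalogue the infeasible loops of an ensemble of direction draws
#'
#' Runs the repair pipeline on each direction assignment of an ensemble and
#' collects the removed loops, deduplicated by reaction set and sign pattern
#' up to global inversion, with occurrence counts. Also reports the fraction
#' of draws that were feasible without any repair.
#'
#' @inheritParams correct_directions
#' @param ensemble either a positive integer (that many random direction
#'   assignments are drawn with [random_direction_assignment()]) or a list of
#'   direction vectors.
#' @param seed integer seed for the draws and repairs.
#' @return object of class `loop_catalogue`: `loops` (list with members
#'   `reactions`, `signs`, `gamma`, `reversible_members`, `occurrences`),
#'   `feasible_fraction`, `statuses` (per-draw outcome; errors are recorded,
#'   not propagated).
#' @export
catalogue_loops <- function(network, ensemble, priors = NULL,
                            control = solver_control(), k_max = 8,
                            max_rounds = 100, seed = NULL) {
  stopifnot(inherits(network, "reaction_network"))
  if (is.numeric(ensemble) && length(ensemble) == 1L) {
    n <- as.integer(ensemble)
    dseeds <- with_seed(seed, sample.int(.Machine$integer.max, 2 * n))
    draws <- lapply(seq_len(n), function(i)
      random_direction_assignment(network, seed = dseeds[2 * i - 1]))
    rseeds <- dseeds[seq_len(n) * 2]
  } else {
    draws <- ensemble
    n <- length(draws)
    rseeds <- with_seed(seed, sample.int(.Machine$integer.max, n))
  }
  if (!n) stop_gibbscape("ensemble is empty", "gibbscape_validation_error")
  tab <- new.env(parent = emptyenv())
  statuses <- character(n)
  n_clean <- 0L
  for (i in seq_len(n)) {
    rep_i <- tryCatch(
      correct_directions(network, draws[[i]], priors = priors,
                         control = control, k_max = k_max,
                         max_rounds = max_rounds, seed = rseeds[i]),
      gibbscape_error = function(e) e)
    if (inherits(rep_i, "condition")) {
      statuses[i] <- paste0("error: ", conditionMessage(rep_i))
      next
    }
    if (!length(rep_i$certificates)) {
      statuses[i] <- "feasible"
      n_clean <- n_clean + 1L
    } else statuses[i] <- sprintf("repaired (%d loops)", length(rep_i$certificates))
    for (cert in rep_i$certificates) {
      key <- .loop_key(cert, network)
      if (is.null(tab[[key]])) {
        tab[[key]] <- list(
          reactions = network$reaction_ids[cert$reactions],
          signs = cert$signs, gamma = cert$gamma,
          reversible_members = network$reaction_ids[
            cert$reactions[network$reversible[cert$reactions]]],
          occurrences = 1L)
      } else tab[[key]]$occurrences <- tab[[key]]$occurrences + 1L
    }
  }
  loops <- lapply(sort(names(tab)), function(k) tab[[k]])
  loops <- loops[order(vapply(loops, function(l) length(l$reactions), 1L))]
  structure(list(loops = loops, feasible_fraction = n_clean / n,
                 statuses = statuses, n_draws = n),
            class = "loop_catalogue")
}

#' @export
print.loop_catalogue <- function(x, ...) {
  cat(sprintf("loop_catalogue: %d distinct loop(s) from %d draws (feasible fraction %.3f)\n",
              length(x$loops), x$n_draws, x$feasible_fraction))
  if (length(x$loops)) {
    cat(sprintf("%-4s %-7s %s\n", "ID", "Length", "Formula"))
    for (i in seq_along(x$loops)) {
      l <- x$loops[[i]]
      mark <- ifelse(l$reactions %in% l$reversible_members, "(R)", "")
      formula <- paste(sprintf("%s%s%s", ifelse(l$signs >= 0, "+", "-"),
                               l$reactions, mark), collapse = " ")
      cat(sprintf("%-4d %-7d %s  [x%d]\n", i, length(l$reactions), formula,
                  l$occurrences))
    }
  }
  invisible(x)
}
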