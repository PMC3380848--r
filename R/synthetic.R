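#' Generate a random sparse stoichiometric network
#'
#' Coefficients are drawn from a small signed-integer alphabet so certificate
#' arithmetic is numerically trivial and survives TSV round-trips exactly.
#' Every reaction column is guaranteed at least one nonzero coefficient.
#'
#' @param M,N numbers of metabolites and reactions.
#' @param density expected fraction of nonzero coefficients per column,
#'   in (0, 1].
#' @param coeff_values alphabet of nonzero coefficients
#'   (default \{-2, -1, 1, 2\}).
#' @param reversible_fraction probability that a reaction is flagged
#'   reversible.
#' @param seed optional integer seed; generation is a pure function of the
#'   arguments and the seed.
#' @return a [reaction_network()].
#' @export
#' @examples
#' net <- generate_network(5, 6, seed = 1)
generate_network <- function(M, N, density = 0.3,
                             coeff_values = c(-2, -1, 1, 2),
                             reversible_fraction = 0.5, seed = NULL) {
  stopifnot(M >= 1, N >= 1, density > 0, density <= 1,
            length(coeff_values) >= 2, all(coeff_values != 0),
            reversible_fraction >= 0, reversible_fraction <= 1)
  if (density * M < 0.5)
    stop_gibbscape("density too low to give every reaction a nonzero column",
                   "gibbscape_validation_error")
  with_seed(seed, {
    S <- matrix(0, M, N)
    for (r in seq_len(N)) {
      k <- max(1L, rbinom(1L, M, density))
      rows <- sample.int(M, k)
      S[rows, r] <- sample(coeff_values, k, replace = TRUE)
    }
    reversible <- rbinom(N, 1L, reversible_fraction) == 1L
    reaction_network(S, reversible = reversible,
                     metabolite_ids = sprintf("m%03d", seq_len(M)),
                     reaction_ids = sprintf("r%03d", seq_len(N)))
  })
}

#' Plant a feasible direction assignment with known margin
#'
#' Draws a witness potential vector mu*, orients every reaction downhill
#' (sigma_r = -sign(DeltaG_r(mu*))) and resamples mu* coordinates until every
#' reaction has |DeltaG_r| >= margin. By construction the assignment admits a
#' solution with margin at least `margin`, so the MinOver convergence
#' guarantee applies.
#'
#' @param network a [reaction_network()].
#' @param margin required margin c > 0, kJ/mol.
#' @param mu_scale half-width of the uniform distribution the witness is
#'   drawn from (kJ/mol, default 10).
#' @param seed optional integer seed.
#' @param max_tries resampling budget (default 1000).
#' @return list with `sigma` (direction vector, no zeros) and `mu_star`
#'   (the witness [potential_vector()]).
#' @export
plant_feasible_directions <- function(network, margin = 1, mu_scale = 10,
                                      seed = NULL, max_tries = 1000) {
  stopifnot(inherits(network, "reaction_network"), margin > 0, mu_scale > 0)
  with_seed(seed, {
    M <- nrow(network$S)
    mu <- runif(M, -mu_scale, mu_scale)
    for (try in seq_len(max_tries)) {
      dg <- gibbs_changes(network, mu)
      bad <- abs(dg) < margin
      if (!any(bad)) break
      touched <- which(rowSums(abs(network$S[, bad, drop = FALSE])) > 0)
      mu[touched] <- runif(length(touched), -mu_scale, mu_scale)
      if (try == max_tries)
        stop_gibbscape("could not plant the requested margin; reduce `margin` or increase `mu_scale`",
                       "gibbscape_budget_error")
    }
    dg <- gibbs_changes(network, mu)
    sigma <- as.integer(-sign(dg))
    names(sigma) <- network$reaction_ids
    list(sigma = sigma,
         mu_star = potential_vector(mu, metabolite_ids = network$metabolite_ids))
  })
}

#' Plant a directed loop with a known certificate
#'
#' Appends k reactions over k fresh metabolites forming a directed cycle:
#' column j consumes cycle metabolite j and produces metabolite j+1 (mod k),
#' so with all planted directions forward the signed columns cancel with
#' gamma = (1, ..., 1). Fresh metabolites make the planted certificate the
#' unique minimal loop involving the new reactions, which keeps ground-truth
#' recovery tests exact.
#'
#' @param network base [reaction_network()].
#' @param sigma base direction vector (length N).
#' @param k loop length (>= 2).
#' @param reversible logical vector of length k (or scalar): reversibility of
#'   the planted reactions.
#' @return list with `network` (augmented), `sigma` (augmented; planted
#'   members forward) and `certificate` (the exact [loop_certificate()]).
#' @export
plant_loop <- function(network, sigma, k = 3, reversible = TRUE) {
  stopifnot(inherits(network, "reaction_network"), k >= 2)
  reversible <- rep_len(as.logical(reversible), k)
  M <- nrow(network$S); N <- ncol(network$S)
  loop_m <- sprintf("loopm%02d_%d", seq_len(k), N)
  loop_r <- sprintf("loopr%02d_%d", seq_len(k), N)
  S2 <- rbind(network$S, matrix(0, k, N))
  cols <- matrix(0, M + k, k)
  for (j in seq_len(k)) {
    cols[M + j, j] <- -1
    cols[M + (j %% k) + 1L, j] <- 1
  }
  S2 <- cbind(S2, cols)
  net2 <- reaction_network(S2,
                           reversible = c(network$reversible, reversible),
                           metabolite_ids = c(network$metabolite_ids, loop_m),
                           reaction_ids = c(network$reaction_ids, loop_r))
  sigma2 <- c(as.integer(sigma), rep(1L, k))
  names(sigma2) <- net2$reaction_ids
  cert <- loop_certificate(N + seq_len(k), rep(1, k), rep(1L, k),
                           network = net2)
  list(network = net2, sigma = sigma2, certificate = cert)
}

#' Random direction assignment under the reversibility annotation
#'
#' Irreversible reactions keep their annotated forward direction; every
#' reversible reaction is set to +1 or -1 independently with probability 1/2.
#' No reaction is left unassigned: all reactions are treated as operating,
#' the worst case for thermodynamic feasibility.
#'
#' @param network a [reaction_network()].
#' @param seed optional integer seed.
#' @return integer direction vector named by reaction id.
#' @export
random_direction_assignment <- function(network, seed = NULL) {
  stopifnot(inherits(network, "reaction_network"))
  with_seed(seed, {
    sigma <- rep(1L, ncol(network$S))
    nrev <- sum(network$reversible)
    if (nrev) sigma[network$reversible] <- sample(c(-1L, 1L), nrev, replace = TRUE)
    names(sigma) <- network$reaction_ids
    sigma
  })
}

#' Random desk-scale test instance with known ground truth
#'
#' Convenience factory for validation studies: draws a small random sparse
#' network (8-20 metabolites, 10-25 reactions) and either plants a feasible
#' direction assignment with the requested margin, or additionally plants a
#' directed loop (which makes the assignment provably infeasible, with the
#' exact certificate returned).
#'
#' @param seed integer seed; the instance is a pure function of the arguments.
#' @param kind "feasible" or "loop".
#' @param margin planted feasibility margin for the base assignment, kJ/mol.
#' @param loop_k planted loop length (kind = "loop").
#' @param loop_reversible reversibility pattern of the planted loop members
#'   (scalar or length `loop_k`).
#' @return list with `network`, `sigma`, `mu_star` (witness for the base
#'   part), `certificate` (`NULL` for feasible instances) and `kind`.
#' @export
random_instance <- function(seed, kind = c("feasible", "loop"), margin = 1,
                            loop_k = 3, loop_reversible = TRUE) {
  kind <- match.arg(kind)
  with_seed(seed, {
    M <- sample(8:20, 1)
    N <- sample(10:25, 1)
    net <- generate_network(M, N, density = 0.3, reversible_fraction = 0.5)
    planted <- plant_feasible_directions(net, margin = margin)
    sigma <- planted$sigma
    cert <- NULL
    if (kind == "loop") {
      aug <- plant_loop(net, sigma, k = loop_k, reversible = loop_reversible)
      net <- aug$network
      sigma <- aug$sigma
      cert <- aug$certificate
    }
    list(network = net, sigma = sigma, mu_star = planted$mu_star,
         certificate = cert, kind = kind)
  })
}

#' Red-blood-cell-scale fixture with a biochemical prior
#'
#' Emulates, at desk scale, the setting of a small metabolic network studied
#' with a thermodynamic prior: 35 metabolites and 40 reactions, a prior table
#' in which roughly half the metabolites carry formation energies plus
#' measured concentration ranges (spanning two standard deviations), the
#' rest formation energies only (four concentration decades), and one
#' water-like metabolite whose chemical potential is clamped to set the
#' energy scale. Directions are planted downhill of a witness drawn from the
#' prior itself and sharpened to the requested margin, so the assignment is
#' feasible by construction while the prior stays realistically informative.
#'
#' @param seed integer seed.
#' @param M,N network size (defaults 35 and 40).
#' @param margin planted margin, kJ/mol (default 0.5).
#' @return list with `network`, `prior_table`, `priors` (a
#'   [build_prior()] result), `sigma` and `mu_witness`.
#' @export
hrbc_scale_fixture <- function(seed, M = 35, N = 40, margin = 0.5) {
  with_seed(seed, {
    for (attempt in 1:20) {
      net <- generate_network(M, N, density = 0.12,
                              coeff_values = c(-2, -1, 1, 2),
                              reversible_fraction = 0.1)
      has_conc <- c(FALSE, rbinom(M - 1, 1, 0.5) == 1)  # row 1 is "water"
      conc <- ifelse(has_conc, 10^runif(M, -5, -2), NA_real_)
      tab <- data.frame(metabolite_id = net$metabolite_ids,
                        dGf0 = round(runif(M, -400, 0), 1),
                        conc_center = conc,
                        conc_sd = ifelse(has_conc, conc / 4, NA_real_),
                        clamp = c(TRUE, rep(FALSE, M - 1)))
      priors <- build_prior(net, tab)
      mu <- as.numeric(sample_prior(priors))
      ok <- FALSE
      for (try in 1:500) {
        dg <- gibbs_changes(net, mu)
        bad <- abs(dg) < margin
        if (!any(bad)) { ok <- TRUE; break }
        touched <- which(rowSums(abs(net$S[, bad, drop = FALSE])) > 0 &
                           !priors$clamp)
        if (!length(touched)) break  # offending reactions are fully clamped
        mu[touched] <- priors$mu_center[touched] +
          runif(length(touched), -1, 1) * pmax(priors$mu_halfwidth[touched], 1)
      }
      if (!ok) next
      sigma <- as.integer(-sign(gibbs_changes(net, mu)))
      names(sigma) <- net$reaction_ids
      return(list(network = net, prior_table = tab, priors = priors,
                  sigma = sigma,
                  mu_witness = potential_vector(mu, clamped = priors$clamp,
                                                metabolite_ids = net$metabolite_ids)))
    }
    stop_gibbscape("could not construct a feasible prior-consistent fixture",
                   "gibbscape_budget_error")
  })
}
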