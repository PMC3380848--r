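#' Chemical potential of a dilute solute
#'
#' mu = dGf0 + RT ln(c / c0) with reference concentration c0 = 1 M: the
#' dilute-solution relation linking the standard Gibbs energy of formation
#' and the intracellular concentration to the chemical potential.
#'
#' @param dGf0 standard Gibbs energy of formation, kJ/mol.
#' @param c concentration, molar (> 0).
#' @param temperature kelvin.
#' @return chemical potential, kJ/mol.
#' @export
#' @examples
#' mu_from_concentration(-100, 1e-3)  # -117.124 kJ/mol
mu_from_concentration <- function(dGf0, c, temperature = 298.15) {
  if (any(c <= 0))
    stop_gibbscape("concentration must be positive", "gibbscape_domain_error")
  dGf0 + rt_energy(temperature) * log(c)
}

#' Concentration implied by a chemical potential
#'
#' Exact inverse of [mu_from_concentration()]: c = c0 exp((mu - dGf0) / RT).
#'
#' @param dGf0 standard Gibbs energy of formation, kJ/mol.
#' @param mu chemical potential, kJ/mol.
#' @param temperature kelvin.
#' @return concentration, molar.
#' @export
concentration_from_mu <- function(dGf0, mu, temperature = 298.15) {
  z <- (mu - dGf0) / rt_energy(temperature)
  if (any(abs(z) > 700))
    stop_gibbscape("mu - dGf0 too large: exp() would overflow",
                   "gibbscape_domain_error")
  exp(z)
}

#' Build per-metabolite trial distributions for the chemical potentials
#'
#' Turns a table of formation energies and concentration ranges into the
#' uniform prior boxes that initialize the solvers:
#' * metabolites with both `dGf0` and concentration statistics get a box
#'   centered at mu(conc_center) whose endpoints are the dilute-solution map
#'   of `conc_center - 2 sd` and `conc_center + 2 sd` (the span covers two
#'   standard deviations in concentration; the asymmetric mu-interval is
#'   symmetrized by taking half its width);
#' * metabolites with `dGf0` only are centered at mu(`default_conc`) and span
#'   `decades` orders of magnitude of concentration uniformly on the
#'   chemical-potential scale (halfwidth = decades/2 * RT ln 10);
#' * clamped metabolites (e.g. water, which sets the energy scale) get
#'   halfwidth 0 and are held fixed by every solver.
#'
#' @param network a [reaction_network()].
#' @param prior_table data frame with columns `metabolite_id`, `dGf0`
#'   (kJ/mol, NA if unknown), `conc_center`, `conc_sd` (molar, NA if unknown)
#'   and `clamp` (logical / 0-1). Metabolites absent from the table are an
#'   error unless the policy provides an unknown-metabolite center.
#' @param policy list: `default_conc` (molar, used when concentration data is
#'   missing; default 1e-3 M), `decades` (default 4), `temperature` (K),
#'   `span_in_concentration` (default `TRUE`: the two-sd span is symmetric in
#'   concentration and mapped through the dilute-solution relation; `FALSE`
#'   makes it symmetric on the mu scale, halfwidth = mu(c + 2sd) - mu(c)),
#'   `unknown_center` (mu in kJ/mol for metabolites without any table row;
#'   `NULL`, the default, makes such metabolites an error).
#' @return data frame of class `metabolite_priors` with columns
#'   `metabolite_id`, `mu_center`, `mu_halfwidth` (kJ/mol), `clamp`.
#' @export
build_prior <- function(network, prior_table, policy = list()) {
  stopifnot(inherits(network, "reaction_network"), is.data.frame(prior_table))
  pol <- modifyList(list(default_conc = 1e-3, decades = 4,
                         temperature = 298.15, span_in_concentration = TRUE,
                         unknown_center = NULL), policy)
  rt <- rt_energy(pol$temperature)
  need <- c("metabolite_id")
  if (!all(need %in% names(prior_table)))
    stop_gibbscape("prior table needs a metabolite_id column",
                   "gibbscape_format_error")
  getcol <- function(nm) if (nm %in% names(prior_table)) prior_table[[nm]]
                         else rep(NA_real_, nrow(prior_table))
  tab <- data.frame(metabolite_id = as.character(prior_table$metabolite_id),
                    dGf0 = as.numeric(getcol("dGf0")),
                    conc_center = as.numeric(getcol("conc_center")),
                    conc_sd = as.numeric(getcol("conc_sd")),
                    clamp = as.logical(ifelse(is.na(getcol("clamp")), FALSE,
                                              getcol("clamp"))),
                    stringsAsFactors = FALSE)
  if (anyDuplicated(tab$metabolite_id))
    stop_gibbscape("duplicate metabolite in prior table", "gibbscape_format_error")
  idx <- match(network$metabolite_ids, tab$metabolite_id)
  out <- data.frame(metabolite_id = network$metabolite_ids,
                    mu_center = NA_real_, mu_halfwidth = NA_real_,
                    clamp = FALSE, stringsAsFactors = FALSE)
  for (k in seq_along(idx)) {
    i <- idx[k]
    if (is.na(i)) {
      if (is.null(pol$unknown_center))
        stop_gibbscape(sprintf("no prior data or policy coverage for metabolite '%s'",
                               out$metabolite_id[k]),
                       "gibbscape_validation_error")
      out$mu_center[k] <- pol$unknown_center
      out$mu_halfwidth[k] <- pol$decades / 2 * rt * log(10)
      next
    }
    dg <- tab$dGf0[i]; cc <- tab$conc_center[i]; sd <- tab$conc_sd[i]
    if (is.na(dg))
      stop_gibbscape(sprintf("metabolite '%s' has a prior row but no dGf0",
                             out$metabolite_id[k]),
                     "gibbscape_validation_error")
    if (!is.na(cc) && !is.na(sd)) {
      lo <- cc - 2 * sd
      if (lo <= 0)
        stop_gibbscape(sprintf(
          "degenerate concentration range for '%s': center - 2 sd <= 0",
          out$metabolite_id[k]), "gibbscape_domain_error")
      center <- mu_from_concentration(dg, cc, pol$temperature)
      if (pol$span_in_concentration) {
        hi_mu <- mu_from_concentration(dg, cc + 2 * sd, pol$temperature)
        lo_mu <- mu_from_concentration(dg, lo, pol$temperature)
        hw <- (hi_mu - lo_mu) / 2
      } else {
        hw <- mu_from_concentration(dg, cc + 2 * sd, pol$temperature) - center
      }
      out$mu_center[k] <- center
      out$mu_halfwidth[k] <- hw
    } else {
      conc <- if (!is.na(cc)) cc else pol$default_conc
      out$mu_center[k] <- mu_from_concentration(dg, conc, pol$temperature)
      out$mu_halfwidth[k] <- pol$decades / 2 * rt * log(10)
    }
    if (tab$clamp[i]) {
      out$clamp[k] <- TRUE
      out$mu_halfwidth[k] <- 0
    }
  }
  class(out) <- c("metabolite_priors", "data.frame")
  out
}

#' Sample a starting potential vector from the prior boxes
#'
#' Each unclamped potential is drawn independently and uniformly from
#' `[center - halfwidth, center + halfwidth]`; clamped potentials are set to
#' their center.
#'
#' @param priors a [build_prior()] result.
#' @param seed optional integer for reproducibility.
#' @return a [potential_vector()].
#' @export
sample_prior <- function(priors, seed = NULL) {
  stopifnot(inherits(priors, "metabolite_priors"))
  mu <- with_seed(seed, {
    u <- runif(nrow(priors), -1, 1)
    priors$mu_center + u * priors$mu_halfwidth
  })
  mu[priors$clamp] <- priors$mu_center[priors$clamp]
  potential_vector(mu, clamped = priors$clamp,
                   metabolite_ids = priors$metabolite_id)
}

#' Read a priors table from TSV
#'
#' Columns: `metabolite_id`, `dGf0_kJ_per_mol`, `conc_center_M`, `conc_sd_M`,
#' `clamp` (0/1); missing values as empty fields.
#' @param path path to the TSV file.
#' @return data frame suitable for [build_prior()].
#' @export
read_priors <- function(path) {
  if (!file.exists(path))
    stop_gibbscape(sprintf("file not found: %s", path), "gibbscape_io_error")
  df <- read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                   stringsAsFactors = FALSE, na.strings = c("", "NA"))
  ren <- c(dGf0_kJ_per_mol = "dGf0", conc_center_M = "conc_center",
           conc_sd_M = "conc_sd")
  for (nm in names(ren)) if (nm %in% names(df))
    names(df)[names(df) == nm] <- ren[[nm]]
  df
}

#' Write a priors table to TSV
#' @param prior_table data frame with the [read_priors()] columns.
#' @param path output path.
#' @export
write_priors <- function(prior_table, path) {
  df <- prior_table
  ren <- c(dGf0 = "dGf0_kJ_per_mol", conc_center = "conc_center_M",
           conc_sd = "conc_sd_M")
  for (nm in names(ren)) if (nm %in% names(df))
    names(df)[names(df) == nm] <- ren[[nm]]
  if ("clamp" %in% names(df)) df$clamp <- as.integer(as.logical(df$clamp))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  invisible(path)
}

#' Is the solution space bounded?
#'
#' The solution space of the inequality system is bounded iff its recession
#' cone — directions x on the unclamped coordinates with
#' sigma_r sum_i S_ir x_i <= 0 for every constrained reaction, plus the
#' homogeneous versions of any box bounds (a two-sided bound pins x_i = 0, a
#' one-sided bound signs it) — contains only the null vector. Decided by
#' linear programming: maximize each coordinate in both signs under the cone
#' constraints and an l-infinity cap; any strictly positive optimum yields a
#' nonzero recession ray as a witness of unboundedness.
#'
#' @inheritParams minover_solve
#' @param clamped logical mask of clamped metabolites (their coordinates are
#'   removed from the cone).
#' @param bounds optional M x 2 box-bound matrix.
#' @return list with `status` ("BOUNDED"/"UNBOUNDED") and, when unbounded,
#'   `ray`: a nonzero length-M vector (zeros on clamped coordinates) along
#'   which all homogeneous constraints stay satisfied.
#' @export
boundedness_check <- function(network, sigma, clamped = NULL, bounds = NULL) {
  stopifnot(inherits(network, "reaction_network"))
  M <- nrow(network$S)
  sigma <- as.integer(sigma)
  if (is.null(clamped)) clamped <- rep(FALSE, M)
  free <- which(!clamped)
  if (!length(free)) return(list(status = "BOUNDED", ray = NULL))
  cons <- which(sigma != 0L)
  ## rows of the cone system A x <= 0 on the free coordinates
  A <- t(network$S[free, cons, drop = FALSE]) * as.numeric(sigma[cons])
  lb <- rep(-1, length(free)); ub <- rep(1, length(free))
  if (!is.null(bounds)) {
    stopifnot(is.matrix(bounds), nrow(bounds) == M, ncol(bounds) == 2)
    for (j in seq_along(free)) {
      i <- free[j]
      if (is.finite(bounds[i, 2])) ub[j] <- 0  # x_i <= 0 allowed only
      if (is.finite(bounds[i, 1])) lb[j] <- 0
    }
  }
  tol <- 1e-7
  for (j in seq_along(free)) {
    for (sgn in c(1, -1)) {
      cc <- numeric(length(free)); cc[j] <- -sgn  # maximize sgn * x_j
      sol <- .lp_solve_split(cc, A_ub = A, b_ub = rep(0, nrow(A)),
                             lb = lb, ub = ub)
      if (!is.null(sol) && sgn * sol[j] > tol) {
        ray <- numeric(M)
        ray[free] <- sol
        names(ray) <- network$metabolite_ids
        return(list(status = "UNBOUNDED", ray = ray))
      }
    }
  }
  list(status = "BOUNDED", ray = NULL)
}
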