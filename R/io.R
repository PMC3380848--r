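#' Write chemical potentials to TSV
#'
#' Two columns: `metabolite_id`, `mu` (kJ/mol).
#' @param mu a [potential_vector()] (named) or named numeric.
#' @param path output path.
#' @param header optional comment lines (without `#`), e.g. seed and config.
#' @export
write_potentials <- function(mu, path, header = NULL) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  if (length(header)) writeLines(paste0("# ", header), con)
  writeLines("metabolite_id\tmu", con)
  ids <- names(mu)
  if (is.null(ids)) ids <- sprintf("m%03d", seq_along(mu))
  writeLines(paste(ids, format(as.numeric(mu), digits = 17, trim = TRUE),
                   sep = "\t"), con)
  invisible(path)
}

#' Read chemical potentials from TSV
#' @param path path to a [write_potentials()] file.
#' @return named numeric vector, kJ/mol.
#' @export
read_potentials <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                   stringsAsFactors = FALSE)
  setNames(as.numeric(df$mu), df$metabolite_id)
}

#' Write per-reaction Gibbs energy changes to TSV
#'
#' Columns: `reaction_id`, `deltaG` (kJ/mol), `sigma`, `satisfied` (1 when
#' sigma_r DeltaG_r <= -eps or the reaction is unassigned).
#' @inheritParams least_satisfied
#' @param path output path.
#' @param eps feasibility margin used for the `satisfied` column.
#' @param header optional comment lines.
#' @export
write_gibbs <- function(network, mu, sigma, path, eps = 1e-6, header = NULL) {
  dg <- gibbs_changes(network, mu)
  sigma <- as.integer(sigma)
  sat <- as.integer(sigma == 0L | sigma * dg <= -eps)
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  if (length(header)) writeLines(paste0("# ", header), con)
  writeLines("reaction_id\tdeltaG\tsigma\tsatisfied", con)
  writeLines(paste(network$reaction_ids,
                   format(dg, digits = 17, trim = TRUE),
                   sigma, sat, sep = "\t"), con)
  invisible(path)
}

#' Write a loop catalogue to JSON
#'
#' A JSON list with one object per distinct loop: `reactions`, `signs`,
#' `gamma`, `reversible_members`, `occurrences` (mirroring the tabular
#' ID / length / formula presentation). An empty catalogue is written as
#' `[]`.
#' @param catalogue a [catalogue_loops()] result, or a list of
#'   [loop_certificate()]s together with `network`.
#' @param path output path.
#' @param network needed when `catalogue` is a plain certificate list.
#' @export
write_loop_catalogue <- function(catalogue, path, network = NULL) {
  if (inherits(catalogue, "loop_catalogue")) {
    loops <- catalogue$loops
  } else {
    loops <- lapply(catalogue, function(cert) {
      ids <- if (!is.null(cert$reaction_ids)) cert$reaction_ids
             else if (!is.null(network)) network$reaction_ids[cert$reactions]
             else as.character(cert$reactions)
      rev_mem <- if (!is.null(network))
        ids[network$reversible[cert$reactions]] else character(0)
      list(reactions = ids, signs = cert$signs, gamma = cert$gamma,
           reversible_members = rev_mem, occurrences = 1L)
    })
  }
  json <- jsonlite::toJSON(loops, auto_unbox = FALSE, digits = NA,
                           pretty = TRUE)
  writeLines(json, path)
  invisible(path)
}

#' Read a loop catalogue from JSON
#' @param path path written by [write_loop_catalogue()].
#' @return list of loop records.
#' @export
read_loop_catalogue <- function(path) {
  jsonlite::fromJSON(readLines(path), simplifyDataFrame = FALSE)
}

#' Write any gibbscape result to a file
#'
#' Dispatch helper: potential vectors go to TSV via [write_potentials()],
#' solve/fit results to a Gibbs-change TSV via [write_gibbs()], loop
#' catalogues and certificate lists to JSON via [write_loop_catalogue()].
#' @param result the object to write.
#' @param path output path.
#' @param network required for results that need reaction ids.
#' @param sigma required for solve results without an embedded assignment.
#' @param ... passed on to the specific writer.
#' @export
write_report <- function(result, path, network = NULL, sigma = NULL, ...) {
  if (inherits(result, "potential_vector"))
    return(write_potentials(result, path, ...))
  if (inherits(result, "gibbs_fit"))
    return(write_gibbs(result$network, coef(result), result$sigma, path,
                       eps = result$result$control$eps, ...))
  if (inherits(result, "gibbs_solve")) {
    stopifnot(!is.null(network), !is.null(sigma))
    return(write_gibbs(network, result$mu, sigma, path,
                       eps = result$control$eps, ...))
  }
  if (inherits(result, "loop_catalogue") ||
      (is.list(result) && (all(vapply(result, inherits, TRUE, "loop_certificate")))))
    return(write_loop_catalogue(result, path, network = network))
  stop_gibbscape("no writer for this result type", "gibbscape_validation_error")
}
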