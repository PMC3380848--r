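#' Reaction network container
#'
#' A validated stoichiometric network: the M x N matrix `S` of signed
#' stoichiometric coefficients (substrates negative, products positive),
#' metabolite and reaction identifiers, and a per-reaction reversibility flag.
#'
#' @param S numeric matrix, metabolites in rows, reactions in columns.
#'   Row names are taken as metabolite ids and column names as reaction ids
#'   unless `metabolite_ids` / `reaction_ids` are given.
#' @param reversible logical vector of length N; `TRUE` marks a reaction
#'   annotated as reversible. Defaults to all irreversible.
#' @param metabolite_ids,reaction_ids optional character vectors of unique ids.
#' @return an object of class `reaction_network` with elements `S`,
#'   `metabolite_ids`, `reaction_ids`, `reversible`.
#' @export
#' @examples
#' net <- reaction_network(matrix(c(-1, 1), 2, 1,
#'                                dimnames = list(c("A", "B"), "r1")))
#' net
reaction_network <- function(S, reversible = NULL,
                             metabolite_ids = NULL, reaction_ids = NULL) {
  S <- as.matrix(S)
  storage.mode(S) <- "double"
  if (is.null(metabolite_ids)) metabolite_ids <- rownames(S)
  if (is.null(reaction_ids)) reaction_ids <- colnames(S)
  if (is.null(metabolite_ids)) metabolite_ids <- sprintf("m%03d", seq_len(nrow(S)))
  if (is.null(reaction_ids)) reaction_ids <- sprintf("r%03d", seq_len(ncol(S)))
  metabolite_ids <- as.character(metabolite_ids)
  reaction_ids <- as.character(reaction_ids)
  if (nrow(S) < 1L || ncol(S) < 1L)
    stop_gibbscape("network must have at least one metabolite and one reaction",
                   "gibbscape_validation_error")
  if (length(metabolite_ids) != nrow(S) || length(reaction_ids) != ncol(S))
    stop_gibbscape("id vectors do not match matrix dimensions",
                   "gibbscape_validation_error")
  dup <- c(metabolite_ids[duplicated(metabolite_ids)],
           reaction_ids[duplicated(reaction_ids)])
  if (length(dup))
    stop_gibbscape(sprintf("duplicate identifier(s): %s",
                           paste(unique(dup), collapse = ", ")),
                   "gibbscape_format_error")
  if (!all(is.finite(S)))
    stop_gibbscape("stoichiometric coefficients must be finite",
                   "gibbscape_validation_error")
  zero <- colSums(S != 0) == 0L
  if (any(zero))
    stop_gibbscape(sprintf("all-zero stoichiometry for reaction(s): %s",
                           paste(reaction_ids[zero], collapse = ", ")),
                   "gibbscape_validation_error")
  if (is.null(reversible)) reversible <- rep(FALSE, ncol(S))
  reversible <- as.logical(reversible)
  if (length(reversible) != ncol(S) || anyNA(reversible))
    stop_gibbscape("reversible must be a logical vector of length N",
                   "gibbscape_validation_error")
  dimnames(S) <- list(metabolite_ids, reaction_ids)
  structure(list(S = S, metabolite_ids = metabolite_ids,
                 reaction_ids = reaction_ids, reversible = reversible),
            class = "reaction_network")
}

#' @export
print.reaction_network <- function(x, ...) {
  cat(sprintf("reaction_network: %d metabolites x %d reactions (%d reversible)\n",
              nrow(x$S), ncol(x$S), sum(x$reversible)))
  invisible(x)
}

#' @export
dim.reaction_network <- function(x) dim(x$S)

#' Direction assignment for a reaction network
#'
#' Validates a vector of reaction directions against a network: `+1` forward,
#' `-1` backward, `0` unassigned (no thermodynamic constraint imposed). In
#' strict mode a zero is only allowed on reversible reactions and a `-1` on an
#' irreversible reaction is rejected; in lenient mode such entries are accepted
#' with a warning, so users can probe direction patterns the annotation forbids.
#'
#' @param sigma integer-ish vector in \{-1, 0, +1\}, length N, optionally named
#'   by reaction id (order is taken from the network).
#' @param network a [reaction_network()].
#' @param strict logical; default `TRUE`.
#' @return integer vector of class `direction_assignment`, named by reaction id.
#' @export
direction_assignment <- function(sigma, network, strict = TRUE) {
  stopifnot(inherits(network, "reaction_network"))
  n <- ncol(network$S)
  if (!is.null(names(sigma))) {
    missing <- setdiff(network$reaction_ids, names(sigma))
    if (length(missing))
      stop_gibbscape(sprintf("missing direction for reaction(s): %s",
                             paste(missing, collapse = ", ")),
                     "gibbscape_format_error")
    unknown <- setdiff(names(sigma), network$reaction_ids)
    if (length(unknown))
      stop_gibbscape(sprintf("unknown reaction id(s) in directions: %s",
                             paste(unknown, collapse = ", ")),
                     "gibbscape_format_error")
    sigma <- sigma[network$reaction_ids]
  }
  if (length(sigma) != n)
    stop_gibbscape("direction vector length does not match number of reactions",
                   "gibbscape_validation_error")
  if (!all(sigma %in% c(-1, 0, 1)))
    stop_gibbscape("directions must be -1, 0 or +1", "gibbscape_parse_error")
  sigma <- as.integer(sigma)
  bad <- !network$reversible & sigma != 1L
  if (any(bad)) {
    msg <- sprintf("direction disagrees with irreversible annotation for: %s",
                   paste(network$reaction_ids[bad], collapse = ", "))
    if (strict) stop_gibbscape(msg, "gibbscape_validation_error")
    warning(msg, call. = FALSE)
  }
  structure(setNames(sigma, network$reaction_ids),
            class = "direction_assignment")
}

#' @export
print.direction_assignment <- function(x, ...) {
  cat(sprintf("direction_assignment: %d reactions (+1: %d, -1: %d, unassigned: %d)\n",
              length(x), sum(x == 1L), sum(x == -1L), sum(x == 0L)))
  invisible(x)
}

## ---- text formats ----------------------------------------------------------
## Network TSV: first non-comment row = reaction ids; an optional "#rev" row of
## 0/1 flags; then one row per metabolite (id + N coefficients). Blank lines
## and other #-comments ignored. UTF-8, "." decimal point.

.read_lines <- function(path) {
  if (!file.exists(path))
    stop_gibbscape(sprintf("file not found: %s", path), "gibbscape_io_error")
  readLines(path, encoding = "UTF-8")
}

#' Read a stoichiometric network from TSV
#'
#' Layout: the first non-comment line holds the reaction ids (tab-separated);
#' an optional line starting with `#rev` holds 0/1 reversibility flags; every
#' following line is a metabolite id followed by N numeric coefficients.
#'
#' @param path path to the TSV file.
#' @return a [reaction_network()].
#' @export
read_network <- function(path) {
  lines <- .read_lines(path)
  rev_line <- NULL
  keep <- character(0)
  for (ln in lines) {
    if (!nzchar(trimws(ln))) next
    if (startsWith(ln, "#")) {
      if (startsWith(ln, "#rev")) rev_line <- ln
      next
    }
    keep <- c(keep, ln)
  }
  if (length(keep) < 2L)
    stop_gibbscape("network file needs a reaction-id header and at least one metabolite row",
                   "gibbscape_format_error")
  split_tab <- function(x) strsplit(x, "\t", fixed = TRUE)[[1]]
  rids <- split_tab(keep[1])
  n <- length(rids)
  rows <- lapply(keep[-1], split_tab)
  mids <- vapply(rows, `[`, character(1), 1L)
  coef <- matrix(NA_real_, length(rows), n)
  for (i in seq_along(rows)) {
    vals <- rows[[i]][-1L]
    if (length(vals) != n)
      stop_gibbscape(sprintf("row '%s' has %d coefficients, expected %d",
                             mids[i], length(vals), n),
                     "gibbscape_format_error")
    num <- suppressWarnings(as.numeric(vals))
    if (anyNA(num)) {
      j <- which(is.na(num))[1]
      stop_gibbscape(sprintf("non-numeric coefficient at row '%s', column '%s': '%s'",
                             mids[i], rids[j], vals[j]),
                     "gibbscape_parse_error")
    }
    coef[i, ] <- num
  }
  reversible <- rep(FALSE, n)
  if (!is.null(rev_line)) {
    flags <- split_tab(rev_line)[-1L]
    if (length(flags) != n || !all(flags %in% c("0", "1")))
      stop_gibbscape("#rev row must hold one 0/1 flag per reaction",
                     "gibbscape_format_error")
    reversible <- flags == "1"
  }
  reaction_network(coef, reversible = reversible,
                   metabolite_ids = mids, reaction_ids = rids)
}

#' Write a stoichiometric network to TSV
#'
#' Inverse of [read_network()]; the round-trip preserves coefficients exactly
#' (values are printed with full precision).
#'
#' @param network a [reaction_network()].
#' @param path output path.
#' @param header optional character vector of comment lines (without `#`).
#' @export
write_network <- function(network, path, header = NULL) {
  stopifnot(inherits(network, "reaction_network"))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  if (length(header)) writeLines(paste0("# ", header), con)
  writeLines(paste(network$reaction_ids, collapse = "\t"), con)
  writeLines(paste(c("#rev", as.integer(network$reversible)), collapse = "\t"), con)
  fmt <- function(v) vapply(v, function(x) format(x, digits = 17, scientific = FALSE),
                            character(1))
  for (i in seq_len(nrow(network$S)))
    writeLines(paste(c(network$metabolite_ids[i], fmt(network$S[i, ])),
                     collapse = "\t"), con)
  invisible(path)
}

#' Read a direction assignment from TSV
#'
#' Two tab-separated columns: reaction id, direction in \{-1, 0, +1\}. Every
#' reaction of the network must appear exactly once.
#'
#' @inheritParams direction_assignment
#' @param path path to the TSV file.
#' @export
read_directions <- function(path, network, strict = TRUE) {
  lines <- .read_lines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ids <- vapply(parts, `[`, character(1), 1L)
  vals <- vapply(parts, function(p) if (length(p) >= 2L) p[2L] else NA_character_,
                 character(1))
  if (anyNA(vals))
    stop_gibbscape("each direction row needs two tab-separated fields",
                   "gibbscape_format_error")
  if (anyDuplicated(ids))
    stop_gibbscape(sprintf("duplicate reaction id(s) in directions: %s",
                           paste(unique(ids[duplicated(ids)]), collapse = ", ")),
                   "gibbscape_format_error")
  num <- suppressWarnings(as.numeric(vals))
  bad <- is.na(num) | !(num %in% c(-1, 0, 1))
  if (any(bad))
    stop_gibbscape(sprintf("invalid direction value '%s' for reaction '%s'",
                           vals[bad][1], ids[bad][1]),
                   "gibbscape_parse_error")
  direction_assignment(setNames(as.integer(num), ids), network, strict = strict)
}

#' Write a direction assignment to TSV
#' @param sigma a [direction_assignment()] (or named vector).
#' @param path output path.
#' @param header optional comment lines (without `#`).
#' @export
write_directions <- function(sigma, path, header = NULL) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  if (length(header)) writeLines(paste0("# ", header), con)
  writeLines(paste(names(sigma), as.integer(sigma), sep = "\t"), con)
  invisible(path)
}
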