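# Whole-network and node-level measures: density, degree centrality (total,
# in, out), Freeman degree centralization, isolates, response rate, and the
# low/moderate/high interpretive bands.

#' Network density
#'
#' The proportion of actual ties relative to the maximum possible:
#' `2E / (n (n - 1))` for an undirected network with `E` edges, and
#' `A / (n (n - 1))` for a directed network with `A` arcs (arc-level
#' convention; each ordered pair is a possible arc).
#'
#' @param m A [sociomatrix].
#' @param level `"arc"` (default) or `"dyad"`: for directed networks, whether
#'   the denominator counts ordered pairs (`n (n - 1)`) or unordered dyads
#'   (`n (n - 1) / 2`, a dyad counting as linked when either arc is present).
#' @return A fraction in \[0, 1\].
#' @export
network_density <- function(m, level = c("arc", "dyad")) {
  stopifnot(inherits(m, "sociomatrix"))
  level <- match.arg(level)
  n <- nrow(m$values)
  if (n < 2L) stop("density is undefined for n < 2", call. = FALSE)
  if (m$directed && level == "dyad") {
    linked <- (m$values + t(m$values)) > 0
    return(sum(linked[upper.tri(linked)]) / (n * (n - 1) / 2))
  }
  # undirected: symmetric values sum to 2E, so the same formula applies
  sum(m$values) / (n * (n - 1))
}

#' Degree centrality
#'
#' The number of ties each organization has. For directed networks,
#' `"in"` counts incoming arcs, `"out"` outgoing arcs, and `"total"` counts
#' distinct neighbours (organizations connected by an arc in either
#' direction). For undirected networks only `"total"` is defined.
#'
#' @param m A [sociomatrix].
#' @param basis `"total"`, `"in"` or `"out"`.
#' @return Named integer vector (one entry per roster organization).
#' @export
degree_centrality <- function(m, basis = c("total", "in", "out")) {
  stopifnot(inherits(m, "sociomatrix"))
  basis <- match.arg(basis)
  if (!m$directed && basis != "total") {
    stop("basis '", basis, "' requires a directed network; '", m$relation,
         "' is undirected", call. = FALSE)
  }
  v <- m$values
  deg <- switch(basis,
    total = if (m$directed) rowSums((v + t(v)) > 0) else rowSums(v),
    "in"  = colSums(v),
    out   = rowSums(v))
  stats::setNames(as.integer(round(deg)), rownames(v))
}

#' Freeman degree centralization
#'
#' A network-level index of how concentrated connectivity is on a few
#' organizations: the sum of gaps between the maximum observed centrality
#' and each organization's centrality, divided by the maximum attainable
#' sum — `(n - 1)(n - 2)` for undirected total degree, `(n - 1)^2` for
#' directed in- or out-degree. A star achieves 1; any regular network
#' (including the complete and the empty network) achieves 0.
#'
#' @param m A [sociomatrix].
#' @param basis Centrality basis: `"total"` (undirected), `"in"` or `"out"`
#'   (directed). Defaults to the natural basis for the matrix's
#'   directedness.
#' @return A fraction in \[0, 1\].
#' @export
freeman_centralization <- function(m,
                                   basis = if (m$directed) "in" else "total") {
  stopifnot(inherits(m, "sociomatrix"))
  n <- nrow(m$values)
  if (n < 3L) stop("degree centralization is undefined for n < 3",
                   call. = FALSE)
  if (m$directed && basis == "total") {
    stop("total-degree centralization is defined for undirected networks; ",
         "use basis 'in' or 'out' for directed networks", call. = FALSE)
  }
  deg <- degree_centrality(m, basis)
  denom <- if (m$directed) (n - 1)^2 else (n - 1) * (n - 2)
  sum(max(deg) - deg) / denom
}

#' Interpretive band for a density or centralization score
#'
#' Scores under 0.30 are low, 0.30 to 0.50 (inclusive on both ends)
#' moderate, and above 0.50 high.
#'
#' @param score Numeric score(s) in \[0, 1\].
#' @return Character vector: `"low"`, `"moderate"` or `"high"`.
#' @export
#' @examples
#' classify_band(c(0.229, 0.400, 0.648))
classify_band <- function(score) {
  if (any(is.na(score) | score < 0 | score > 1)) {
    stop("scores must lie in [0, 1]", call. = FALSE)
  }
  ifelse(score < 0.30, "low", ifelse(score <= 0.50, "moderate", "high"))
}

#' Isolates of a network
#'
#' Organizations with no ties at all in the relation (zero total degree:
#' for directed networks, neither incoming nor outgoing arcs).
#'
#' @param m A [sociomatrix].
#' @return A list with `count` and `org_ids`.
#' @export
count_isolates <- function(m) {
  deg <- degree_centrality(m, "total")
  ids <- names(deg)[deg == 0L]
  list(count = length(ids), org_ids = ids)
}

#' Organization-level response rate
#'
#' @param roster A [roster].
#' @return Percentage of roster organizations that responded, to one
#'   decimal place.
#' @export
#' @examples
#' r <- roster(letters[1:15], is_lead = c(TRUE, rep(FALSE, 14)),
#'             responded = c(rep(TRUE, 14), FALSE))
#' response_rate(r)  # 93.3
response_rate <- function(roster) {
  stopifnot(inherits(roster, "roster"))
  round(100 * sum(roster$responded) / nrow(roster), 1)
}

#' Full metric set for one network
#'
#' Computes every measure reported per relation network: size, tie count,
#' density with band, Freeman centralization with band and basis, per-node
#' degrees, isolates, and the roster's response rate.
#'
#' @param m A [sociomatrix].
#' @param basis Centralization basis; defaults to `"in"` for directed and
#'   `"total"` for undirected networks.
#' @return An object of class `"network_metrics"` (a list).
#' @export
network_metrics <- function(m, basis = if (m$directed) "in" else "total") {
  stopifnot(inherits(m, "sociomatrix"))
  n <- nrow(m$values)
  L <- if (m$directed) sum(m$values) else sum(m$values) / 2
  dens <- network_density(m)
  centr <- freeman_centralization(m, basis)
  per_node <- data.frame(
    org_id = m$roster$org_id,
    degree = as.integer(degree_centrality(m, "total")),
    stringsAsFactors = FALSE
  )
  if (m$directed) {
    per_node$in_degree <- as.integer(degree_centrality(m, "in"))
    per_node$out_degree <- as.integer(degree_centrality(m, "out"))
  }
  iso <- count_isolates(m)
  structure(list(
    case = case_label(m$roster),
    relation = m$relation,
    mode = m$mode,
    n = n,
    L = as.integer(round(L)),
    density = dens,
    density_band = classify_band(dens),
    centralization = centr,
    centralization_basis = basis,
    centralization_band = classify_band(centr),
    response_rate = response_rate(m$roster),
    isolates = iso$org_ids,
    per_node = per_node
  ), class = "network_metrics")
}

#' @export
print.network_metrics <- function(x, ...) {
  cat("Network metrics — case '", x$case, "', relation '", x$relation, "'",
      if (x$mode != "not_applicable") paste0(" (", x$mode, " ties)"),
      "\n", sep = "")
  cat(sprintf("  n = %d, L = %d, density = %.3f (%s)\n",
              x$n, x$L, x$density, x$density_band))
  cat(sprintf("  centralization (%s-degree) = %.3f (%s)\n",
              x$centralization_basis, x$centralization,
              x$centralization_band))
  cat(sprintf("  response rate = %.1f%%, isolates = %d\n",
              x$response_rate, length(x$isolates)))
  invisible(x)
}

#' Write a metrics report as JSON
#'
#' Densities and centralizations are reported to three decimals, response
#' rates to one decimal, matching the reporting convention used throughout.
#'
#' @param x A `network_metrics` object (or list of them).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_metrics_json <- function(x, path) {
  to_list <- function(mm) {
    pn <- mm$per_node
    per_node <- lapply(seq_len(nrow(pn)), function(i) {
      row <- as.list(pn[i, setdiff(names(pn), "org_id")])
      lapply(row, as.integer)
    })
    names(per_node) <- pn$org_id
    list(case = mm$case, relation = mm$relation, mode = mm$mode,
         n = mm$n, L = mm$L,
         density = round(mm$density, 3), density_band = mm$density_band,
         centralization = round(mm$centralization, 3),
         centralization_basis = mm$centralization_basis,
         centralization_band = mm$centralization_band,
         response_rate = mm$response_rate,
         isolates = as.list(mm$isolates),
         per_node = per_node)
  }
  payload <- if (inherits(x, "network_metrics")) to_list(x) else
    lapply(x, to_list)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
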