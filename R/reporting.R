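# Case-level reporting: network plots in the study's visual conventions
# (node size = degree or in-degree, colour = organization type, arrowheads
# on directed ties), per-case metric summary tables, and perception
# endorsement tabulation.

org_type_palette <- function() {
  stats::setNames(
    c("#D55E00", "#E69F00", "#0072B2", "#009E73", "#56B4E9", "#CC79A7",
      "#F0E442", "#999999"),
    org_types())
}

#' Deterministic force-directed layout for a sociomatrix
#'
#' Fruchterman-Reingold coordinates computed under the given seed; the same
#' matrix and seed always give identical coordinates.
#'
#' @param m A [sociomatrix].
#' @param seed Layout seed.
#' @return Numeric n x 2 matrix of coordinates, rows named by org_id.
#' @export
network_layout <- function(m, seed = 42L) {
  g <- as_igraph(m)
  set.seed(seed)
  coords <- igraph::layout_with_fr(g)
  rownames(coords) <- m$roster$org_id
  coords
}

#' Plot a network in the study's conventions
#'
#' One node per roster organization (isolates are always drawn), node area
#' monotone in the chosen centrality with a floor so isolates stay visible,
#' colour keyed to organization type with a legend, arrowheads iff the
#' relation is directed, and a deterministic force-directed layout.
#'
#' @param m A [sociomatrix].
#' @param size_basis `"degree"` (total degree) or `"in_degree"` (directed
#'   networks only). Defaults to the convention used per directedness.
#' @param seed Layout seed.
#' @param file Optional output path; the extension selects the device
#'   (`.png`, `.svg` or `.pdf`). `NULL` draws on the current device.
#' @param legend Draw the organization-type legend.
#' @return Invisibly, the layout coordinate matrix.
#' @export
plot_network <- function(m,
                         size_basis = if (m$directed) "in_degree" else "degree",
                         seed = 42L, file = NULL, legend = TRUE) {
  stopifnot(inherits(m, "sociomatrix"))
  size_basis <- match.arg(size_basis, c("degree", "in_degree"))
  if (size_basis == "in_degree" && !m$directed) {
    stop("in-degree node sizing requires a directed network", call. = FALSE)
  }
  deg <- if (size_basis == "degree") degree_centrality(m, "total")
         else degree_centrality(m, "in")
  # linear size with a floor: isolates remain visible
  sizes <- 8 + 22 * deg / max(1L, max(deg))
  coords <- network_layout(m, seed)
  g <- as_igraph(m)
  pal <- org_type_palette()
  cols <- pal[m$roster$org_type]
  dev_open <- FALSE
  if (!is.null(file)) {
    ext <- tolower(tools::file_ext(file))
    switch(ext,
           png = grDevices::png(file, width = 900, height = 700, res = 110),
           svg = grDevices::svg(file, width = 9, height = 7),
           pdf = grDevices::pdf(file, width = 9, height = 7),
           stop("unsupported plot format: .", ext, call. = FALSE))
    dev_open <- TRUE
    on.exit(grDevices::dev.off(), add = TRUE)
  }
  igraph::plot.igraph(
    g, layout = coords,
    vertex.size = sizes, vertex.color = cols, vertex.frame.color = "grey30",
    vertex.label = m$roster$org_id, vertex.label.cex = 0.7,
    vertex.label.color = "black",
    edge.arrow.size = if (m$directed) 0.5 else 0,
    edge.color = "grey50",
    main = sprintf("%s - %s%s", case_label(m$roster), m$relation,
                   if (m$directed) paste0(" (", m$mode, " ties)") else ""))
  if (legend) {
    present <- unique(m$roster$org_type)
    graphics::legend("bottomleft", legend = present, pt.bg = pal[present],
                     pch = 21, pt.cex = 1.4, cex = 0.75, bty = "n")
  }
  invisible(coords)
}

#' Summarize a case across its relation networks
#'
#' One row per (relation, mode) combination, carrying the full metric set;
#' the CPAT team score and the perception table ride along as attributes.
#'
#' @param networks Named or unnamed list of [sociomatrix] objects for one
#'   case (e.g. contact and integration plus confirmed/unconfirmed variants
#'   of each directed relation).
#' @param roster The case [roster].
#' @param cpat Optional `cpat_responses` for the lead agency's team.
#' @param map CPAT domain map used when `cpat` is given.
#' @param perceptions Optional `perception_responses`.
#' @return A data.frame of class `"case_summary"`.
#' @export
summarize_case <- function(networks, roster, cpat = NULL,
                           map = cpat_domain_map(), perceptions = NULL) {
  stopifnot(inherits(roster, "roster"))
  if (inherits(networks, "sociomatrix")) networks <- list(networks)
  rows <- lapply(networks, function(m) {
    mm <- network_metrics(m)
    data.frame(
      case = mm$case, relation = mm$relation, mode = mm$mode,
      n = mm$n, L = mm$L,
      density = round(mm$density, 3), density_band = mm$density_band,
      centralization = round(mm$centralization, 3),
      centralization_basis = mm$centralization_basis,
      centralization_band = mm$centralization_band,
      n_isolates = length(mm$isolates),
      response_rate = mm$response_rate,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (anyDuplicated(out[c("relation", "mode")])) {
    stop("summarize_case() expects at most one network per (relation, mode)",
         call. = FALSE)
  }
  if (!is.null(cpat)) {
    attr(out, "cpat_team") <- score_team(score_provider(cpat, map))
  }
  if (!is.null(perceptions)) {
    attr(out, "perceptions") <- tabulate_perceptions(perceptions, roster)
  }
  class(out) <- c("case_summary", "data.frame")
  out
}

#' @export
print.case_summary <- function(x, ...) {
  cat("Case summary — '", x$case[1], "' (", x$n[1], " organizations, ",
      sprintf("%.1f%%", x$response_rate[1]), " response rate)\n", sep = "")
  print(as.data.frame(x)[c("relation", "mode", "L", "density",
                           "density_band", "centralization",
                           "centralization_band", "n_isolates")], ...)
  ct <- attr(x, "cpat_team")
  if (!is.null(ct)) {
    cat(sprintf("CPAT team score: %.2f (sd %.2f, %d providers)\n",
                ct$team_score, ct$sd, ct$n_providers))
  }
  pc <- attr(x, "perceptions")
  if (!is.null(pc)) {
    cat("Perception endorsements (% of responding organizations):\n")
    print(pc, ...)
  }
  invisible(x)
}

#' Write a case summary as CSV and/or JSON
#'
#' @param x A `case_summary`.
#' @param csv,json Optional output paths.
#' @return Invisibly, the paths written.
#' @export
write_case_summary <- function(x, csv = NULL, json = NULL) {
  stopifnot(inherits(x, "case_summary"))
  if (!is.null(csv)) {
    utils::write.csv(as.data.frame(x), csv, row.names = FALSE, quote = TRUE)
  }
  if (!is.null(json)) {
    payload <- list(summary = as.data.frame(x))
    ct <- attr(x, "cpat_team")
    if (!is.null(ct)) payload$cpat_team <- ct
    pc <- attr(x, "perceptions")
    if (!is.null(pc)) payload$perceptions <- pc
    jsonlite::write_json(payload, json, auto_unbox = TRUE, pretty = TRUE,
                         dataframe = "rows")
  }
  invisible(c(csv = csv, json = json))
}

#' Tabulate perception endorsements
#'
#' For each benefit/drawback item, the percentage of responding
#' organizations that endorsed it, to one decimal place. Organizations that
#' did not respond to the survey are excluded from the denominator.
#'
#' @param responses A `perception_responses` table.
#' @param roster The case [roster].
#' @return Data.frame with columns `item`, `n_endorsed`, `n_respondents`,
#'   `percent`.
#' @export
#' @examples
#' r <- roster(sprintf("o%02d", 1:12), is_lead = c(TRUE, rep(FALSE, 11)),
#'             responded = c(rep(TRUE, 11), FALSE))
#' p <- perception_responses(data.frame(
#'   org_id = sprintf("o%02d", 1:11), item = "loss_of_autonomy",
#'   endorsed = c(TRUE, TRUE, rep(FALSE, 9))), r)
#' tabulate_perceptions(p, r)  # 2 of 11 -> 18.2
tabulate_perceptions <- function(responses, roster) {
  stopifnot(inherits(responses, "perception_responses"),
            inherits(roster, "roster"))
  n_resp <- sum(roster$responded)
  if (n_resp == 0L) {
    stop("no responding organizations: endorsement percentages undefined",
         call. = FALSE)
  }
  keep <- responses$org_id %in% roster$org_id[roster$responded]
  responses <- responses[keep, , drop = FALSE]
  items <- sort(unique(responses$item))
  n_end <- vapply(items, function(it) {
    sum(responses$endorsed[responses$item == it])
  }, integer(1))
  data.frame(item = items, n_endorsed = n_end, n_respondents = n_resp,
             percent = round(100 * n_end / n_resp, 1),
             stringsAsFactors = FALSE, row.names = NULL)
}
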