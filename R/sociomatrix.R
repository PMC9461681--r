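# The sociomatrix container: per-relation n x n binary tie structure with a
# missing-data mask, tied to the roster that defines its indexing.

#' Construct a sociomatrix
#'
#' A sociomatrix holds the final 0/1 tie structure for one relation over one
#' roster: `values[i, j] == 1` means an (i, j) tie (an arc i -> j when
#' directed, an edge when undirected). The diagonal is always 0 (self-ties
#' are never represented), undirected matrices are symmetric, and
#' `missing[i, j]` marks dyads for which no usable report existed (typically
#' both endpoints were nonrespondents).
#'
#' @param values Numeric n x n matrix of 0/1 tie values.
#' @param roster The [roster] defining row/column order.
#' @param relation Relation kind; see [relation_kinds()].
#' @param directed Logical; defaults to the relation's directedness.
#' @param mode `"confirmed"`, `"unconfirmed"` (directed relations) or
#'   `"not_applicable"` (undirected relations).
#' @param missing Logical n x n mask of unusable dyads (default: none).
#' @param imputed Logical n x n mask of dyads filled by reconstruction or the
#'   single-report fallback (default: none).
#' @return An object of class `"sociomatrix"`.
#' @export
sociomatrix <- function(values, roster, relation,
                        directed = relation_info(relation)$directed,
                        mode = if (directed) "confirmed" else "not_applicable",
                        missing = NULL, imputed = NULL) {
  stopifnot(inherits(roster, "roster"))
  n <- nrow(roster)
  values <- as.matrix(values)
  if (!all(dim(values) == c(n, n))) {
    stop("values must be an ", n, " x ", n, " matrix matching the roster",
         call. = FALSE)
  }
  if (is.null(missing)) missing <- matrix(FALSE, n, n)
  if (is.null(imputed)) imputed <- matrix(FALSE, n, n)
  storage.mode(values) <- "double"
  dimnames(values) <- dimnames(missing) <- dimnames(imputed) <-
    list(roster$org_id, roster$org_id)
  diag(values) <- 0
  diag(missing) <- FALSE
  m <- structure(
    list(values = values, missing = missing, imputed = imputed,
         roster = roster, relation = relation, directed = directed,
         mode = match.arg(mode, c("confirmed", "unconfirmed",
                                  "not_applicable"))),
    class = "sociomatrix")
  validate_sociomatrix(m)
  m
}

validate_sociomatrix <- function(m) {
  v <- m$values
  if (any(diag(v) != 0)) stop("sociomatrix diagonal must be 0", call. = FALSE)
  if (any(v < 0 | v > 1)) {
    stop("sociomatrix values must lie in [0, 1]", call. = FALSE)
  }
  if (!m$directed) {
    if (!isTRUE(all.equal(v, t(v)))) {
      stop("undirected sociomatrix must be symmetric", call. = FALSE)
    }
    if (!identical(m$missing, t(m$missing))) {
      stop("undirected missing mask must be symmetric", call. = FALSE)
    }
  }
  if (m$directed && m$mode == "not_applicable") {
    stop("directed sociomatrix must have mode 'confirmed' or 'unconfirmed'",
         call. = FALSE)
  }
  invisible(m)
}

#' @export
print.sociomatrix <- function(x, ...) {
  n <- nrow(x$values)
  ties <- if (x$directed) sum(x$values) else sum(x$values) / 2
  cat("Sociomatrix: ", x$relation,
      if (x$directed) paste0(" (directed, ", x$mode, " ties)")
      else " (undirected)",
      "\n  ", n, " organizations, ", ties,
      if (x$directed) " arcs" else " edges",
      ", ", sum(x$missing[upper.tri(x$missing)] |
                t(x$missing)[upper.tri(x$missing)]),
      " dyads without usable reports\n", sep = "")
  invisible(x)
}

#' Convert a sociomatrix to an igraph graph
#'
#' Isolates are preserved (one vertex per roster organization). Vertex
#' attributes carry `name`, `org_type` and `is_lead`.
#'
#' @param m A [sociomatrix].
#' @return An `igraph` graph.
#' @export
as_igraph <- function(m) {
  stopifnot(inherits(m, "sociomatrix"))
  g <- igraph::graph_from_adjacency_matrix(
    m$values, mode = if (m$directed) "directed" else "undirected",
    diag = FALSE)
  igraph::V(g)$org_type <- m$roster$org_type
  igraph::V(g)$is_lead <- m$roster$is_lead
  g
}

#' Write / read a sociomatrix as an adjacency CSV
#'
#' The adjacency export is a square 0/1 CSV with roster-ordered org_id
#' headers on both axes; self-loops are never emitted (diagonal written as
#' 0). `read_sociomatrix()` restores the object given the same roster.
#'
#' @param m A [sociomatrix].
#' @param path CSV path.
#' @return `path` (write) or a [sociomatrix] (read).
#' @export
write_sociomatrix <- function(m, path) {
  stopifnot(inherits(m, "sociomatrix"))
  out <- as.data.frame(m$values)
  out <- cbind(org_id = rownames(m$values), out)
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_sociomatrix
#' @param roster The [roster] the matrix was built from.
#' @param relation Relation kind.
#' @param mode Tie mode for directed relations.
#' @export
read_sociomatrix <- function(path, roster, relation,
                             mode = if (relation_info(relation)$directed)
                               "confirmed" else "not_applicable") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!identical(df$org_id, roster$org_id)) {
    stop("adjacency rows do not match the roster order", call. = FALSE)
  }
  v <- as.matrix(df[, -1, drop = FALSE])
  sociomatrix(v, roster, relation, mode = mode)
}

#' Edge list of a sociomatrix
#'
#' One row per present tie: `source,target,relation,mode`. Undirected edges
#' appear once, in canonical (lexicographic) order.
#'
#' @param m A [sociomatrix].
#' @return A data.frame.
#' @export
as_edge_list <- function(m) {
  stopifnot(inherits(m, "sociomatrix"))
  idx <- which(m$values == 1, arr.ind = TRUE)
  ids <- rownames(m$values)
  src <- ids[idx[, 1]]
  tgt <- ids[idx[, 2]]
  if (!m$directed) {
    keep <- src < tgt
    src <- src[keep]; tgt <- tgt[keep]
  }
  o <- order(src, tgt)
  data.frame(source = src[o], target = tgt[o], relation = m$relation,
             mode = m$mode, stringsAsFactors = FALSE)
}

#' @rdname as_edge_list
#' @param path CSV path.
#' @export
write_edge_list <- function(m, path) {
  utils::write.csv(as_edge_list(m), path, row.names = FALSE, quote = TRUE)
  invisible(path)
}
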