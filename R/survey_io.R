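# Reading, validating and writing the survey tables: roster, dyadic
# responses, CPAT item responses and perception endorsements. All inputs are
# UTF-8 comma-separated files with a header row; referential integrity is
# enforced here, before any network is built.

#' Construct and validate a roster
#'
#' A roster is the bounded set of organizations in one case (one network).
#' Its row order is fixed and defines the row/column indexing of every
#' sociomatrix built from it.
#'
#' @param org_id Character vector of unique organization identifiers.
#' @param name Organization display names (defaults to `org_id`).
#' @param org_type Organization types; see [org_types()].
#' @param is_lead Logical; exactly one organization must be the lead agency.
#' @param responded Logical; whether the organization answered the survey.
#' @param case_label Label for the case this roster belongs to.
#' @return A data.frame of class `"roster"` with attribute `case_label`.
#' @export
roster <- function(org_id, name = org_id, org_type = "other",
                   is_lead = FALSE, responded = TRUE, case_label = "case") {
  df <- data.frame(
    org_id = as.character(org_id),
    name = as.character(name),
    org_type = as.character(org_type),
    is_lead = as.logical(is_lead),
    responded = as.logical(responded),
    stringsAsFactors = FALSE
  )
  validate_roster(df)
  attr(df, "case_label") <- as.character(case_label)
  class(df) <- c("roster", "data.frame")
  df
}

validate_roster <- function(df) {
  if (nrow(df) < 2L) {
    stop("roster must contain at least 2 organizations", call. = FALSE)
  }
  dup <- duplicated(df$org_id)
  if (any(dup)) {
    stop("duplicate org_id in roster: ",
         paste(unique(df$org_id[dup]), collapse = ", "),
         " (rows ", paste(which(df$org_id %in% df$org_id[dup]),
                          collapse = ", "), ")", call. = FALSE)
  }
  bad_type <- !df$org_type %in% org_types()
  if (any(bad_type)) {
    stop("unknown org_type in roster rows ",
         paste(which(bad_type), collapse = ", "), ": ",
         paste(unique(df$org_type[bad_type]), collapse = ", "), call. = FALSE)
  }
  if (anyNA(df$is_lead) || anyNA(df$responded)) {
    stop("is_lead and responded must be TRUE/FALSE with no missing values",
         call. = FALSE)
  }
  n_lead <- sum(df$is_lead)
  if (n_lead != 1L) {
    stop("roster must have exactly one lead agency, found ", n_lead,
         if (n_lead > 1L) paste0(" (rows ", paste(which(df$is_lead),
                                                  collapse = ", "), ")"),
         call. = FALSE)
  }
  invisible(df)
}

#' Read a roster from CSV
#'
#' Expects columns `org_id,name,org_type,is_lead,responded` (extra columns
#' are ignored) plus an optional `case_label` column or argument. Row order
#' is preserved as the matrix index order.
#'
#' @param path Path to a CSV file.
#' @param case_label Case label; overrides any `case_label` column.
#' @return A [roster] object.
#' @export
read_roster <- function(path, case_label = NULL) {
  df <- read_csv_checked(path, c("org_id", "name", "org_type", "is_lead",
                                 "responded"))
  if (is.null(case_label)) {
    case_label <- if ("case_label" %in% names(df)) df$case_label[1] else "case"
  }
  roster(df$org_id, df$name, df$org_type, parse_flag(df$is_lead),
         parse_flag(df$responded), case_label = case_label)
}

#' Write a roster to CSV
#'
#' @param x A [roster].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_roster <- function(x, path) {
  stopifnot(inherits(x, "roster"))
  out <- as.data.frame(x)
  out$case_label <- case_label(x)
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname roster
#' @param x A roster.
#' @export
case_label <- function(x) attr(x, "case_label")

#' Fraction of organizations that did not respond
#'
#' Missingness is defined at the organization level: the fraction of roster
#' organizations that returned no survey at all. This is the quantity the
#' 30\% imputation guard in [build_network()] is checked against.
#'
#' @param roster A [roster].
#' @return A fraction in \[0, 1\].
#' @export
#' @examples
#' r <- roster(letters[1:15], is_lead = c(TRUE, rep(FALSE, 14)),
#'             responded = c(rep(TRUE, 14), FALSE))
#' respondent_missingness(r)  # 1 - 14/15
respondent_missingness <- function(roster) {
  stopifnot(inherits(roster, "roster"))
  1 - sum(roster$responded) / nrow(roster)
}

#' Read dyadic survey responses from CSV
#'
#' Expects columns `reporter,source,target,relation,value`: one row is one
#' reporter's claim about one ordered (directed relation) or unordered
#' (undirected relation) pair. Values are parsed into the relation's domain:
#' contact frequency levels, integration levels, or 0/1 reports. For
#' undirected relations the pair is canonicalized to lexicographic order on
#' `org_id`, so reports about (B, A) and (A, B) land on the same dyad key.
#'
#' @param path Path to a CSV file.
#' @param roster The [roster] the responses refer to.
#' @return A data.frame of class `"dyadic_responses"` with columns
#'   `reporter,source,target,relation,value,code` (`code` is the parsed
#'   integer value).
#' @export
read_responses <- function(path, roster) {
  df <- read_csv_checked(path, c("reporter", "source", "target", "relation",
                                 "value"))
  dyadic_responses(df, roster)
}

#' Validate a dyadic response table
#'
#' @param df Data.frame with columns `reporter,source,target,relation,value`.
#' @param roster The [roster] the responses refer to.
#' @return Validated data.frame of class `"dyadic_responses"`.
#' @export
dyadic_responses <- function(df, roster) {
  stopifnot(inherits(roster, "roster"))
  req <- c("reporter", "source", "target", "relation", "value")
  miss <- setdiff(req, names(df))
  if (length(miss)) {
    stop("response table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  df <- df[req]
  for (col in c("reporter", "source", "target", "relation")) {
    df[[col]] <- as.character(df[[col]])
  }
  ids <- roster$org_id
  for (col in c("reporter", "source", "target")) {
    bad <- !df[[col]] %in% ids
    if (any(bad)) {
      stop("unknown org_id in '", col, "' at row(s) ",
           paste(utils::head(which(bad), 10), collapse = ", "), ": ",
           paste(unique(df[[col]][bad]), collapse = ", "), call. = FALSE)
    }
  }
  bad_rel <- !df$relation %in% relation_kinds()$kind
  if (any(bad_rel)) {
    stop("unknown relation at row(s) ",
         paste(utils::head(which(bad_rel), 10), collapse = ", "), ": ",
         paste(unique(df$relation[bad_rel]), collapse = ", "), call. = FALSE)
  }
  self <- df$source == df$target
  if (any(self)) {
    stop("self-ties (source == target) at row(s) ",
         paste(utils::head(which(self), 10), collapse = ", "), call. = FALSE)
  }
  not_endpoint <- df$reporter != df$source & df$reporter != df$target
  if (any(not_endpoint)) {
    stop("reporter is not an endpoint of the dyad at row(s) ",
         paste(utils::head(which(not_endpoint), 10), collapse = ", "),
         call. = FALSE)
  }
  # canonical unordered pair for undirected relations
  undirected <- df$relation %in%
    relation_kinds()$kind[!relation_kinds()$directed]
  flip <- undirected & df$source > df$target
  if (any(flip)) {
    tmp <- df$source[flip]
    df$source[flip] <- df$target[flip]
    df$target[flip] <- tmp
  }
  key <- paste(df$reporter, df$source, df$target, df$relation, sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) {
    stop("duplicate (reporter, source, target, relation) at row(s) ",
         paste(utils::head(which(dup), 10), collapse = ", "), call. = FALSE)
  }
  df$code <- NA_integer_
  for (rel in unique(df$relation)) {
    i <- df$relation == rel
    df$code[i] <- parse_value(df$value[i], rel)
  }
  rownames(df) <- NULL
  class(df) <- c("dyadic_responses", "data.frame")
  df
}

#' Write dyadic responses to CSV
#'
#' @param x A `dyadic_responses` table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_responses <- function(x, path) {
  stopifnot(inherits(x, "dyadic_responses"))
  utils::write.csv(
    as.data.frame(x)[c("reporter", "source", "target", "relation", "value")],
    path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read CPAT item responses from CSV
#'
#' Expects columns `provider_id,item_id,value`: one row per provider and
#' item, items numbered 1 to 56, values on the 7-point scale (1 to 7).
#' Duplicate (provider, item) rows are rejected.
#'
#' @param path Path to a CSV file.
#' @return A data.frame of class `"cpat_responses"`.
#' @export
read_cpat <- function(path) {
  df <- read_csv_checked(path, c("provider_id", "item_id", "value"))
  cpat_responses(df)
}

#' Validate a CPAT item-response table
#'
#' @param df Data.frame with columns `provider_id,item_id,value`.
#' @return Validated data.frame of class `"cpat_responses"`.
#' @export
cpat_responses <- function(df) {
  req <- c("provider_id", "item_id", "value")
  miss <- setdiff(req, names(df))
  if (length(miss)) {
    stop("CPAT table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  df <- df[req]
  df$provider_id <- as.character(df$provider_id)
  df$item_id <- as.integer(df$item_id)
  df$value <- as.numeric(df$value)
  bad_item <- is.na(df$item_id) | df$item_id < 1L | df$item_id > 56L
  if (any(bad_item)) {
    stop("item_id outside 1..56 at row(s) ",
         paste(utils::head(which(bad_item), 10), collapse = ", "),
         call. = FALSE)
  }
  bad_val <- is.na(df$value) | df$value < 1 | df$value > 7
  if (any(bad_val)) {
    stop("CPAT value outside the 1..7 scale at row(s) ",
         paste(utils::head(which(bad_val), 10), collapse = ", "),
         call. = FALSE)
  }
  dup <- duplicated(df[c("provider_id", "item_id")])
  if (any(dup)) {
    stop("duplicate (provider_id, item_id) at row(s) ",
         paste(utils::head(which(dup), 10), collapse = ", "), call. = FALSE)
  }
  rownames(df) <- NULL
  class(df) <- c("cpat_responses", "data.frame")
  df
}

#' Read perception (benefit/drawback) endorsements from CSV
#'
#' Expects columns `org_id,item,endorsed`. At most one response per
#' (organization, item).
#'
#' @param path Path to a CSV file.
#' @param roster The [roster] the responses refer to.
#' @return A data.frame of class `"perception_responses"`.
#' @export
read_perceptions <- function(path, roster) {
  df <- read_csv_checked(path, c("org_id", "item", "endorsed"))
  perception_responses(df, roster)
}

#' Validate a perception-response table
#'
#' @param df Data.frame with columns `org_id,item,endorsed`.
#' @param roster The [roster] the responses refer to.
#' @return Validated data.frame of class `"perception_responses"`.
#' @export
perception_responses <- function(df, roster) {
  stopifnot(inherits(roster, "roster"))
  req <- c("org_id", "item", "endorsed")
  miss <- setdiff(req, names(df))
  if (length(miss)) {
    stop("perception table is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  df <- df[req]
  df$org_id <- as.character(df$org_id)
  df$item <- as.character(df$item)
  df$endorsed <- parse_flag(df$endorsed)
  bad <- !df$org_id %in% roster$org_id
  if (any(bad)) {
    stop("unknown org_id in perception rows ",
         paste(utils::head(which(bad), 10), collapse = ", "), call. = FALSE)
  }
  dup <- duplicated(df[c("org_id", "item")])
  if (any(dup)) {
    stop("more than one response per (org, item) at row(s) ",
         paste(utils::head(which(dup), 10), collapse = ", "), call. = FALSE)
  }
  rownames(df) <- NULL
  class(df) <- c("perception_responses", "data.frame")
  df
}

# ---- internal CSV helpers ---------------------------------------------------

read_csv_checked <- function(path, required) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  miss <- setdiff(required, names(df))
  if (length(miss)) {
    stop("'", basename(path), "' is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  df
}

parse_flag <- function(x) {
  if (is.logical(x)) return(x)
  v <- tolower(trimws(as.character(x)))
  out <- ifelse(v %in% c("true", "t", "1", "yes", "y"), TRUE,
         ifelse(v %in% c("false", "f", "0", "no", "n"), FALSE, NA))
  if (anyNA(out)) {
    stop("cannot parse logical value(s): ",
         paste(unique(x[is.na(out)]), collapse = ", "), call. = FALSE)
  }
  out
}

#' @export
print.roster <- function(x, ...) {
  cat("Roster '", case_label(x), "': ", nrow(x), " organizations (",
      sum(x$responded), " responded, lead agency: ",
      x$org_id[x$is_lead], ")\n", sep = "")
  print(as.data.frame(x), ...)
  invisible(x)
}
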