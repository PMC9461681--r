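# CPAT (Collaborative Practice Assessment Tool) scoring: 56 Likert items in
# 8 domains, each domain scored as the mean of its items, a provider total
# as the sum of the 8 domain means (range 8..56), and a team score as the
# mean of provider totals.

#' CPAT domain map
#'
#' Maps the 8 domain labels to disjoint item-id sets covering items 1..56.
#' The published instrument has uneven domain sizes which are not
#' reproduced here, so the map is a required input for scoring real data;
#' the default uniform map (7 consecutive items per domain) is a documented
#' fallback that preserves the instrument's bounds.
#'
#' @param domains Named list mapping 8 domain labels to integer item-id
#'   vectors, or `NULL` for the uniform fallback.
#' @return A named list of class `"cpat_domain_map"`.
#' @export
#' @examples
#' map <- cpat_domain_map()
#' lengths(map)
cpat_domain_map <- function(domains = NULL) {
  if (is.null(domains)) {
    domains <- lapply(0:7, function(d) d * 7L + 1:7)
    names(domains) <- paste0("domain_", 1:8)
  }
  domains <- lapply(domains, function(x) sort(as.integer(x)))
  if (length(domains) != 8L || is.null(names(domains)) ||
      any(!nzchar(names(domains))) || anyDuplicated(names(domains))) {
    stop("a CPAT domain map needs exactly 8 uniquely named domains",
         call. = FALSE)
  }
  items <- unlist(domains, use.names = FALSE)
  if (anyDuplicated(items)) {
    stop("CPAT domains must be disjoint (item(s) ",
         paste(unique(items[duplicated(items)]), collapse = ", "),
         " appear in more than one domain)", call. = FALSE)
  }
  if (!setequal(items, 1:56)) {
    stop("CPAT domains must cover items 1..56 exactly", call. = FALSE)
  }
  class(domains) <- "cpat_domain_map"
  domains
}

#' Read a CPAT domain map from CSV
#'
#' Expects columns `domain,item_id`.
#'
#' @param path Path to a CSV file.
#' @return A [cpat_domain_map()].
#' @export
read_domain_map <- function(path) {
  df <- read_csv_checked(path, c("domain", "item_id"))
  cpat_domain_map(split(as.integer(df$item_id), df$domain))
}

#' Score CPAT domains per provider
#'
#' Each domain score is the arithmetic mean of its items, in \[1, 7\].
#' By default every item of every domain must be answered; with
#' `partial = TRUE` a domain is scored over its answered items (a domain
#' with no answered item is still an error).
#'
#' @param responses A `cpat_responses` table (see [read_cpat()]).
#' @param map A [cpat_domain_map()].
#' @param partial Allow domain means over answered items only.
#' @return Data.frame: `provider_id` plus one column per domain.
#' @export
score_domains <- function(responses, map = cpat_domain_map(),
                          partial = FALSE) {
  stopifnot(inherits(responses, "cpat_responses"),
            inherits(map, "cpat_domain_map"))
  providers <- unique(responses$provider_id)
  out <- data.frame(provider_id = providers, stringsAsFactors = FALSE)
  for (dom in names(map)) {
    items <- map[[dom]]
    out[[dom]] <- vapply(providers, function(p) {
      vals <- responses$value[responses$provider_id == p &
                                responses$item_id %in% items]
      if (length(vals) == 0L) {
        stop("provider '", p, "' answered no item in domain '", dom, "'",
             call. = FALSE)
      }
      if (!partial && length(vals) < length(items)) {
        stop("provider '", p, "' is missing ", length(items) - length(vals),
             " item(s) in domain '", dom,
             "' (use partial = TRUE to score over answered items)",
             call. = FALSE)
      }
      mean(vals)
    }, numeric(1))
  }
  rownames(out) <- NULL
  out
}

#' Score provider totals
#'
#' A provider's total is the sum of their 8 domain means; with items on the
#' 1..7 scale the total lies in \[8, 56\].
#'
#' @inheritParams score_domains
#' @return Named numeric vector of provider totals.
#' @export
#' @examples
#' one <- cpat_responses(data.frame(provider_id = "p1", item_id = 1:56,
#'                                  value = 4))
#' score_provider(one)  # 32
score_provider <- function(responses, map = cpat_domain_map(),
                           partial = FALSE) {
  dom <- score_domains(responses, map, partial)
  stats::setNames(rowSums(dom[names(map)]), dom$provider_id)
}

#' Aggregate provider totals to a team score
#'
#' The team score is the unweighted mean of provider totals; the standard
#' deviation is reported when at least two providers are present.
#'
#' @param totals Numeric vector of provider totals (see [score_provider()]).
#' @return List with `team_score`, `sd` (NA for a single provider) and
#'   `n_providers`.
#' @export
score_team <- function(totals) {
  totals <- as.numeric(totals)
  if (length(totals) == 0L) {
    stop("cannot compute a team score from zero providers", call. = FALSE)
  }
  list(team_score = mean(totals),
       sd = if (length(totals) >= 2L) stats::sd(totals) else NA_real_,
       n_providers = length(totals))
}
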