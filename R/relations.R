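# Relation catalogue and ordinal response scales shared across the package.

#' Relation kinds measured by the survey
#'
#' The pipeline analyses six relation types between organizations. Contact
#' frequency and perceived integration are undirected (a property of the
#' unordered pair); referrals, information sharing, joint care planning and
#' shared resources are directed (sent/received).
#'
#' @return A data.frame with columns `kind`, `directed` and `value_domain`
#'   (one of `"contact_frequency"`, `"integration_level"`, `"binary_report"`).
#' @export
#' @examples
#' relation_kinds()
relation_kinds <- function() {
  data.frame(
    kind = c("contact", "integration", "referral", "information_sharing",
             "joint_care_planning", "shared_resources"),
    directed = c(FALSE, FALSE, TRUE, TRUE, TRUE, TRUE),
    value_domain = c("contact_frequency", "integration_level",
                     "binary_report", "binary_report", "binary_report",
                     "binary_report"),
    stringsAsFactors = FALSE
  )
}

relation_info <- function(relation) {
  rk <- relation_kinds()
  i <- match(relation, rk$kind)
  if (is.na(i)) {
    stop("unknown relation kind: '", relation, "' (expected one of ",
         paste(rk$kind, collapse = ", "), ")", call. = FALSE)
  }
  rk[i, , drop = FALSE]
}

#' Ordinal scale of contact frequency
#'
#' Levels in increasing order of contact intensity. The absence of a report
#' about a partner maps to `"none"`.
#'
#' @return Character vector of levels, lowest first (codes 0 to 5).
#' @export
contact_levels <- function() {
  c("none", "annually", "biannually", "monthly", "weekly", "daily")
}

#' Ordinal scale of perceived integration
#'
#' Seven levels of interorganizational integration, from no working
#' relationship to fully linked (mutual planning and shared staff/resources),
#' coded 0 to 6 in scale order.
#'
#' @return Character vector of levels, lowest first (codes 0 to 6).
#' @export
integration_levels <- function() {
  c("not_linked", "communication", "cooperation", "coordination",
    "collaboration", "partnership", "fully_linked")
}

#' Organization types on the roster
#'
#' @return Character vector of recognised organization type labels.
#' @export
org_types <- function() {
  c("primary_care_lead", "primary_care", "hospital", "home_community_care",
    "long_term_care", "community_agency", "government_agency", "other")
}

# Ordinal code of a contact level: 0 (none) .. 5 (daily).
contact_code <- function(value) {
  lv <- contact_levels()
  if (is.numeric(value)) {
    code <- as.integer(value)
    bad <- is.na(code) | code < 0L | code > length(lv) - 1L | code != value
  } else {
    code <- match(tolower(trimws(as.character(value))), lv) - 1L
    bad <- is.na(code)
  }
  if (any(bad)) {
    stop("invalid contact frequency value(s): ",
         paste(unique(value[bad]), collapse = ", "), call. = FALSE)
  }
  code
}

# Ordinal code of an integration level: 0 (not_linked) .. 6 (fully_linked).
integration_code <- function(value) {
  lv <- integration_levels()
  if (is.numeric(value)) {
    code <- as.integer(value)
    bad <- is.na(code) | code < 0L | code > length(lv) - 1L | code != value
  } else {
    code <- match(tolower(trimws(as.character(value))), lv) - 1L
    bad <- is.na(code)
  }
  if (any(bad)) {
    stop("invalid integration level value(s): ",
         paste(unique(value[bad]), collapse = ", "), call. = FALSE)
  }
  code
}

# Parse a binary (0/1) report, accepting common logical spellings.
binary_code <- function(value) {
  v <- tolower(trimws(as.character(value)))
  code <- ifelse(v %in% c("1", "true", "t", "yes", "y"), 1L,
          ifelse(v %in% c("0", "false", "f", "no", "n"), 0L, NA_integer_))
  if (anyNA(code)) {
    stop("invalid binary report value(s): ",
         paste(unique(value[is.na(code)]), collapse = ", "), call. = FALSE)
  }
  code
}

# Parse values for one relation into integer codes.
parse_value <- function(value, relation) {
  switch(relation_info(relation)$value_domain,
    contact_frequency = contact_code(value),
    integration_level = integration_code(value),
    binary_report     = binary_code(value)
  )
}
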