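# From validated dyadic responses to one per-relation sociomatrix:
# dichotomization of ordinal reports, mean-tie resolution of dyadic
# discrepancies, reconstruction imputation for dyads with a single
# respondent endpoint (undirected), and confirmed/unconfirmed tie
# extraction (directed).

#' Tie-construction rule configuration
#'
#' Bundles the preprocessing cut-offs and thresholds applied when turning
#' survey reports into binary ties.
#'
#' @param contact_cutoff Contact frequency at or above which a dyad counts
#'   as linked. Default `"monthly"`: contact more often than twice a year.
#' @param integration_cutoff Integration level at or above which a dyad
#'   counts as integrated. Default `"coordination"` (code 3).
#' @param discrepancy_threshold Mean tie value at or above which a dyad with
#'   discrepant reports is linked. Default 0.5, so a (1, 0) disagreement,
#'   averaged to 0.5, counts as linked.
#' @param missingness_limit Organization-level nonresponse fraction above
#'   which reconstruction imputation is refused. Default 0.30.
#' @param single_report_fallback For directed relations: whether a dyad with
#'   one nonrespondent endpoint takes the single available report as the tie
#'   value (default `TRUE`; such dyads are flagged in the `imputed` mask).
#'   With `FALSE` these dyads are dropped (value 0, missing mask set).
#' @param discrepancy_order `"dichotomize_first"` (default) dichotomizes each
#'   report, then averages the two 0/1 values; `"average_ordinal_first"`
#'   averages the raw ordinal codes and applies the cut-off to the mean.
#' @return An object of class `"tie_rule_config"`.
#' @export
tie_rule_config <- function(contact_cutoff = "monthly",
                            integration_cutoff = "coordination",
                            discrepancy_threshold = 0.5,
                            missingness_limit = 0.30,
                            single_report_fallback = TRUE,
                            discrepancy_order = c("dichotomize_first",
                                                  "average_ordinal_first")) {
  cfg <- list(
    contact_cutoff = contact_code(contact_cutoff),
    integration_cutoff = integration_code(integration_cutoff),
    discrepancy_threshold = discrepancy_threshold,
    missingness_limit = missingness_limit,
    single_report_fallback = isTRUE(single_report_fallback),
    discrepancy_order = match.arg(discrepancy_order)
  )
  if (!is.numeric(discrepancy_threshold) || discrepancy_threshold <= 0 ||
      discrepancy_threshold > 1) {
    stop("discrepancy_threshold must lie in (0, 1]", call. = FALSE)
  }
  if (!is.numeric(missingness_limit) || missingness_limit <= 0 ||
      missingness_limit > 1) {
    stop("missingness_limit must lie in (0, 1]", call. = FALSE)
  }
  class(cfg) <- "tie_rule_config"
  cfg
}

#' Dichotomize a contact-frequency report
#'
#' A dyad is linked when contact is at or above the cut-off: with the
#' default (`"monthly"`), organizations in contact more than twice per year
#' are linked, while biannual or rarer contact is not.
#'
#' @param value Contact frequency level(s) (names or codes 0..5).
#' @param config A [tie_rule_config()].
#' @return Integer 0/1 vector.
#' @export
#' @examples
#' dichotomize_contact(c("monthly", "biannually", "daily"))
dichotomize_contact <- function(value, config = tie_rule_config()) {
  as.integer(contact_code(value) >= config$contact_cutoff)
}

#' Dichotomize a perceived-integration report
#'
#' A dyad is integrated when the reported level is at or above the cut-off:
#' with the default (`"coordination"`), coordination, collaboration,
#' partnership and fully linked all count as integrated.
#'
#' @param value Integration level(s) (names or codes 0..6).
#' @param config A [tie_rule_config()].
#' @return Integer 0/1 vector.
#' @export
#' @examples
#' dichotomize_integration(c("coordination", "cooperation"))
dichotomize_integration <- function(value, config = tie_rule_config()) {
  as.integer(integration_code(value) >= config$integration_cutoff)
}

#' Mean tie value for a dyad reported by both endpoints
#'
#' When the two members of a dyad disagree, the mean of their (dichotomized)
#' reports is used as the dyad's tie value; agreement returns the common
#' value unchanged.
#'
#' @param a,b The two endpoints' 0/1 reports (vectorized).
#' @return Numeric vector in \[0, 1\].
#' @export
#' @examples
#' resolve_discrepancy(1, 0)  # 0.5
resolve_discrepancy <- function(a, b) {
  stopifnot(all(a %in% c(0, 1)), all(b %in% c(0, 1)))
  (a + b) / 2
}

#' Reconstruction imputation for a single-respondent dyad
#'
#' When exactly one endpoint of an undirected dyad responded, the single
#' respondent's (dichotomized) report is taken as the dyad's tie value. The
#' rule is only defensible when overall organization-level missingness is
#' below the configured limit; above it, an error instructs the caller.
#'
#' @param report The respondent endpoint's 0/1 report (vectorized).
#' @param missingness Organization-level nonresponse fraction of the roster
#'   (see [respondent_missingness()]).
#' @param config A [tie_rule_config()].
#' @return Integer 0/1 vector equal to `report`.
#' @export
reconstruct_impute <- function(report, missingness = 0,
                               config = tie_rule_config()) {
  if (missingness >= config$missingness_limit) {
    stop("reconstruction imputation refused: organization nonresponse (",
         sprintf("%.1f%%", 100 * missingness), ") is at or above the ",
         sprintf("%.0f%%", 100 * config$missingness_limit),
         " limit; collect more responses or analyse respondents only",
         call. = FALSE)
  }
  stopifnot(all(report %in% c(0, 1)))
  as.integer(report)
}

#' Extract confirmed or unconfirmed ties for a directed relation
#'
#' An arc A -> B is *confirmed* when A reports sending to B and B reports
#' receiving from A; it is *unconfirmed* when either endpoint reports it.
#' For dyads with one nonrespondent endpoint the behaviour follows
#' `config$single_report_fallback`; dyads with two nonrespondent endpoints
#' are left at 0 with the missing mask set.
#'
#' @param responses A `dyadic_responses` table (see [read_responses()]).
#' @param roster The [roster].
#' @param relation A directed relation kind.
#' @param mode `"confirmed"` or `"unconfirmed"`.
#' @param config A [tie_rule_config()].
#' @return A directed [sociomatrix].
#' @export
confirm_ties <- function(responses, roster, relation,
                         mode = c("confirmed", "unconfirmed"),
                         config = tie_rule_config()) {
  mode <- match.arg(mode)
  info <- relation_info(relation)
  if (!info$directed) {
    stop("confirm_ties() applies to directed relations only; '", relation,
         "' is undirected", call. = FALSE)
  }
  views <- reporter_views_directed(responses, roster, relation)
  send <- views$send   # send[a, b]: a's report of arc a -> b (NA if a NR)
  recv <- views$recv   # recv[a, b]: b's report of arc a -> b (NA if b NR)
  n <- nrow(roster)
  values <- matrix(0, n, n)
  missing <- matrix(FALSE, n, n)
  imputed <- matrix(FALSE, n, n)
  both <- !is.na(send) & !is.na(recv)
  values[both] <- if (mode == "confirmed") {
    as.numeric(send[both] == 1 & recv[both] == 1)
  } else {
    as.numeric(send[both] == 1 | recv[both] == 1)
  }
  one <- xor(is.na(send), is.na(recv))
  if (config$single_report_fallback) {
    single <- ifelse(is.na(send), recv, send)
    values[one] <- single[one]
    imputed[one] <- TRUE
  } else {
    missing[one] <- TRUE
  }
  neither <- is.na(send) & is.na(recv)
  missing[neither] <- TRUE
  diag(missing) <- FALSE
  sociomatrix(values, roster, relation, directed = TRUE, mode = mode,
              missing = missing, imputed = imputed)
}

#' Build the sociomatrix for one relation
#'
#' The full preprocessing pipeline for one relation network. Undirected
#' relations (contact, integration): each report is dichotomized at the
#' relation's cut-off, dyads reported by both endpoints take the mean tie
#' value (linked at `discrepancy_threshold`), dyads with a single respondent
#' endpoint are imputed by reconstruction, and dyads with no respondent are
#' left at 0 with the missing mask set. Directed relations (referral,
#' information sharing, joint care planning, shared resources): ties are
#' extracted via [confirm_ties()] in the requested mode.
#'
#' @param responses A `dyadic_responses` table.
#' @param roster The [roster].
#' @param relation A relation kind; see [relation_kinds()].
#' @param config A [tie_rule_config()].
#' @param mode Tie mode for directed relations (ignored for undirected).
#' @return A [sociomatrix].
#' @export
#' @examples
#' r <- roster(c("A", "B", "C"), is_lead = c(TRUE, FALSE, FALSE))
#' resp <- dyadic_responses(data.frame(
#'   reporter = c("A", "B"), source = c("A", "A"), target = c("B", "B"),
#'   relation = "contact", value = c("monthly", "annually")), r)
#' m <- build_network(resp, r, "contact")
#' m$values["A", "B"]  # (1, 0) reports -> mean 0.5 -> linked
build_network <- function(responses, roster, relation,
                          config = tie_rule_config(),
                          mode = c("confirmed", "unconfirmed")) {
  stopifnot(inherits(responses, "dyadic_responses"), inherits(roster, "roster"))
  info <- relation_info(relation)
  if (info$directed) {
    return(confirm_ties(responses, roster, relation, match.arg(mode), config))
  }
  build_undirected(responses, roster, relation, config)
}

# ---- internals --------------------------------------------------------------

# Undirected pipeline: dichotomize -> mean-tie -> threshold -> reconstruction.
build_undirected <- function(responses, roster, relation, config) {
  n <- nrow(roster)
  ids <- roster$org_id
  resp <- responses[responses$relation == relation, , drop = FALSE]
  miss_frac <- respondent_missingness(roster)
  any_nonresp <- any(!roster$responded)
  if (any_nonresp && miss_frac >= config$missingness_limit) {
    stop("reconstruction imputation refused for relation '", relation,
         "': organization nonresponse (", sprintf("%.1f%%", 100 * miss_frac),
         ") is at or above the ",
         sprintf("%.0f%%", 100 * config$missingness_limit),
         " limit; collect more responses or analyse respondents only",
         call. = FALSE)
  }
  # view[i, j]: ordinal code reported by i about dyad {i, j};
  # 0 (no tie / none) for respondents with no row; NA for nonrespondents.
  view <- matrix(0L, n, n, dimnames = list(ids, ids))
  view[!roster$responded, ] <- NA_integer_
  if (nrow(resp)) {
    ri <- match(resp$reporter, ids)
    oi <- ifelse(resp$reporter == resp$source,
                 match(resp$target, ids), match(resp$source, ids))
    view[cbind(ri, oi)] <- resp$code
  }
  diag(view) <- NA_integer_
  cutoff <- switch(relation_info(relation)$value_domain,
                   contact_frequency = config$contact_cutoff,
                   integration_level = config$integration_cutoff,
                   stop("undirected relations must carry an ordinal domain"))
  values <- matrix(0, n, n, dimnames = list(ids, ids))
  missing <- matrix(FALSE, n, n, dimnames = list(ids, ids))
  imputed <- matrix(FALSE, n, n, dimnames = list(ids, ids))
  n_unobserved <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in seq((i + 1L), n)) {
      a <- view[i, j]  # i's report about {i, j}
      b <- view[j, i]  # j's report about {i, j}
      if (!is.na(a) && !is.na(b)) {
        tie <- if (config$discrepancy_order == "dichotomize_first") {
          mean_tie <- resolve_discrepancy(as.integer(a >= cutoff),
                                          as.integer(b >= cutoff))
          as.numeric(mean_tie >= config$discrepancy_threshold)
        } else {
          as.numeric((a + b) / 2 >= cutoff)
        }
        values[i, j] <- values[j, i] <- tie
      } else if (!is.na(a) || !is.na(b)) {
        single <- if (is.na(a)) b else a
        tie <- reconstruct_impute(as.integer(single >= cutoff),
                                  missingness = miss_frac, config = config)
        values[i, j] <- values[j, i] <- tie
        imputed[i, j] <- imputed[j, i] <- TRUE
      } else {
        missing[i, j] <- missing[j, i] <- TRUE
        n_unobserved <- n_unobserved + 1L
      }
    }
  }
  if (n_unobserved > 0L) {
    warning(n_unobserved, " dyad(s) in relation '", relation,
            "' had no respondent endpoint; left untied and flagged missing",
            call. = FALSE)
  }
  sociomatrix(values, roster, relation, directed = FALSE,
              mode = "not_applicable", missing = missing, imputed = imputed)
}

# Directed reporter views. send[a, b]: a's report of the arc a -> b;
# recv[a, b]: b's report of the arc a -> b. NA where the reporter did not
# respond; 0 where a respondent filed no row for that arc.
reporter_views_directed <- function(responses, roster, relation) {
  stopifnot(inherits(responses, "dyadic_responses"))
  n <- nrow(roster)
  ids <- roster$org_id
  resp <- responses[responses$relation == relation, , drop = FALSE]
  send <- recv <- matrix(0L, n, n, dimnames = list(ids, ids))
  send[!roster$responded, ] <- NA_integer_
  recv[, !roster$responded] <- NA_integer_   # recv[a, b] belongs to reporter b
  if (nrow(resp)) {
    si <- match(resp$source, ids)
    ti <- match(resp$target, ids)
    is_sender <- resp$reporter == resp$source
    s <- which(is_sender)
    r <- which(!is_sender)
    if (length(s)) send[cbind(si[s], ti[s])] <- resp$code[s]
    if (length(r)) recv[cbind(si[r], ti[r])] <- resp$code[r]
  }
  diag(send) <- NA_integer_
  diag(recv) <- NA_integer_
  list(send = send, recv = recv)
}
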