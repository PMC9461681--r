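# Seeded generator of complete synthetic cases: roster, six-relation dyadic
# survey responses with reporting noise and organizational nonresponse, CPAT
# item responses with a target team score, and perception endorsements.
# Ground truth is retained so every pipeline stage can be checked against a
# known network.

#' Simulation configuration
#'
#' All randomness is governed by `seed`; per-stage substreams are derived
#' deterministically from it, so a config reproduces its outputs exactly.
#' Defaults emulate the low-CPAT study case: 15 organizations with one
#' nonrespondent, true densities per relation near the reported values,
#' modest hub structure around the lead agency, and a CPAT block echoing
#' the antecedent survey's team-score distribution (mean 46.6, sd 2.47).
#'
#' @param seed Integer seed.
#' @param n_orgs Number of organizations (>= 3).
#' @param org_type_probs Named sampling probabilities over non-lead
#'   organization types (see [org_types()]).
#' @param relations Named list (one entry per relation kind) of
#'   `list(p = true density, alpha = hub weight)`. `alpha` mixes a uniform
#'   random graph (weight `1 - alpha`) with a star centred on the lead
#'   agency (`alpha = 1` gives a pure star, maximal centralization); the
#'   expected density is `p` when `alpha = 0`.
#' @param false_negative_rate Probability a reporter omits a true tie.
#' @param false_positive_rate Probability a reporter claims an absent tie.
#' @param nonresponse_fraction Fraction of organizations (never the lead
#'   agency) returning no survey; must be below 1 and, for the undirected
#'   pipeline to run, below the 30\% imputation limit.
#' @param cpat List: `n_providers`, `target_team_mean` in \[8, 56\],
#'   `provider_sd`, `item_dispersion` (sd of item-level jitter).
#' @param perception_items Named endorsement probabilities per
#'   benefit/drawback item.
#' @return An object of class `"simulation_config"`.
#' @export
simulation_config <- function(
    seed = 1L,
    n_orgs = 15L,
    org_type_probs = c(primary_care = 0.20, hospital = 0.15,
                       home_community_care = 0.10, long_term_care = 0.10,
                       community_agency = 0.30, government_agency = 0.10,
                       other = 0.05),
    relations = list(
      contact             = list(p = 0.648, alpha = 0.25),
      integration         = list(p = 0.400, alpha = 0.25),
      referral            = list(p = 0.119, alpha = 0.25),
      information_sharing = list(p = 0.229, alpha = 0.25),
      joint_care_planning = list(p = 0.110, alpha = 0.25),
      shared_resources    = list(p = 0.100, alpha = 0.25)
    ),
    false_negative_rate = 0.10,
    false_positive_rate = 0.02,
    nonresponse_fraction = 1 / 15,
    cpat = list(n_providers = 10L, target_team_mean = 46.6,
                provider_sd = 2.47, item_dispersion = 1),
    perception_items = c(improved_capacity = 0.80,
                         better_use_of_services = 0.70,
                         loss_of_autonomy = 0.18,
                         strained_relations = 0.36,
                         too_much_time_resources = 0.45,
                         difficulty_with_members = 0.27)) {
  cfg <- list(seed = as.integer(seed), n_orgs = as.integer(n_orgs),
              org_type_probs = org_type_probs, relations = relations,
              false_negative_rate = false_negative_rate,
              false_positive_rate = false_positive_rate,
              nonresponse_fraction = nonresponse_fraction,
              cpat = cpat, perception_items = perception_items)
  validate_simulation_config(cfg)
  class(cfg) <- "simulation_config"
  cfg
}

validate_simulation_config <- function(cfg) {
  if (is.na(cfg$seed)) stop("seed must be an integer", call. = FALSE)
  if (cfg$n_orgs < 3L) stop("n_orgs must be >= 3", call. = FALSE)
  if (!all(names(cfg$org_type_probs) %in% setdiff(org_types(),
                                                  "primary_care_lead"))) {
    stop("org_type_probs must be named by non-lead org types", call. = FALSE)
  }
  miss_rel <- setdiff(relation_kinds()$kind, names(cfg$relations))
  if (length(miss_rel)) {
    stop("relations is missing: ", paste(miss_rel, collapse = ", "),
         call. = FALSE)
  }
  for (rel in names(cfg$relations)) {
    pr <- cfg$relations[[rel]]
    if (is.null(pr$p) || pr$p < 0 || pr$p > 1 ||
        is.null(pr$alpha) || pr$alpha < 0 || pr$alpha > 1) {
      stop("relation '", rel, "' needs p and alpha in [0, 1]", call. = FALSE)
    }
  }
  for (r in c("false_negative_rate", "false_positive_rate")) {
    if (cfg[[r]] < 0 || cfg[[r]] > 1) {
      stop(r, " must lie in [0, 1]", call. = FALSE)
    }
  }
  if (cfg$nonresponse_fraction < 0 || cfg$nonresponse_fraction >= 1) {
    stop("nonresponse_fraction must lie in [0, 1)", call. = FALSE)
  }
  cp <- cfg$cpat
  if (cp$target_team_mean < 8 || cp$target_team_mean > 56) {
    stop("target_team_mean must lie in [8, 56] (the CPAT bounds)",
         call. = FALSE)
  }
  if (cp$n_providers < 1L || cp$provider_sd < 0 || cp$item_dispersion < 0) {
    stop("invalid CPAT block: n_providers >= 1, provider_sd >= 0, ",
         "item_dispersion >= 0 required", call. = FALSE)
  }
  if (any(cfg$perception_items < 0 | cfg$perception_items > 1)) {
    stop("perception endorsement probabilities must lie in [0, 1]",
         call. = FALSE)
  }
  invisible(cfg)
}

# Deterministic per-stage substream seed, kept within 32-bit integer range.
stage_seed <- function(seed, stage) {
  tags <- c("roster", relation_kinds()$kind,
            paste0("responses_", relation_kinds()$kind),
            "cpat", "perceptions")
  k <- match(stage, tags)
  if (is.na(k)) stop("unknown simulation stage: ", stage, call. = FALSE)
  as.integer((abs(as.numeric(seed)) + k * 100003) %% 2147483629) + 1L
}

#' Generate a synthetic roster
#'
#' Organization 1 is the lead agency (a primary care practice); it always
#' responds, since the lead administers the network survey. Nonrespondents
#' (`round(nonresponse_fraction * n_orgs)` of them) are drawn uniformly
#' from the remaining organizations.
#'
#' @param config A [simulation_config()].
#' @return A [roster].
#' @export
generate_roster <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(stage_seed(config$seed, "roster"))
  n <- config$n_orgs
  ids <- sprintf("org%02d", seq_len(n))
  probs <- config$org_type_probs / sum(config$org_type_probs)
  types <- c("primary_care_lead",
             sample(names(probs), n - 1L, replace = TRUE, prob = probs))
  responded <- rep(TRUE, n)
  k <- round(config$nonresponse_fraction * n)
  if (k > 0L) responded[sample(2:n, min(k, n - 1L))] <- FALSE
  roster(ids, name = sprintf("Organization %02d", seq_len(n)),
         org_type = types, is_lead = c(TRUE, rep(FALSE, n - 1L)),
         responded = responded, case_label = "synthetic_case")
}

#' Generate a ground-truth network for one relation
#'
#' Each dyad (undirected) or ordered pair (directed) carries a tie with
#' probability `(1 - alpha) * p + alpha * star`, where `star` is 1 for
#' dyads touching the lead agency (undirected) or arcs pointing into the
#' lead agency (directed) and 0 otherwise. With `alpha = 0` the expected
#' density is exactly `p`; with `alpha = 1` the network is a pure star on
#' the lead agency (maximal degree centralization).
#'
#' @param config A [simulation_config()].
#' @param relation Relation kind.
#' @param roster Optional [roster] (generated from `config` if omitted).
#' @return A [sociomatrix] (the ground truth; no missing dyads).
#' @export
generate_true_network <- function(config, relation, roster = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  if (is.null(roster)) roster <- generate_roster(config)
  info <- relation_info(relation)
  pr <- config$relations[[relation]]
  set.seed(stage_seed(config$seed, relation))
  n <- nrow(roster)
  lead <- which(roster$is_lead)
  v <- matrix(0, n, n)
  if (info$directed) {
    for (a in seq_len(n)) for (b in seq_len(n)) {
      if (a == b) next
      star <- as.numeric(b == lead)
      v[a, b] <- stats::rbinom(1, 1, (1 - pr$alpha) * pr$p + pr$alpha * star)
    }
  } else {
    for (i in seq_len(n - 1L)) for (j in seq((i + 1L), n)) {
      star <- as.numeric(i == lead || j == lead)
      tie <- stats::rbinom(1, 1, (1 - pr$alpha) * pr$p + pr$alpha * star)
      v[i, j] <- v[j, i] <- tie
    }
  }
  sociomatrix(v, roster, relation, directed = info$directed,
              mode = if (info$directed) "unconfirmed" else "not_applicable")
}

# Flip a 0/1 report by the false-negative / false-positive rates.
flip_report <- function(truth, fnr, fpr) {
  u <- stats::runif(length(truth))
  ifelse(truth == 1, as.integer(u >= fnr), as.integer(u < fpr))
}

# Map a 0/1 observation to an ordinal survey value, uniform over the
# admissible side of the cut-off.
ordinal_value <- function(obs, domain) {
  lv <- switch(domain, contact_frequency = contact_levels(),
               integration_level = integration_levels())
  cut <- switch(domain, contact_frequency = contact_code("monthly"),
                integration_level = integration_code("coordination"))
  vapply(obs, function(o) {
    side <- if (o == 1) lv[(cut + 1L):length(lv)] else lv[1:cut]
    if (length(side) == 1L) side else sample(side, 1L)
  }, character(1))
}

#' Generate survey responses for one ground-truth network
#'
#' Each responding organization reports its own row of the truth, with each
#' report independently flipped by the false-negative/false-positive rates.
#' Observed ties are expressed as ordinal values at or above the relation's
#' cut-off (uniform over that side of the scale) and non-ties below it;
#' directed relations are reported as 0/1 from both the sending and the
#' receiving perspective. Nonrespondents contribute no rows.
#'
#' @param truth A ground-truth [sociomatrix] (see [generate_true_network()]).
#' @param config A [simulation_config()].
#' @return A validated `dyadic_responses` table.
#' @export
generate_responses <- function(truth, config) {
  stopifnot(inherits(truth, "sociomatrix"),
            inherits(config, "simulation_config"))
  roster <- truth$roster
  relation <- truth$relation
  set.seed(stage_seed(config$seed, paste0("responses_", relation)))
  n <- nrow(roster)
  ids <- roster$org_id
  domain <- relation_info(relation)$value_domain
  fnr <- config$false_negative_rate
  fpr <- config$false_positive_rate
  rows <- list()
  for (i in which(roster$responded)) {
    others <- setdiff(seq_len(n), i)
    if (truth$directed) {
      obs_send <- flip_report(truth$values[i, others], fnr, fpr)
      obs_recv <- flip_report(truth$values[others, i], fnr, fpr)
      rows[[length(rows) + 1L]] <- data.frame(
        reporter = ids[i],
        source = c(rep(ids[i], length(others)), ids[others]),
        target = c(ids[others], rep(ids[i], length(others))),
        relation = relation,
        value = as.character(c(obs_send, obs_recv)),
        stringsAsFactors = FALSE)
    } else {
      obs <- flip_report(truth$values[i, others], fnr, fpr)
      rows[[length(rows) + 1L]] <- data.frame(
        reporter = ids[i], source = ids[i], target = ids[others],
        relation = relation, value = ordinal_value(obs, domain),
        stringsAsFactors = FALSE)
    }
  }
  df <- if (length(rows)) {
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
  } else {
    data.frame(reporter = character(), source = character(),
               target = character(), relation = character(),
               value = character(), stringsAsFactors = FALSE)
  }
  dyadic_responses(df, roster)
}

#' Generate CPAT item responses with a target team score
#'
#' Provider totals are drawn from a normal distribution around
#' `target_team_mean` with `provider_sd`, clipped to the instrument's
#' \[8, 56\] bounds. Each total is realized as integer item responses on
#' the 1..7 scale (jittered by `item_dispersion`, then adjusted item by
#' item) so that rescoring the items under the uniform domain map recovers
#' the drawn total to within half an item step (1/14).
#'
#' @param config A [simulation_config()].
#' @return A `cpat_responses` table; the drawn provider totals are attached
#'   as attribute `"drawn_totals"`.
#' @export
generate_cpat <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  cp <- config$cpat
  set.seed(stage_seed(config$seed, "cpat"))
  totals <- stats::rnorm(cp$n_providers, cp$target_team_mean, cp$provider_sd)
  totals <- pmin(56, pmax(8, totals))
  out <- vector("list", cp$n_providers)
  for (k in seq_len(cp$n_providers)) {
    target <- totals[k]
    mu <- target / 8            # per-domain (and per-item) target mean
    items <- round(mu + stats::rnorm(56, 0, cp$item_dispersion))
    items <- pmin(7L, pmax(1L, as.integer(items)))
    # greedy adjustment: each unit item change moves the total by 1/7
    repeat {
      cur <- sum(tapply(items, rep(1:8, each = 7), mean))
      if (abs(cur - target) <= 1 / 14) break
      if (cur < target) {
        i <- which(items < 7L)[1]
        if (is.na(i)) break
        items[i] <- items[i] + 1L
      } else {
        i <- which(items > 1L)[1]
        if (is.na(i)) break
        items[i] <- items[i] - 1L
      }
    }
    out[[k]] <- data.frame(provider_id = sprintf("provider%02d", k),
                           item_id = 1:56, value = items,
                           stringsAsFactors = FALSE)
  }
  res <- cpat_responses(do.call(rbind, out))
  attr(res, "drawn_totals") <- totals
  res
}

#' Generate perception endorsements
#'
#' Each responding organization endorses each benefit/drawback item
#' independently with the item's configured probability.
#'
#' @param config A [simulation_config()].
#' @param roster A [roster] (generated from `config` if omitted).
#' @return A `perception_responses` table.
#' @export
generate_perceptions <- function(config, roster = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  if (is.null(roster)) roster <- generate_roster(config)
  set.seed(stage_seed(config$seed, "perceptions"))
  items <- names(config$perception_items)
  resp <- roster$org_id[roster$responded]
  df <- expand.grid(org_id = resp, item = items, stringsAsFactors = FALSE,
                    KEEP.OUT.ATTRS = FALSE)
  df <- df[order(df$org_id, df$item), ]
  df$endorsed <- stats::runif(nrow(df)) <
    config$perception_items[df$item]
  perception_responses(df, roster)
}

#' Generate and write a complete synthetic case
#'
#' Writes `roster.csv`, `responses.csv` (all six relations), `cpat.csv`,
#' `perceptions.csv`, one `truth_<relation>.csv` adjacency per relation,
#' and `manifest.json` recording the configuration and seed.
#'
#' @param config A [simulation_config()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list with the in-memory objects: `roster`, `truth`
#'   (named list of sociomatrices), `responses`, `cpat`, `perceptions`.
#' @export
simulate_case <- function(config, dir) {
  stopifnot(inherits(config, "simulation_config"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ros <- generate_roster(config)
  truth <- list()
  resp <- list()
  for (rel in relation_kinds()$kind) {
    truth[[rel]] <- generate_true_network(config, rel, roster = ros)
    resp[[rel]] <- generate_responses(truth[[rel]], config)
    write_sociomatrix(truth[[rel]],
                      file.path(dir, paste0("truth_", rel, ".csv")))
  }
  responses <- do.call(rbind, lapply(resp, as.data.frame))
  rownames(responses) <- NULL
  responses <- dyadic_responses(responses, ros)
  cpat <- generate_cpat(config)
  perc <- generate_perceptions(config, ros)
  write_roster(ros, file.path(dir, "roster.csv"))
  write_responses(responses, file.path(dir, "responses.csv"))
  utils::write.csv(as.data.frame(cpat), file.path(dir, "cpat.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(perc), file.path(dir, "perceptions.csv"),
                   row.names = FALSE)
  manifest <- unclass(config)
  manifest$relations <- lapply(manifest$relations, unclass)
  jsonlite::write_json(list(generator = "orgnet simulate_case",
                            config = manifest),
                       file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(roster = ros, truth = truth, responses = responses,
                 cpat = cpat, perceptions = perc))
}
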