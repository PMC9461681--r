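# Fixture builders and independent brute-force oracles used across the
# suite. Oracles enumerate pairs directly and never call the package's
# metric functions.

make_roster <- function(n, responded = rep(TRUE, n), case_label = "test") {
  roster(sprintf("org%02d", seq_len(n)),
         org_type = c("primary_care_lead", rep("community_agency", n - 1)),
         is_lead = c(TRUE, rep(FALSE, n - 1)),
         responded = responded, case_label = case_label)
}

# Build a dyadic_responses table from a data.frame-like list of rows.
make_responses <- function(ros, ...) {
  rows <- list(...)
  df <- do.call(rbind, lapply(rows, function(r) {
    data.frame(reporter = r[[1]], source = r[[2]], target = r[[3]],
               relation = r[[4]], value = as.character(r[[5]]),
               stringsAsFactors = FALSE)
  }))
  dyadic_responses(df, ros)
}

# Random sociomatrix on the current RNG stream.
rand_sociomatrix <- function(n, p, directed, relation = if (directed)
                               "referral" else "contact") {
  ros <- make_roster(n)
  v <- matrix(0, n, n)
  if (directed) {
    v[] <- rbinom(n * n, 1, p)
    diag(v) <- 0
  } else {
    up <- which(upper.tri(v))
    v[up] <- rbinom(length(up), 1, p)
    v <- v + t(v)
  }
  sociomatrix(v, ros, relation, directed = directed,
              mode = if (directed) "unconfirmed" else "not_applicable")
}

# ---- brute-force oracles (pair enumeration) --------------------------------

oracle_density <- function(v, directed) {
  n <- nrow(v)
  ties <- 0; possible <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    if (directed || i < j) {
      possible <- possible + 1
      if (v[i, j] == 1) ties <- ties + 1
    }
  }
  ties / possible
}

oracle_degrees <- function(v, directed, basis) {
  n <- nrow(v)
  deg <- integer(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    hit <- switch(basis,
      total = if (directed) (v[i, j] == 1 || v[j, i] == 1) else v[i, j] == 1,
      "in"  = v[j, i] == 1,
      out   = v[i, j] == 1)
    if (hit) deg[i] <- deg[i] + 1L
  }
  deg
}

oracle_centralization <- function(v, directed, basis) {
  n <- nrow(v)
  deg <- oracle_degrees(v, directed, basis)
  denom <- if (directed) (n - 1)^2 else (n - 1) * (n - 2)
  sum(max(deg) - deg) / denom
}

# Noise-free simulation config used by the recovery/parameter tests.
noiseless_config <- function(seed, n, p, alpha = 0, nonresponse = 0,
                             fnr = 0, fpr = 0) {
  rels <- lapply(relation_kinds()$kind, function(k) list(p = p, alpha = alpha))
  names(rels) <- relation_kinds()$kind
  simulation_config(seed = seed, n_orgs = n, relations = rels,
                    false_negative_rate = fnr, false_positive_rate = fpr,
                    nonresponse_fraction = nonresponse)
}
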