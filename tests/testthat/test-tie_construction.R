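test_that("contact dichotomization links monthly-or-more, not biannual", {
  expect_equal(dichotomize_contact(c("monthly", "weekly", "daily")),
               c(1L, 1L, 1L))
  expect_equal(dichotomize_contact(c("none", "annually", "biannually")),
               c(0L, 0L, 0L))
  # configurable cut-off
  cfg <- tie_rule_config(contact_cutoff = "weekly")
  expect_equal(dichotomize_contact("monthly", cfg), 0L)
})

test_that("integration dichotomization is inclusive at coordination", {
  expect_equal(dichotomize_integration(c("coordination", "collaboration",
                                         "partnership", "fully_linked")),
               rep(1L, 4))
  expect_equal(dichotomize_integration(c("not_linked", "communication",
                                         "cooperation")), rep(0L, 3))
})

test_that("discrepant dyad reports resolve to their mean", {
  expect_equal(resolve_discrepancy(1, 0), 0.5)
  expect_equal(resolve_discrepancy(1, 1), 1)
  expect_equal(resolve_discrepancy(0, 0), 0)
})

test_that("reconstruction takes the single respondent's report, within the missingness limit", {
  expect_equal(reconstruct_impute(1, missingness = 0.1), 1L)
  expect_equal(reconstruct_impute(0, missingness = 0.1), 0L)
  expect_error(reconstruct_impute(1, missingness = 0.4), "refused")
  expect_error(reconstruct_impute(1, missingness = 0.30), "refused")
})

test_that("a (monthly, annually) dyad dichotomizes to (1, 0), averages to 0.5, and links", {
  ros <- make_roster(3)
  resp <- make_responses(ros,
    list("org01", "org01", "org02", "contact", "monthly"),
    list("org02", "org01", "org02", "contact", "annually"))
  m <- build_network(resp, ros, "contact")
  expect_equal(m$values["org01", "org02"], 1)
  # under a stricter threshold the same dyad is unlinked
  strict <- build_network(resp, ros, "contact",
                          config = tie_rule_config(discrepancy_threshold = 0.6))
  expect_equal(strict$values["org01", "org02"], 0)
})

test_that("saturated consistent contact input yields a complete symmetric network", {
  ros <- make_roster(3)
  rows <- list()
  for (i in 1:2) for (j in (i + 1):3) {
    a <- sprintf("org%02d", i); b <- sprintf("org%02d", j)
    rows <- c(rows, list(list(a, a, b, "contact", "weekly"),
                         list(b, a, b, "contact", "weekly")))
  }
  m <- build_network(do.call(make_responses, c(list(ros), rows)),
                     ros, "contact")
  expect_equal(network_density(m), 1)
  expect_identical(m$values, t(m$values))
  expect_false(any(m$missing))
})

test_that("reconstruction fills one-sided dyads and never touches two-respondent dyads", {
  ros <- make_roster(4, responded = c(TRUE, TRUE, TRUE, FALSE))
  resp <- make_responses(ros,
    list("org01", "org01", "org02", "contact", "annually"),
    list("org02", "org01", "org02", "contact", "annually"),
    list("org01", "org01", "org04", "contact", "daily"),
    list("org02", "org02", "org04", "contact", "none"))
  m <- build_network(resp, ros, "contact")
  expect_equal(m$values["org01", "org02"], 0)   # both responded: not imputed
  expect_false(m$imputed["org01", "org02"])
  expect_equal(m$values["org01", "org04"], 1)   # respondent reported a tie
  expect_true(m$imputed["org01", "org04"])
  expect_equal(m$values["org02", "org04"], 0)   # respondent reported no tie
  expect_true(m$imputed["org02", "org04"])
  expect_false(any(m$missing))
})

test_that("imputation is refused at or above 30% organization nonresponse", {
  ros <- make_roster(5, responded = c(TRUE, TRUE, TRUE, FALSE, FALSE))
  resp <- make_responses(ros,
    list("org01", "org01", "org02", "contact", "daily"))
  expect_error(build_network(resp, ros, "contact"), "refused")
})

test_that("dyads with two nonrespondent endpoints stay untied and flagged missing", {
  ros <- make_roster(10, responded = c(rep(TRUE, 8), FALSE, FALSE))
  resp <- make_responses(ros,
    list("org01", "org01", "org02", "contact", "daily"))
  expect_warning(m <- build_network(resp, ros, "contact"),
                 "no respondent endpoint")
  expect_equal(m$values["org09", "org10"], 0)
  expect_true(m$missing["org09", "org10"])
  expect_false(m$missing["org01", "org09"])    # one-sided: imputed, not missing
})

test_that("confirmed directed ties require both the sender and the receiver report", {
  ros <- make_roster(3)
  # org01 says it sent to org02; org02 confirms receiving
  # org01 says it sent to org03; org03 (a respondent) does not confirm
  resp <- make_responses(ros,
    list("org01", "org01", "org02", "referral", "1"),
    list("org02", "org01", "org02", "referral", "1"),
    list("org01", "org01", "org03", "referral", "1"))
  conf <- build_network(resp, ros, "referral", mode = "confirmed")
  unconf <- build_network(resp, ros, "referral", mode = "unconfirmed")
  expect_equal(conf$values["org01", "org02"], 1)
  expect_equal(conf$values["org01", "org03"], 0)
  expect_equal(unconf$values["org01", "org03"], 1)
  expect_error(confirm_ties(resp, ros, "contact"), "undirected")
})

test_that("directed dyads with a nonrespondent endpoint follow the fallback setting", {
  ros <- make_roster(3, responded = c(TRUE, TRUE, FALSE))
  resp <- make_responses(ros,
    list("org01", "org01", "org03", "referral", "1"))
  m <- build_network(resp, ros, "referral", mode = "confirmed")
  expect_equal(m$values["org01", "org03"], 1)
  expect_true(m$imputed["org01", "org03"])
  strict <- build_network(resp, ros, "referral", mode = "confirmed",
                          config = tie_rule_config(single_report_fallback = FALSE))
  expect_equal(strict$values["org01", "org03"], 0)
  expect_true(strict$missing["org01", "org03"])
})

test_that("a single reciprocally confirmed arc among 12 organizations yields exactly one arc", {
  ros <- make_roster(12)
  resp <- make_responses(ros,
    list("org01", "org01", "org02", "referral", "1"),
    list("org02", "org01", "org02", "referral", "1"))
  m <- build_network(resp, ros, "referral", mode = "confirmed")
  expect_equal(sum(m$values), 1)
  expect_equal(count_isolates(m)$count, 10)
})

test_that("confirmed arcs are a subset of unconfirmed arcs across random cases", {
  for (s in 1:20) {
    cfg <- noiseless_config(seed = s, n = 8, p = 0.4, fnr = 0.3, fpr = 0.1,
                            nonresponse = 0.1)
    ros <- generate_roster(cfg)
    truth <- generate_true_network(cfg, "referral", ros)
    resp <- generate_responses(truth, cfg)
    conf <- build_network(resp, ros, "referral", mode = "confirmed")
    unconf <- build_network(resp, ros, "referral", mode = "unconfirmed")
    expect_true(all(conf$values <= unconf$values))
  }
})

test_that("undirected builds are symmetric and monotone in the reported ordinal value", {
  ros <- make_roster(4)
  base <- list(
    list("org01", "org01", "org02", "contact", "biannually"),
    list("org02", "org01", "org02", "contact", "monthly"),
    list("org01", "org01", "org03", "contact", "weekly"),
    list("org03", "org01", "org03", "contact", "weekly"))
  m0 <- build_network(do.call(make_responses, c(list(ros), base)),
                      ros, "contact")
  expect_identical(m0$values, t(m0$values))
  # raising org01's report about org02 from biannually to daily cannot
  # delete any tie
  raised <- base
  raised[[1]][[5]] <- "daily"
  m1 <- build_network(do.call(make_responses, c(list(ros), raised)),
                      ros, "contact")
  expect_true(all(m1$values >= m0$values))
  # lowering org02's report cannot create one
  lowered <- base
  lowered[[2]][[5]] <- "none"
  m2 <- build_network(do.call(make_responses, c(list(ros), lowered)),
                      ros, "contact")
  expect_true(all(m2$values <= m0$values))
})

test_that("average-ordinal-first is a supported alternative discrepancy order", {
  ros <- make_roster(3)
  # codes: monthly=3, annually=1 -> mean 2 < 3 -> unlinked under
  # average_ordinal_first, linked under dichotomize_first
  resp <- make_responses(ros,
    list("org01", "org01", "org02", "contact", "monthly"),
    list("org02", "org01", "org02", "contact", "annually"))
  m_avg <- build_network(resp, ros, "contact",
                         config = tie_rule_config(
                           discrepancy_order = "average_ordinal_first"))
  expect_equal(m_avg$values["org01", "org02"], 0)
  # codes monthly=3, weekly=4 -> mean 3.5 >= 3 -> linked either way
  resp2 <- make_responses(ros,
    list("org01", "org01", "org02", "contact", "monthly"),
    list("org02", "org01", "org02", "contact", "weekly"))
  m2 <- build_network(resp2, ros, "contact",
                      config = tie_rule_config(
                        discrepancy_order = "average_ordinal_first"))
  expect_equal(m2$values["org01", "org02"], 1)
})

test_that("re-surveying a fully observed truth with one organization deleted restores it", {
  for (s in 1:10) {
    n <- 6 + (s %% 5)
    cfg <- noiseless_config(seed = s, n = n, p = 0.4)
    ros <- generate_roster(cfg)
    truth <- generate_true_network(cfg, "integration", ros)
    resp <- generate_responses(truth, cfg)
    # delete one (non-lead) organization's responses
    drop <- ros$org_id[2 + (s %% (n - 1))]
    ros2 <- ros
    ros2$responded[ros2$org_id == drop] <- FALSE
    resp2 <- dyadic_responses(
      as.data.frame(resp)[resp$reporter != drop,
                          c("reporter", "source", "target", "relation",
                            "value")], ros2)
    truth2 <- sociomatrix(truth$values, ros2, "integration")
    rebuilt <- build_network(resp2, ros2, "integration")
    expect_identical(rebuilt$values, truth2$values)
  }
})
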