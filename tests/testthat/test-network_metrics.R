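test_that("density matches closed forms and the pair-enumeration oracle", {
  # complete undirected n=4: all 6 edges
  ros <- make_roster(4)
  complete <- sociomatrix(1 - diag(4), ros, "contact")
  expect_equal(network_density(complete), 1)
  empty <- sociomatrix(matrix(0, 4, 4), ros, "contact")
  expect_equal(network_density(empty), 0)
  # directed n=12 with 30 arcs
  set.seed(11)
  v <- matrix(0, 12, 12)
  arcs <- sample(which(row(v) != col(v)), 30)
  v[arcs] <- 1
  m <- sociomatrix(v, make_roster(12), "referral", mode = "unconfirmed")
  expect_equal(network_density(m), 30 / 132)
  expect_equal(network_density(m), oracle_density(m$values, TRUE))
  # n < 2 is undefined
  expect_error(network_density(
    structure(list(values = matrix(0, 1, 1), directed = FALSE),
              class = "sociomatrix")), "n < 2")
})

test_that("dyad-level directed density counts unordered linked pairs", {
  ros <- make_roster(3)
  v <- matrix(0, 3, 3); v[1, 2] <- 1; v[2, 1] <- 1; v[1, 3] <- 1
  m <- sociomatrix(v, ros, "referral", mode = "unconfirmed")
  expect_equal(network_density(m), 3 / 6)         # arc level
  expect_equal(network_density(m, "dyad"), 2 / 3) # {1,2}, {1,3} linked
})

test_that("degree centralities match direct counts on canonical graphs", {
  # undirected star n=5
  ros <- make_roster(5)
  v <- matrix(0, 5, 5); v[1, 2:5] <- 1; v[2:5, 1] <- 1
  star <- sociomatrix(v, ros, "contact")
  expect_equal(unname(degree_centrality(star)), c(4L, 1L, 1L, 1L, 1L))
  expect_error(degree_centrality(star, "in"), "directed")
  # directed single arc
  ros3 <- make_roster(3)
  a <- matrix(0, 3, 3); a[1, 2] <- 1
  arc <- sociomatrix(a, ros3, "referral", mode = "unconfirmed")
  expect_equal(unname(degree_centrality(arc, "out")), c(1L, 0L, 0L))
  expect_equal(unname(degree_centrality(arc, "in")), c(0L, 1L, 0L))
  expect_equal(unname(degree_centrality(arc, "total")), c(1L, 1L, 0L))
})

test_that("density, centralities and centralization match brute force on 200 seeded graphs", {
  set.seed(20240917)
  for (k in 1:200) {
    n <- sample(3:7, 1)
    directed <- k %% 2 == 0
    p <- runif(1, 0.1, 0.9)
    m <- rand_sociomatrix(n, p, directed)
    expect_equal(network_density(m), oracle_density(m$values, directed))
    bases <- if (directed) c("in", "out", "total") else "total"
    for (b in bases) {
      expect_equal(unname(degree_centrality(m, b)),
                   oracle_degrees(m$values, directed, b))
    }
    cb <- if (directed) sample(c("in", "out"), 1) else "total"
    expect_equal(freeman_centralization(m, cb),
                 oracle_centralization(m$values, directed, cb))
  }
})

test_that("centralization agrees with igraph's Freeman index", {
  set.seed(99)
  for (k in 1:25) {
    directed <- k %% 2 == 0
    m <- rand_sociomatrix(sample(4:9, 1), runif(1, 0.2, 0.8), directed)
    g <- as_igraph(m)
    if (directed) {
      expect_equal(freeman_centralization(m, "in"),
                   igraph::centr_degree(g, mode = "in",
                                        loops = FALSE)$centralization)
      expect_equal(freeman_centralization(m, "out"),
                   igraph::centr_degree(g, mode = "out",
                                        loops = FALSE)$centralization)
    } else {
      expect_equal(freeman_centralization(m),
                   igraph::centr_degree(g, loops = FALSE)$centralization)
    }
  }
})

test_that("stars achieve centralization 1 and regular graphs 0, for n in 3..10", {
  for (n in 3:10) {
    ros <- make_roster(n)
    v <- matrix(0, n, n); v[1, 2:n] <- 1; v[2:n, 1] <- 1
    expect_equal(freeman_centralization(sociomatrix(v, ros, "contact")), 1)
    complete <- sociomatrix(1 - diag(n), ros, "contact")
    expect_equal(freeman_centralization(complete), 0)
    expect_equal(network_density(complete), 1)
    empty <- sociomatrix(matrix(0, n, n), ros, "contact")
    expect_equal(freeman_centralization(empty), 0)  # all-zero convention
    expect_equal(network_density(empty), 0)
    # directed star: all arcs into the hub
    vin <- matrix(0, n, n); vin[2:n, 1] <- 1
    din <- sociomatrix(vin, ros, "referral", mode = "unconfirmed")
    expect_equal(freeman_centralization(din, "in"), 1)
  }
  # path on 4 nodes: degrees 1,2,2,1 -> 2 / 6
  ros <- make_roster(4)
  v <- matrix(0, 4, 4)
  v[1, 2] <- v[2, 1] <- v[2, 3] <- v[3, 2] <- v[3, 4] <- v[4, 3] <- 1
  expect_equal(freeman_centralization(sociomatrix(v, ros, "contact")), 1 / 3)
  expect_error(freeman_centralization(
    sociomatrix(matrix(0, 2, 2), make_roster(2), "contact")), "n < 3")
})

test_that("the interpretive bands reproduce the printed score-band pairings", {
  cases <- data.frame(
    score = c(0.400, 0.229, 0.242, 0.500, 0.648),
    band = c("moderate", "low", "low", "moderate", "high"))
  expect_equal(classify_band(cases$score), cases$band)
  # boundaries: 0.30 and 0.50 are both moderate
  expect_equal(classify_band(c(0.30, 0.50)), c("moderate", "moderate"))
  expect_equal(classify_band(c(0.2999, 0.5001)), c("low", "high"))
  expect_equal(classify_band(c(0, 1)), c("low", "high"))
  expect_error(classify_band(1.2), "\\[0, 1\\]")
})

test_that("isolates are organizations with zero total degree", {
  ros <- make_roster(5)
  empty <- sociomatrix(matrix(0, 5, 5), ros, "contact")
  expect_equal(count_isolates(empty)$count, 5)
  complete <- sociomatrix(1 - diag(5), ros, "contact")
  expect_equal(count_isolates(complete)$count, 0)
  # a node with only an incoming arc is not an isolate
  v <- matrix(0, 5, 5); v[1, 2] <- 1
  m <- sociomatrix(v, ros, "referral", mode = "unconfirmed")
  iso <- count_isolates(m)
  expect_equal(iso$count, 3)
  expect_false("org02" %in% iso$org_ids)
})

test_that("response rates reproduce the study's printed percentages", {
  expect_equal(response_rate(
    make_roster(15, responded = c(rep(TRUE, 14), FALSE))), 93.3)
  expect_equal(response_rate(
    make_roster(12, responded = c(rep(TRUE, 11), FALSE))), 91.7)
  expect_equal(response_rate(make_roster(9)), 100.0)
})

test_that("network-level metrics are invariant to roster relabeling", {
  set.seed(5)
  for (directed in c(FALSE, TRUE)) {
    m <- rand_sociomatrix(7, 0.4, directed)
    perm <- sample(7)
    ros_p <- roster(m$roster$org_id,
                    org_type = m$roster$org_type[perm],
                    is_lead = m$roster$is_lead[perm],
                    responded = m$roster$responded[perm])
    mp <- sociomatrix(m$values[perm, perm], ros_p, m$relation,
                      directed = directed, mode = m$mode)
    expect_equal(network_density(mp), network_density(m))
    b <- if (directed) "in" else "total"
    expect_equal(freeman_centralization(mp, b),
                 freeman_centralization(m, b))
    expect_equal(count_isolates(mp)$count, count_isolates(m)$count)
    expect_equal(sort(unname(degree_centrality(mp))),
                 sort(unname(degree_centrality(m))))
  }
})

test_that("adding a tie never decreases density, and metrics stay in [0, 1]", {
  set.seed(8)
  for (k in 1:20) {
    m <- rand_sociomatrix(6, 0.3, directed = k %% 2 == 0)
    d0 <- network_density(m)
    expect_gte(d0, 0); expect_lte(d0, 1)
    open <- which(m$values == 0 & row(m$values) != col(m$values))
    if (!length(open)) next
    v <- m$values
    idx <- open[1]
    v[idx] <- 1
    if (!m$directed) v[col(v)[idx], row(v)[idx]] <- 1
    m2 <- sociomatrix(v, m$roster, m$relation, directed = m$directed,
                      mode = m$mode)
    expect_gte(network_density(m2), d0)
  }
})

test_that("the metrics report assembles every measure consistently", {
  set.seed(3)
  m <- rand_sociomatrix(8, 0.35, directed = TRUE)
  mm <- network_metrics(m)
  expect_equal(mm$density, network_density(m))
  expect_equal(mm$centralization, freeman_centralization(m, "in"))
  expect_equal(mm$centralization_basis, "in")
  expect_equal(mm$L, sum(m$values))
  expect_equal(mm$density_band, classify_band(mm$density))
  expect_named(mm$per_node, c("org_id", "degree", "in_degree", "out_degree"))
  path <- withr::local_tempfile(fileext = ".json")
  write_metrics_json(mm, path)
  parsed <- jsonlite::read_json(path)
  expect_equal(parsed$density, round(mm$density, 3))
  expect_equal(parsed$response_rate, mm$response_rate)
})
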