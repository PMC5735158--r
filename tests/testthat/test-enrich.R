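test_that("standard enrichment p-values match the enumeration oracle", {
  universe <- sprintf("g%03d", 1:100)
  sets <- list(S = universe[1:10])
  query <- c(universe[6:10], universe[90:94])
  res <- standard_enrichment(query, sets, universe)
  expect_equal(res$p, enum_upper_tail(5, 5, 5, 85), tolerance = 1e-12)
  expect_equal(res$n_overlap, 5L)
  # random configurations
  set.seed(7)
  for (i in 1:50) {
    n_u <- sample(20:60, 1)
    u <- sprintf("u%03d", seq_len(n_u))
    s <- sample(u, sample(3:10, 1))
    q <- sample(u, sample(3:10, 1))
    a <- length(intersect(q, s))
    res <- standard_enrichment(q, list(S = s), u)
    expect_equal(res$p,
                 enum_upper_tail(a, length(q) - a, length(s) - a,
                                 n_u - length(q) - length(s) + a),
                 tolerance = 1e-10)
  }
})

test_that("degenerate queries behave sensibly", {
  u <- sprintf("g%02d", 1:40)
  sets <- list(A = u[1:10], B = u[11:20])
  # zero overlap: the upper tail covers everything
  res <- standard_enrichment(u[21:30], sets, u)
  expect_true(all(res$p > 0.5))
  # query identical to a set: that set is the extreme, rank 1
  res2 <- standard_enrichment(u[1:10], sets, u)
  expect_equal(res2$target[1], "A")
  expect_lt(res2$p[1], res2$p[2])
  expect_error(standard_enrichment(character(), sets, u), "empty query")
  expect_error(standard_enrichment("nope", sets, u), "disjoint")
})

test_that("unit construction enumerates connected pairs and triples once", {
  sets <- list(A = c("p1", "x1"), B = c("p2", "x2"), C = c("p3", "x3"),
               D = c("p4", "x4"))
  pert <- c("p1", "p2", "p3", "p4")
  chain <- structure(data.frame(
    removed_scp = c("A", "B"), remaining_scp = c("B", "C"),
    score = c(2, 1), contributing_genes = "", stringsAsFactors = FALSE),
    class = c("scp_edges", "data.frame"))
  units <- build_units(pert, sets, chain)
  expect_setequal(names(units), c("A+B", "B+C", "A+B+C"))
  expect_setequal(units[["A+B+C"]], c("p1", "x1", "p2", "x2", "p3", "x3"))
  # triangle: three pairs plus the triple, emitted once
  tri <- structure(data.frame(
    removed_scp = c("A", "B", "A"), remaining_scp = c("B", "C", "C"),
    score = c(3, 2, 1), contributing_genes = "", stringsAsFactors = FALSE),
    class = c("scp_edges", "data.frame"))
  units <- build_units(pert, sets, tri)
  expect_setequal(names(units), c("A+B", "A+C", "B+C", "A+B+C"))
  # edge insertion order does not matter
  tri2 <- tri[c(3, 1, 2), ]
  expect_identical(build_units(pert, sets, tri2), units)
  # an SCP without perturbed genes joins no unit
  units <- build_units(c("p1", "p2"), sets, tri)
  expect_setequal(names(units), "A+B")
  # max_size = 2 suppresses triples
  units <- build_units(pert, sets, tri, max_size = 2)
  expect_setequal(names(units), c("A+B", "A+C", "B+C"))
})

test_that("dynamic enrichment with no edges equals standard enrichment", {
  tax <- tiny_tax()
  tab <- assoc_from_sets(list(`C1.a.x` = c("a", "b", "c"),
                              `C1.a.y` = c("d", "e"),
                              `C1.b.x` = c("f", "g"),
                              `C2.a.x` = c("h", "i", "j")))
  no_edges <- structure(data.frame(
    removed_scp = character(), remaining_scp = character(),
    score = numeric(), contributing_genes = character(),
    stringsAsFactors = FALSE), class = c("scp_edges", "data.frame"))
  dyn <- dynamic_enrichment(c("a", "b", "d"), tab, tax, no_edges)
  std <- standard_enrichment(c("a", "b", "d"),
                             gene_sets_by_level(tab, tax, 3))
  expect_equal(dyn$target, std$target)
  expect_equal(dyn$p, std$p)
  expect_equal(dyn$overlap_genes, std$overlap_genes)
  expect_length(attr(dyn, "units"), 0L)
})

test_that("a merged unit outranks its members when hits span both", {
  tax <- tiny_tax()
  sets <- list(`C1.a.x` = sprintf("a%02d", 1:10),
               `C1.a.y` = sprintf("b%02d", 1:10),
               `C1.b.x` = sprintf("c%02d", 1:10),
               `C2.a.x` = sprintf("d%02d", 1:70))
  tab <- assoc_from_sets(sets)
  edges <- structure(data.frame(
    removed_scp = "C1.a.x", remaining_scp = "C1.a.y", score = 2,
    contributing_genes = "", stringsAsFactors = FALSE),
    class = c("scp_edges", "data.frame"))
  query <- c(sprintf("a%02d", 1:5), sprintf("b%02d", 1:5))
  dyn <- dynamic_enrichment(query, tab, tax, edges, q = 1)
  expect_equal(dyn$target[1], "C1.a.x+C1.a.y")
  expect_lt(dyn$p[1], min(dyn$p[dyn$target %in% c("C1.a.x", "C1.a.y")]))
  # hits concentrated in one SCP: the singleton wins instead
  dyn2 <- dynamic_enrichment(sprintf("a%02d", 1:8), tab, tax, edges, q = 1)
  expect_equal(dyn2$target[1], "C1.a.x")
})

test_that("unit p-values can fall on either side of their members'", {
  u <- sprintf("g%03d", 1:80)
  sets <- list(A = u[1:10], B = u[11:20])
  edges <- structure(data.frame(
    removed_scp = "A", remaining_scp = "B", score = 1,
    contributing_genes = "", stringsAsFactors = FALSE),
    class = c("scp_edges", "data.frame"))
  units <- build_units(c(u[1], u[11]), sets, edges)
  # split hits: union better
  q1 <- c(u[1:4], u[11:14])
  r1 <- standard_enrichment(q1, c(sets, units), u)
  expect_lt(r1$p[r1$target == "A+B"], r1$p[r1$target == "A"])
  # concentrated hits: union worse
  q2 <- u[1:8]
  r2 <- standard_enrichment(q2, c(sets, units), u)
  expect_gt(r2$p[r2$target == "A+B"], r2$p[r2$target == "A"])
})

test_that("context network keeps the largest component and its ancestors", {
  tax <- tiny_tax()
  tab <- assoc_from_sets(list(`C1.a.x` = c("a1", "a2"),
                              `C1.a.y` = c("b1", "b2"),
                              `C1.b.x` = c("c1", "c2"),
                              `C2.a.x` = c("d1", "d2")))
  edges <- structure(data.frame(
    removed_scp = c("C1.a.x", "C1.a.y"),
    remaining_scp = c("C1.a.y", "C1.b.x"),
    score = c(2, 1), contributing_genes = "", stringsAsFactors = FALSE),
    class = c("scp_edges", "data.frame"))
  res <- dynamic_enrichment(c("a1", "a2", "b1", "c1", "d1"), tab, tax,
                            edges, q = 1, top_k = 5)
  net <- extract_context_network(res, edges, tax)
  members <- net$nodes$scp_id[net$nodes$role == "member"]
  expect_setequal(members, c("C1.a.x", "C1.a.y", "C1.b.x"))
  expect_setequal(net$nodes$scp_id[net$nodes$role == "ancestor"],
                  c("C1", "C1.a", "C1.b"))
  expect_equal(nrow(net$edges), 2L)
  # all singletons unconnected: the component holding the best result wins
  iso <- structure(data.frame(
    removed_scp = character(), remaining_scp = character(),
    score = numeric(), contributing_genes = character(),
    stringsAsFactors = FALSE), class = c("scp_edges", "data.frame"))
  res2 <- dynamic_enrichment(c("a1", "a2", "b1"), tab, tax, iso, q = 1)
  net2 <- extract_context_network(res2, iso, tax)
  expect_equal(net2$nodes$scp_id[net2$nodes$role == "member"],
               res2$target[1])
})
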