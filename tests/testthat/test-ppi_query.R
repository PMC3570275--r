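test_that("induced subnetwork keeps only edges among queried genes", {
  g <- toy_interactome()
  sub <- induce_subnetwork(c("A2M", "APP", "APOE"), g)
  expect_setequal(sub$nodes$node_id, c("A2M", "APOE", "APP"))
  expect_identical(sub$edges$a, c("A2M", "APOE"))
  expect_identical(sub$edges$b, c("APOE", "APP"))
})

test_that("single-gene query gives one node and no edges", {
  sub <- induce_subnetwork("APP", toy_interactome())
  expect_equal(glance(sub)$n_nodes, 1)
  expect_equal(glance(sub)$n_edges, 0)
})

test_that("querying all nodes returns the original graph", {
  g <- random_interactome(30, 60, 9)
  sub <- induce_subnetwork(g$nodes$node_id, g)
  expect_identical(sub$edges, g$edges)
  expect_setequal(sub$nodes$node_id, g$nodes$node_id)
})

test_that("unresolvable queries warn but are not fatal; empty query warns", {
  g <- toy_interactome()
  expect_warning(sub <- induce_subnetwork(c("APP", "NOSUCH"), g), "NOSUCH")
  expect_equal(attr(sub, "unresolved"), "NOSUCH")
  expect_warning(empty <- induce_subnetwork(character(), g), "empty")
  expect_equal(glance(empty)$n_nodes, 0)
})

test_that("identifiers resolve by node id, gene id, symbol, protein id", {
  g <- toy_interactome()
  res <- resolve_ids(g, c("ANG", "283", "ang", "P60484"))
  expect_equal(res$node_id, c("ANG", "ANG", "ANG", "PTEN"))
})

test_that("ambiguous symbols raise a lookup error naming candidates", {
  g <- interactome(
    edges = tibble::tibble(a = "n1", b = "n2"),
    nodes = tibble::tibble(node_id = c("n1", "n2"), symbol = c("DUP", "DUP"))
  )
  expect_error(resolve_ids(g, "dup"), "n1, n2", class = "sgpnet_lookup_error")
})

test_that("ANG first neighbourhood is the seven case-study proteins", {
  nb <- expand_neighborhood("ANG", 1, toy_interactome())
  expect_setequal(
    setdiff(nb$nodes$node_id, "ANG"),
    c("ACTC1", "ACTN2", "ATP6AP1", "PTEN", "RNH1", "TDGF1", "TNFSF8")
  )
  lv <- neighborhood_levels(nb)
  expect_equal(lv$n_new_nodes, c(1, 7))
  expect_equal(lv$n_edges[2], 7)
})

test_that("path graph expansion follows BFS distances", {
  g <- interactome(tibble::tibble(a = c("a", "b", "c"), b = c("b", "c", "d")))
  nb <- expand_neighborhood("a", 2, g)
  expect_setequal(nb$nodes$node_id, c("a", "b", "c"))
  expect_equal(nrow(nb$edges), 2)
})

test_that("seed lookup and degree range are enforced", {
  g <- toy_interactome()
  expect_error(expand_neighborhood("NOSUCH", 1, g), class = "sgpnet_lookup_error")
  expect_error(expand_neighborhood("ANG", 0, g), class = "sgpnet_argument_error")
  expect_error(expand_neighborhood("ANG", 4, g), class = "sgpnet_argument_error")
  expect_silent(expand_neighborhood("ANG", 4, g, cap = 5))
})

test_that("neighborhoods are nested in k and match a brute-force BFS", {
  g <- random_interactome(200, 600, 7)
  d <- oracle_bfs_distances(g$edges, g$nodes$node_id, "g001")
  prev <- character()
  for (k in 1:3) {
    nb <- expand_neighborhood("g001", k, g)
    expect_true(all(prev %in% nb$nodes$node_id))
    expect_setequal(nb$nodes$node_id, names(d)[d <= k])
    # induced-subgraph contract, by brute force over the edge list
    ball <- names(d)[d <= k]
    expect_equal(nrow(nb$edges),
                 sum(g$edges$a %in% ball & g$edges$b %in% ball))
    prev <- nb$nodes$node_id
  }
})

test_that("k=1 neighborhood equals seed plus adjacency", {
  g <- random_interactome(50, 120, 21)
  nb <- expand_neighborhood("g005", 1, g)
  adjacent <- unique(c(g$edges$b[g$edges$a == "g005"],
                       g$edges$a[g$edges$b == "g005"]))
  expect_setequal(nb$nodes$node_id, union("g005", adjacent))
})

test_that("self-loops are stored but excluded from expansion by default", {
  g <- interactome(tibble::tibble(a = c("a", "a"), b = c("a", "b")))
  expect_equal(glance(g)$n_edges, 2)
  nb <- expand_neighborhood("a", 1, g)
  expect_setequal(nb$nodes$node_id, c("a", "b"))
  expect_equal(nrow(nb$edges), 1)
  with_loops <- expand_neighborhood("a", 1, g, include_self_loops = TRUE)
  expect_equal(nrow(with_loops$edges), 2)
})

test_that("term filtering induces the annotated subgraph and is idempotent", {
  nb <- expand_neighborhood("ANG", 1, toy_interactome())
  apo <- filter_network(nb, "function", "apoptosis")
  expect_setequal(apo$nodes$node_id,
                  c("TDGF1", "PTEN", "ACTN2", "TNFSF8", "ATP6AP1"))
  again <- filter_network(apo, "function", "apoptosis")
  expect_setequal(again$nodes$node_id, apo$nodes$node_id)
  none <- filter_network(nb, "function", "no-such-term")
  expect_equal(glance(none)$n_nodes, 0)
})

test_that("grouping partitions nodes annotated with exactly one term", {
  g <- interactome(
    edges = tibble::tibble(a = c("x", "y"), b = c("y", "z")),
    annotations = tibble::tibble(
      node_id = c("x", "y", "z"),
      category = "pathway",
      term = c("p1", "p1", "p2")
    )
  )
  groups <- filter_network(g, "pathway")
  all_ids <- sort(unlist(groups$node_ids))
  expect_equal(all_ids, c("x", "y", "z"))    # a partition: no repeats
  expect_error(filter_network(g, "colour"), class = "sgpnet_argument_error")
})
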