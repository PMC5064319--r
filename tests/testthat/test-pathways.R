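# Shortest-path enumeration, CR index, selective betweenness.

named_graph <- function(edges, n) {
  g <- igraph::make_graph(edges, n = n, directed = FALSE)
  igraph::V(g)$name <- paste("A", "LEU", seq_len(n), sep = ":")
  g
}
nd <- function(i) paste("A", "LEU", i, sep = ":")

test_that("path sets on canonical small graphs", {
  # 4-cycle, opposite corners: l=2, sigma=2
  g <- named_graph(c(1, 2, 2, 3, 3, 4, 4, 1), 4)
  ps <- path_set(g, nd(1), nd(3))
  expect_equal(ps$l, 2)
  expect_equal(ps$sigma_AB, 2)
  expect_equal(length(ps$paths), 2)
  # complete graph K5: direct edge
  k5 <- igraph::make_full_graph(5)
  igraph::V(k5)$name <- paste("A", "LEU", 1:5, sep = ":")
  ps <- path_set(k5, nd(1), nd(4))
  expect_equal(ps$l, 1)
  expect_equal(ps$sigma_AB, 1)
  # disconnected pair
  g2 <- named_graph(c(1, 2), 4)
  ps <- path_set(g2, nd(1), nd(4))
  expect_equal(ps$l, Inf)
  expect_equal(ps$sigma_AB, 0)
  expect_equal(length(ps$paths), 0)
})

test_that("path counts and lists match the exhaustive oracle", {
  for (seed in 1:12) {
    n <- 5 + (seed %% 8)
    rg <- random_test_graph(n, 0.45, seed)
    for (a in 1:(n - 1)) for (b in (a + 1):n) {
      orc <- oracle_sigma(rg$adj, a, b)
      ps <- path_set(rg$graph, nd(a), nd(b))
      expect_equal(ps$l, orc$l)
      expect_equal(ps$sigma_AB, orc$sigma)
      if (is.finite(orc$l)) {
        op <- oracle_paths(rg$adj, a, b, orc$l)
        canon <- function(x) sort(vapply(x, paste, character(1), collapse = ">"))
        expect_equal(canon(ps$paths),
                     canon(lapply(op, function(p) nd(p))))
      }
    }
  }
})

test_that("explicit path list is capped but counting stays exact", {
  # ladder of diamonds: sigma grows as 2^k
  edges <- c()
  for (k in 0:5) {
    a <- 3 * k + 1
    edges <- c(edges, a, a + 1, a, a + 2, a + 1, a + 3, a + 2, a + 3)
  }
  g <- named_graph(edges, 19)
  ps <- path_set(g, nd(1), nd(19), cap = 10)
  expect_equal(ps$sigma_AB, 2^6)
  expect_equal(length(ps$paths), 10)
  expect_true(ps$truncated)
})

test_that("CR index obeys its contract", {
  expect_equal(cr_index(10, 5, 0.25), 0.5)
  expect_equal(cr_index(0, NA, 0.25), 0)
  expect_error(cr_index(-1, 2, 0.25), "non-negative")
  expect_error(cr_index(3, 2, 1.2))
  # strict monotonicities on a grid
  sig <- c(1, 2, 5, 10, 20); ls <- c(1, 2, 3, 5, 8); pts <- c(0.1, 0.25, 0.4, 0.6)
  for (l in ls) for (p in pts)
    expect_true(all(diff(cr_index(sig, l, p)) > 0))
  for (s_ in sig) for (p in pts)
    expect_true(all(diff(cr_index(s_, ls, p)) < 0))
  for (s_ in sig) for (l in ls)
    expect_true(all(diff(cr_index(s_, l, pts)) > 0))
})

test_that("selective betweenness matches enumeration and conserves counts", {
  # 4-cycle: intermediate corners carry SB 1/2
  g <- named_graph(c(1, 2, 2, 3, 3, 4, 4, 1), 4)
  sb <- selective_betweenness(g, nd(1), nd(3))
  expect_equal(sb$sb[sb$node %in% c(nd(2), nd(4))], c(0.5, 0.5))
  expect_equal(sb$sb[sb$node %in% c(nd(1), nd(3))], c(1, 1))
  # unique path: every internal node carries SB 1
  pg <- named_graph(c(1, 2, 2, 3, 3, 4), 4)
  sb <- selective_betweenness(pg, nd(1), nd(4))
  expect_equal(sb$sb, c(1, 1, 1, 1))
  # random graphs: sigma_v equals explicit-path counting; conservation
  for (seed in 1:10) {
    n <- 6 + (seed %% 7)
    rg <- random_test_graph(n, 0.5, seed + 50)
    a <- 1; b <- n
    orc <- oracle_sigma(rg$adj, a, b)
    sb <- selective_betweenness(rg$graph, nd(a), nd(b))
    if (!is.finite(orc$l)) { expect_true(all(sb$sb == 0)); next }
    paths <- oracle_paths(rg$adj, a, b, orc$l)
    through <- table(unlist(lapply(paths, function(p) p[-c(1, length(p))])))
    for (v in setdiff(seq_len(n), c(a, b))) {
      expected <- if (as.character(v) %in% names(through))
        as.numeric(through[[as.character(v)]]) else 0
      expect_equal(sb$sigma_v[sb$node == nd(v)], expected)
    }
    internal <- setdiff(seq_len(n), c(a, b))
    expect_equal(sum(sb$sigma_v[sb$node %in% nd(internal)]),
                 orc$sigma * (orc$l - 1))
  }
})

test_that("max-SB path selection is deterministic and recovers unique paths", {
  pg <- named_graph(c(1, 2, 2, 3, 3, 4), 4)
  expect_equal(max_sb_path(pg, nd(1), nd(4)), nd(1:4))
  # 4-cycle: both arms tie; lexicographic tie-break picks the smaller id
  g <- named_graph(c(1, 2, 2, 3, 3, 4, 4, 1), 4)
  p1 <- max_sb_path(g, nd(1), nd(3))
  expect_equal(p1, c(nd(1), nd(2), nd(3)))  # "A:LEU:2" < "A:LEU:4"
  expect_equal(max_sb_path(g, nd(1), nd(3)), p1)
  # disconnected: empty
  g2 <- named_graph(c(1, 2), 4)
  expect_equal(length(max_sb_path(g2, nd(1), nd(4))), 0)
})

test_that("adding an edge never lengthens a shortest path", {
  for (seed in 1:6) {
    rg <- random_test_graph(9, 0.35, seed + 200)
    ps0 <- path_set(rg$graph, nd(1), nd(9))
    miss <- which(rg$adj == 0 & upper.tri(rg$adj), arr.ind = TRUE)
    if (!nrow(miss)) next
    pick <- miss[1 + (seed %% nrow(miss)), ]
    g2 <- igraph::add_edges(rg$graph, c(pick[1], pick[2]))
    ps1 <- path_set(g2, nd(1), nd(9))
    expect_lte(ps1$l, ps0$l)
  }
})

test_that("CR matrices flag missing nodes and match per-pair recomputation", {
  rg <- random_test_graph(10, 0.5, 77)
  src <- nd(c(1, 2)); snk <- nd(c(9, 10))
  m <- cr_matrix(rg$graph, src, snk, p_T = 0.25)
  expect_equal(nrow(m), 4)
  for (r in seq_len(nrow(m))) {
    ps <- path_set(rg$graph, m$source[r], m$sink[r])
    expect_equal(m$sigma_AB[r], ps$sigma_AB)
    expect_equal(m$cr[r],
                 if (ps$sigma_AB == 0) 0 else cr_index(ps$sigma_AB, ps$l, 0.25))
  }
  m2 <- cr_matrix(rg$graph, nd(1), "A:GLY:99", p_T = 0.25)
  expect_false(m2$in_graph[1])
  expect_true(is.na(m2$cr[1]))
})

test_that("cross-state comparison annotates maxima and enforces pair matching", {
  rg <- random_test_graph(8, 0.6, 5)
  a <- cr_matrix(rg$graph, nd(1), nd(c(7, 8)), p_T = 0.2)
  b <- a; b$cr <- b$cr * 2
  cmp <- compare_states(list(s1 = a, s2 = b))
  expect_true(all(cmp$max_state == "s2"))
  cmp_tie <- compare_states(list(s1 = a, s2 = a))
  expect_true(all(cmp_tie$max_state == "tie"))
  bad <- a; bad$sink[1] <- nd(2)
  expect_error(compare_states(list(s1 = a, s2 = bad)), "mismatched")
})
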