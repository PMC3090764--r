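test_that("positive-edge subdivision preserves the line index", {
  # all-negative input is returned unchanged
  g <- signed_graph(data.frame(name = c("a", "b"), color = "grey"),
                    data.frame(u = 1L, v = 2L, sign = -1L))
  expect_equal(nrow(to_all_negative(g)$edges), 1L)

  # single positive edge between greys: still line index 0 as a 2-path
  g2 <- signed_graph(data.frame(name = c("a", "b"), color = "grey"),
                     data.frame(u = 1L, v = 2L, sign = 1L))
  gn2 <- to_all_negative(g2)
  expect_equal(nrow(gn2$vertices), 3L)
  expect_true(all(gn2$edges$sign == -1L))
  expect_equal(line_index_bruteforce(gn2)$value, 0L)

  for (s in 1:150) {
    g <- rand_signed_graph(4000 + s)
    gn <- to_all_negative(g)
    expect_true(all(gn$edges$sign == -1L))
    expect_equal(line_index_bruteforce(gn)$value,
                 line_index_bruteforce(g)$value)
  }
})

test_that("supernode merge keeps parallel edges and adds k+1 guards", {
  g <- signed_graph(
    data.frame(name = c("r1", "r2", "g1", "x"),
               color = c("red", "red", "green", "grey")),
    data.frame(u = c(1L, 2L), v = c(4L, 4L), sign = c(-1L, -1L)))
  mg <- merge_and_guard(g, k = 2)
  expect_equal(nrow(mg$graph$vertices), 3L)  # .red, .green, x
  expect_equal(mg$guard_count, 3L)
  expect_equal(sum(mg$graph$edges$etype == "guard"), 3L)
  expect_equal(sum(mg$graph$edges$etype != "guard"), 2L)  # parallels kept
  expect_true(all(mg$graph$vertices$color == "grey"))

  # all-grey graph: nothing merged, no guards
  g2 <- signed_graph(data.frame(name = c("a", "b"), color = "grey"),
                     data.frame(u = 1L, v = 2L, sign = -1L))
  mg2 <- merge_and_guard(g2, k = 2)
  expect_equal(mg2$guard_count, 0L)
  expect_equal(nrow(mg2$graph$vertices), 2L)

  # any budget-feasible solution must separate the supernodes: with the
  # guards in place the solved optimum equals the line index, and no
  # guard edge is ever removed
  for (s in 1:40) {
    g <- rand_signed_graph(4500 + s, max_e = 10)
    bf <- line_index_bruteforce(g)$value
    gn <- to_all_negative(g)
    mg <- merge_and_guard(gn, k = bf)
    inst <- negate_weights(mg$graph)
    C <- edge_bipartization(inst)
    expect_equal(length(C) + mg$extra_cost, bf)
    expect_true(all(inst$edges$tag[C] != "guard"))
  }
})

test_that("negation turns frustration into monochromatic edge removal", {
  tri <- signed_graph(data.frame(name = c("a", "b", "c"), color = "grey"),
                      data.frame(u = c(1L, 2L, 1L), v = c(2L, 3L, 3L),
                                 sign = -1L))
  inst <- negate_weights(tri)
  expect_equal(bipartization_bruteforce(inst)$size, 1L)
  even <- signed_graph(data.frame(name = paste0("v", 1:4), color = "grey"),
                       data.frame(u = c(1L, 2L, 3L, 4L), v = c(2L, 3L, 4L, 1L),
                                  sign = -1L))
  expect_equal(bipartization_bruteforce(negate_weights(even))$size, 0L)
  empty <- signed_graph()
  expect_equal(bipartization_bruteforce(negate_weights(empty))$size, 0L)
})

test_that("minimum edge cuts match brute force and respect the limit", {
  # three parallel edges need a cut of three
  e3 <- data.frame(u = c(1L, 1L, 1L), v = c(2L, 2L, 2L))
  expect_length(min_edge_cut(e3, 2L, 1L, 2L, limit = 3), 3L)
  expect_null(min_edge_cut(e3, 2L, 1L, 2L, limit = 2))
  # disconnected terminals: empty cut
  e0 <- data.frame(u = 1L, v = 2L)
  expect_length(min_edge_cut(e0, 4L, 3L, 4L), 0L)
  # random graphs: cut size equals the enumeration minimum
  for (s in 1:60) {
    set.seed(6000 + s)
    n <- sample(4:7, 1)
    m <- sample(3:10, 1)
    ed <- data.frame(u = sample(n, m, replace = TRUE),
                     v = sample(n, m, replace = TRUE))
    ed <- ed[ed$u != ed$v, , drop = FALSE]
    if (!nrow(ed)) next
    cut <- min_edge_cut(ed, n, 1L, n)
    # enumeration: smallest edge subset whose removal disconnects 1 from n
    reach <- function(keep) {
      adj <- rep(list(integer(0)), n)
      for (i in keep) {
        adj[[ed$u[i]]] <- c(adj[[ed$u[i]]], ed$v[i])
        adj[[ed$v[i]]] <- c(adj[[ed$v[i]]], ed$u[i])
      }
      seen <- rep(FALSE, n)
      seen[1] <- TRUE
      q <- 1L
      while (length(q)) {
        x <- q[1]
        q <- q[-1]
        for (y in adj[[x]]) if (!seen[y]) { seen[y] <- TRUE; q <- c(q, y) }
      }
      seen[n]
    }
    best <- Inf
    if (!reach(seq_len(nrow(ed)))) {
      best <- 0L
    } else {
      for (size in 1:nrow(ed)) {
        for (comb in utils::combn(nrow(ed), size, simplify = FALSE)) {
          if (!reach(setdiff(seq_len(nrow(ed)), comb))) {
            best <- size
            break
          }
        }
        if (is.finite(best)) break
      }
    }
    expect_equal(length(cut), best)
    expect_false(reach(setdiff(seq_len(nrow(ed)), cut)))
  }
})

test_that("compression finds a smaller set exactly when one exists", {
  # even cycle with one edge declared removed: compress to the empty set
  cyc <- cbind(c(1L, 2L, 3L, 4L), c(2L, 3L, 4L, 1L))
  y <- compress_bipartization(cyc, 4L, xprime = 1L)
  expect_length(y, 0L)
  # triangle: no bipartization of size 0 exists
  tri <- cbind(c(1L, 2L, 1L), c(2L, 3L, 3L))
  expect_null(compress_bipartization(tri, 3L, xprime = 1L))
})

test_that("iterative compression reaches the enumeration optimum", {
  c5 <- structure(list(n = 5L, names = paste0("v", 1:5),
                       edges = data.frame(u = 1:5, v = c(2:5, 1L),
                                          tag = "graph", orig = 1:5)),
                  class = "bipartization_instance")
  expect_length(edge_bipartization(c5), 1L)

  two_tri <- structure(list(n = 6L, names = paste0("v", 1:6),
                            edges = data.frame(u = c(1L, 2L, 1L, 4L, 5L, 4L),
                                               v = c(2L, 3L, 3L, 5L, 6L, 6L),
                                               tag = "graph", orig = 1:6)),
                       class = "bipartization_instance")
  expect_length(edge_bipartization(two_tri), 2L)

  k4 <- structure(list(n = 4L, names = paste0("v", 1:4),
                       edges = data.frame(u = c(1L, 1L, 1L, 2L, 2L, 3L),
                                          v = c(2L, 3L, 4L, 3L, 4L, 4L),
                                          tag = "graph", orig = 1:6)),
                  class = "bipartization_instance")
  expect_equal(length(edge_bipartization(k4)),
               bipartization_bruteforce(k4)$size)

  for (s in 1:120) {
    inst <- rand_multigraph_inst(7000 + s)
    C <- edge_bipartization(inst)
    expect_equal(length(C), bipartization_bruteforce(inst)$size)
    sides <- two_coloring_from_removal(inst, C)
    keep <- setdiff(seq_len(nrow(inst$edges)), C)
    expect_true(all(sides[inst$edges$u[keep]] != sides[inst$edges$v[keep]]))
  }
})

test_that("the recovered two-colouring isolates exactly the removed edges", {
  tri <- structure(list(n = 3L, names = c("a", "b", "c"),
                        edges = data.frame(u = c(1L, 2L, 1L), v = c(2L, 3L, 3L),
                                           tag = "graph", orig = 1:3)),
                   class = "bipartization_instance")
  C <- edge_bipartization(tri)
  expect_length(C, 1L)
  sides <- two_coloring_from_removal(tri, C)
  expect_equal(sides[[tri$edges$u[C]]], sides[[tri$edges$v[C]]])
  expect_error(two_coloring_from_removal(tri, integer(0)), "bipartize")
})
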