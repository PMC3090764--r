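sg <- function(colors, edges) {
  signed_graph(data.frame(name = paste0("v", seq_along(colors)),
                          color = colors),
               edges)
}

test_that("forced-conflict No-instance check respects the budget boundary", {
  g <- sg(c("red", "green"),
          data.frame(u = 1L, v = 2L, sign = 1L))
  expect_true(check_no_instance(g, 0))    # one forced event > 0
  expect_false(check_no_instance(g, 1))
  g2 <- sg(c("green", "green"),
           data.frame(u = 1L, v = 2L, sign = -1L))
  expect_false(check_no_instance(g2, 1))  # exactly 1 <= k
  g3 <- sg(c("grey", "grey"),
           data.frame(u = 1L, v = 2L, sign = -1L))
  expect_false(check_no_instance(g3, 0))  # no resolved conflicts at all
})

test_that("majority and budget rules force grey colours", {
  # degree 3, two positive edges to greens: green forced (2 > 3/2)
  g <- sg(c("grey", "green", "green", "grey"),
          data.frame(u = c(1L, 1L, 1L), v = c(2L, 3L, 4L),
                     sign = c(1L, 1L, 1L)))
  f <- forced_label_rules(g)
  expect_equal(f[["v1"]], "green")
  # one resolved neighbour out of degree 4: nothing forced
  g2 <- sg(c("grey", "green", "grey", "grey", "grey"),
           data.frame(u = c(1L, 1L, 1L, 1L), v = c(2L, 3L, 4L, 5L),
                      sign = 1L))
  expect_length(forced_label_rules(g2), 0)
  # a single positive edge to a green neighbour already forces green by
  # majority (1 > 1/2); the budget argument at k = 0 agrees
  g3 <- sg(c("grey", "green"),
           data.frame(u = 1L, v = 2L, sign = 1L))
  expect_equal(forced_label_rules(g3)[["v1"]], "green")
  expect_equal(forced_label_rules(g3, k = 0)[["v1"]], "green")
  # budget-only forcing: balanced resolved neighbourhood (no majority),
  # but one colour is unaffordable at k = 0
  g4 <- sg(c("grey", "green", "red", "grey", "grey"),
           data.frame(u = c(1L, 1L, 1L, 1L), v = c(2L, 3L, 4L, 5L),
                      sign = c(1L, -1L, 1L, 1L)))
  expect_length(forced_label_rules(g4), 0)
  expect_equal(forced_label_rules(g4, k = 1)[["v1"]], "green")
})

test_that("individual reduction rules fire as their proofs dictate", {
  # isolated grey vertex: deleted, budget unchanged
  r <- reduce_to_fixpoint(sg("grey", data.frame(u = integer(0),
                                                v = integer(0),
                                                sign = integer(0))), 3)
  expect_equal(nrow(r$graph$vertices), 0L)
  expect_equal(r$k, 3)

  # degree-2 grey between opposite resolved vertices via positive edges:
  # deleted at cost 1
  r2 <- reduce_to_fixpoint(sg(c("grey", "red", "green"),
                              data.frame(u = c(1L, 1L), v = c(2L, 3L),
                                         sign = c(1L, 1L))), 5)
  expect_equal(r2$spent, 1L)
  expect_equal(nrow(r2$graph$vertices), 0L)

  # degree-2 grey between two greys via negative edges: replaced by a
  # positive edge, budget unchanged
  g <- sg(c("grey", "grey", "grey", "grey", "grey", "grey"),
          data.frame(u = c(1L, 1L, 2L, 2L, 3L, 3L),
                     v = c(2L, 3L, 4L, 5L, 4L, 6L),
                     sign = c(-1L, -1L, 1L, 1L, 1L, 1L)))
  # v1 has degree 2 (neg to v2, neg to v3); after its removal a positive
  # edge joins v2 and v3 and the whole balanced graph collapses freely
  r3 <- reduce_to_fixpoint(g, 4)
  expect_equal(r3$spent, 0L)
  expect_equal(nrow(r3$graph$vertices), 0L)

  # resolved-resolved edge cleanups keep exact budget accounting
  g4 <- sg(c("red", "red", "green"),
           data.frame(u = c(1L, 1L, 2L), v = c(2L, 3L, 3L),
                      sign = c(-1L, 1L, -1L)))
  r4 <- reduce_to_fixpoint(g4, 10)
  # frustrated: neg red-red (1) + pos red-green (1); neg red-green is free
  expect_equal(r4$spent, 2L)
  expect_equal(nrow(r4$graph$edges), 0L)
})

test_that("reduction preserves the decision answer and the optimum", {
  for (s in 1:120) {
    g <- rand_signed_graph(1000 + s)
    bf <- line_index_bruteforce(g)$value
    r <- reduce_to_fixpoint(g)
    expect_false(r$no_instance)
    expect_equal(r$spent + line_index_bruteforce(r$graph)$value, bf)
    for (k in c(0L, 2L, 4L)) {
      rd <- reduce_to_fixpoint(g, k)
      ans <- if (rd$no_instance) FALSE else
        line_index_bruteforce(rd$graph)$value <= rd$k
      expect_equal(ans, bf <= k)
    }
  }
})

test_that("no grey vertex of degree below three survives reduction", {
  for (s in 1:150) {
    g <- rand_signed_graph(2000 + s)
    r <- reduce_to_fixpoint(g)
    dg <- r$graph
    if (!nrow(dg$vertices)) next
    deg <- tabulate(c(dg$edges$u, dg$edges$v), nrow(dg$vertices))
    expect_true(all(deg[dg$vertices$color == "grey"] >= 3))
  }
})

test_that("trace replay recolours every original vertex optimally", {
  for (s in 1:120) {
    g <- rand_signed_graph(3000 + s)
    bf <- line_index_bruteforce(g)
    r <- reduce_to_fixpoint(g)
    sol_cols <- line_index_bruteforce(r$graph)$colors
    full <- replay_trace(r$trace, sol_cols)
    expect_setequal(names(full), g$vertices$name)
    expect_equal(line_index_of_labeling(g, full)$value, bf$value)
  }
})

test_that("a budget overrun is detected as a No-instance", {
  g <- sg(c("red", "green", "red", "green"),
          data.frame(u = c(1L, 3L), v = c(2L, 4L), sign = c(1L, 1L)))
  r <- reduce_to_fixpoint(g, 1)
  expect_true(r$no_instance)
})
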