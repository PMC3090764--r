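test_that("member labels follow the genotype classes", {
  expect_equal(label_member(0L, 0L), "green")
  expect_equal(label_member(1L, 1L), "green")
  expect_equal(label_member(1L, 0L), "red")
  expect_equal(label_member(0L, 1L), "red")
  expect_equal(label_member(2L, 2L), "grey")
  expect_equal(label_member(0L, 2L), "unlabeled")
  expect_equal(label_member(2L, 1L), "unlabeled")
  expect_equal(label_member(c(0L, 2L), c(0L, 2L)), c("green", "grey"))
})

test_that("positive and negative edges are inserted per trio structure", {
  # both parents labeled, child unlabeled -> one negative edge between them
  ped <- ped_of(mem("u", 0, 1), mem("v", 2, 2, sex = "2"),
                mem("c", 0, 2, father = "u", mother = "v"))
  g <- build_graph(ped)
  expect_setequal(g$vertices$name, c("u", "v"))
  expect_equal(nrow(g$edges), 1L)
  expect_equal(g$edges$sign, -1L)
  expect_equal(g$edges$prov_child, "c")

  # labeled parent and labeled child -> positive edge
  ped2 <- ped_of(mem("u", 0, 1), mem("w", 1, 2, sex = "2"),
                 mem("c", 2, 2, father = "u", mother = "w"))
  g2 <- build_graph(ped2)
  expect_setequal(g2$vertices$name, c("u", "c"))
  expect_equal(g2$edges$sign, 1L)
  # ... and the doubly-homozygous red parent forces the grey child red
  expect_equal(g2$vertices$color[g2$vertices$name == "c"], "red")

  # vertex count never exceeds the member count
  for (s in 1:20) {
    sim <- rand_small_ped(300 + s)
    g <- build_graph(sim$pedigree)
    expect_lte(nrow(g$vertices), nrow(sim$pedigree$members))
  }
})

test_that("propagation forces only from genotype-resolved parents", {
  # green doubly-homozygous parent, grey child: forced green
  g <- signed_graph(
    data.frame(name = c("u", "v"), color = c("green", "grey"),
               origin = c("green", "grey")),
    data.frame(u = 1L, v = 2L, sign = 1L, etype = "parent_child",
               prov_parent = "u", prov_child = "v"))
  expect_equal(propagate_resolved(g)$vertices$color, c("green", "green"))

  # grey parent with a resolved child: the constraint stays soft
  g2 <- signed_graph(
    data.frame(name = c("p", "c"), color = c("grey", "green"),
               origin = c("grey", "green")),
    data.frame(u = 1L, v = 2L, sign = 1L, etype = "parent_child",
               prov_parent = "p", prov_child = "c"))
  expect_equal(propagate_resolved(g2)$vertices$color, c("grey", "green"))

  # a propagated grey is not itself a forcing source: its children stay
  # free, which is what keeps the graph optimum equal to the MRHC optimum
  ped <- ped_of(
    mem("u", 0, 1), mem("s1", 1, 2, sex = "2"),
    mem("c", 2, 2, father = "u", mother = "s1"),
    mem("s2", 2, 0, sex = "2"),
    mem("d", 2, 2, father = "c", mother = "s2"),
    mem("s3", 2, 1, sex = "2"),
    mem("e1", 1, 1, father = "d", mother = "s3"),
    mem("e2", 1, 1, father = "d", mother = "s3"),
    mem("e3", 1, 1, father = "d", mother = "s3"))
  g3 <- build_graph(ped)
  cols <- stats::setNames(g3$vertices$color, g3$vertices$name)
  expect_equal(unname(cols["c"]), "red")   # forced by u
  expect_equal(unname(cols["d"]), "grey")  # not forced through c
  expect_equal(mrhc_bruteforce(ped),
               line_index_bruteforce(g3)$value)
})

test_that("frustration counts positive-across and negative-within edges", {
  g <- signed_graph(
    data.frame(name = c("a", "b", "c"), color = c("red", "green", "green")),
    data.frame(u = c(1L, 2L, 1L), v = c(2L, 3L, 3L),
               sign = c(1L, -1L, -1L)))
  li <- line_index_of_labeling(g, c(a = "red", b = "green", c = "green"))
  # pos red-green: 1; neg green-green: 1; neg red-green: 0
  expect_equal(li$value, 2L)
  expect_setequal(li$frustrated, c(1L, 2L))
  expect_equal(naive_frustration(g, c("red", "green", "green")), 2L)
})

test_that("graph construction is deterministic and idempotent", {
  sim <- rand_small_ped(77)
  g1 <- build_graph(sim$pedigree)
  g2 <- build_graph(sim$pedigree)
  expect_identical(g1, g2)
  expect_identical(propagate_resolved(g1)$vertices, g1$vertices)
})

test_that("graphml export writes well-formed XML with attributes", {
  sim <- rand_small_ped(5)
  g <- build_graph(sim$pedigree)
  path <- withr::local_tempfile(fileext = ".graphml")
  write_graphml(g, path)
  doc <- xml2::read_xml(path)
  ns <- xml2::xml_ns(doc)
  expect_equal(length(xml2::xml_find_all(doc, ".//d1:node", ns)),
               nrow(g$vertices))
  expect_equal(length(xml2::xml_find_all(doc, ".//d1:edge", ns)),
               nrow(g$edges))
})
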