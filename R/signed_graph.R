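#' Construct a signed (multi)graph
#'
#' Vertices carry a colour in `{"red", "green", "grey"}`; edges carry a sign
#' (+1 "should agree once resolved", -1 "should differ") and optional
#' provenance linking them back to the pedigree (positive edges to a
#' parent-child pair, negative edges to the trio whose unlabeled child they
#' replace). Parallel edges are allowed; self-loops are not.
#'
#' @param vertices data.frame with at least `name` and `color`; optional
#'   `origin` (the colour assigned from the genotype alone, before any
#'   propagation — only vertices with origin red/green, i.e.
#'   doubly-homozygous members, force their children's colours) and
#'   `source` (member id or synthetic tag).
#' @param edges data.frame with `u`, `v` (integer vertex indices), `sign`
#'   (+1/-1); optional `etype`, `prov_parent`, `prov_child`.
#' @return object of class `signed_graph`.
#' @export
signed_graph <- function(vertices = data.frame(name = character(0),
                                               color = character(0)),
                         edges = data.frame(u = integer(0), v = integer(0),
                                            sign = integer(0))) {
  vertices <- as.data.frame(vertices, stringsAsFactors = FALSE)
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (!"origin" %in% names(vertices)) vertices$origin <- vertices$color
  if (!"source" %in% names(vertices)) vertices$source <- vertices$name
  if (!"etype" %in% names(edges)) edges$etype <- rep("generic", nrow(edges))
  if (!"prov_parent" %in% names(edges)) edges$prov_parent <- rep(NA_character_, nrow(edges))
  if (!"prov_child" %in% names(edges)) edges$prov_child <- rep(NA_character_, nrow(edges))
  stopifnot(all(vertices$color %in% c("red", "green", "grey")))
  if (anyDuplicated(vertices$name)) stop("duplicate vertex names")
  if (nrow(edges)) {
    edges$u <- as.integer(edges$u)
    edges$v <- as.integer(edges$v)
    edges$sign <- as.integer(edges$sign)
    stopifnot(all(edges$sign %in% c(-1L, 1L)),
              all(edges$u >= 1L), all(edges$v >= 1L),
              all(edges$u <= nrow(vertices)), all(edges$v <= nrow(vertices)))
    if (any(edges$u == edges$v)) stop("self-loops are not allowed")
  }
  structure(list(vertices = vertices, edges = edges), class = "signed_graph")
}

#' @export
print.signed_graph <- function(x, ...) {
  cat(sprintf("<signed_graph> %d vertices (%d red, %d green, %d grey), %d edges (%d pos, %d neg)\n",
              nrow(x$vertices),
              sum(x$vertices$color == "red"),
              sum(x$vertices$color == "green"),
              sum(x$vertices$color == "grey"),
              nrow(x$edges),
              sum(x$edges$sign == 1L), sum(x$edges$sign == -1L)))
  invisible(x)
}

n_vertices <- function(g) nrow(g$vertices)
n_edges <- function(g) nrow(g$edges)

vertex_index <- function(g, names) {
  match(names, g$vertices$name)
}

#' Export a signed graph to GraphML
#'
#' Writes vertex colours and edge signs/provenance as GraphML attributes so
#' the pedigree graph can be inspected in standard graph tools. Parallel
#' edges are preserved.
#'
#' @param g a [signed_graph()].
#' @param path output path.
#' @export
write_graphml <- function(g, path) {
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<graphml xmlns="http://graphml.graphdrawing.org/xmlns">',
    '  <key id="color" for="node" attr.name="color" attr.type="string"/>',
    '  <key id="sign" for="edge" attr.name="sign" attr.type="int"/>',
    '  <key id="etype" for="edge" attr.name="etype" attr.type="string"/>',
    '  <key id="prov" for="edge" attr.name="provenance" attr.type="string"/>',
    '  <graph edgedefault="undirected">'), con)
  for (i in seq_len(nrow(g$vertices))) {
    writeLines(sprintf('    <node id="%s"><data key="color">%s</data></node>',
                       esc(g$vertices$name[i]), g$vertices$color[i]), con)
  }
  if (nrow(g$edges)) {
    for (i in seq_len(nrow(g$edges))) {
      prov <- paste(stats::na.omit(c(g$edges$prov_parent[i],
                                     g$edges$prov_child[i])), collapse = "->")
      writeLines(sprintf(
        '    <edge source="%s" target="%s"><data key="sign">%d</data><data key="etype">%s</data><data key="prov">%s</data></edge>',
        esc(g$vertices$name[g$edges$u[i]]),
        esc(g$vertices$name[g$edges$v[i]]),
        g$edges$sign[i], g$edges$etype[i], esc(prov)), con)
    }
  }
  writeLines(c('  </graph>', '</graphml>'), con)
  invisible(path)
}
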