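# Transformation of the (reduced) signed graph into Bipartization by Edge
# Removal, and the iterative-compression solver. Unsigned multigraphs are
# kept as plain integer edge lists; all indices are edge row numbers so
# solutions map back through every layer (guards, subdivision vertices,
# supernode merges) to original signed edges.

#' Replace every positive edge by two consecutive negative edges
#'
#' Each positive edge (u, v) becomes negative edges (u, y) and (y, v)
#' through a fresh grey subdivision vertex y adjacent only to u and v. The
#' line index is preserved: when u and v sit on the same side y goes
#' opposite to both (no new frustration), and when they differ y can join
#' either side at the cost the positive edge already paid.
#'
#' @param g a [signed_graph()].
#' @return an all-negative [signed_graph()]; column `orig` of its edges
#'   maps every edge back to the row of the input edge it came from.
#' @export
to_all_negative <- function(g) {
  e <- g$edges
  pos <- which(e$sign == 1L)
  v <- g$vertices
  if (!length(pos)) {
    g$edges$orig <- seq_len(nrow(e))
    return(g)
  }
  nv <- nrow(v)
  ys <- data.frame(name = sprintf(".y%d", seq_along(pos)),
                   color = "grey", origin = "grey",
                   source = sprintf("subdiv:%d", pos),
                   stringsAsFactors = FALSE)
  yid <- nv + seq_along(pos)
  keep <- e[e$sign == -1L, , drop = FALSE]
  keep$orig <- which(e$sign == -1L)
  sub1 <- data.frame(u = e$u[pos], v = yid, sign = -1L, etype = "subdivision",
                     prov_parent = e$prov_parent[pos],
                     prov_child = e$prov_child[pos], orig = pos,
                     stringsAsFactors = FALSE)
  sub2 <- sub1
  sub2$u <- yid
  sub2$v <- e$v[pos]
  out <- signed_graph(rbind(v, ys), rbind(keep, sub1, sub2))
  out
}

#' Merge resolved vertices into two supernodes and add guard edges
#'
#' All red vertices collapse into one supernode and all green vertices into
#' another (parallel edges are kept); both supernodes are relabelled grey
#' so the bipartization solver sees an uncoloured graph, and `k + 1`
#' parallel negative guard edges pin them to opposite sides: any solution
#' within budget `k` cannot afford to frustrate all guards. When one colour
#' class is empty the guards are omitted. With `k = Inf` (pure
#' optimization) `|E| + 1` guards are used, since any optimum is at most
#' `|E|`.
#'
#' Negative edges joining two same-coloured resolved vertices would become
#' self-loops; they are always frustrated, so they are dropped and counted
#' in `extra_cost` (zero whenever the graph was reduced first).
#'
#' @param g an all-negative [signed_graph()].
#' @param k recombination budget (may be `Inf`).
#' @return list with `graph` (the guarded [signed_graph()]), `map` (named:
#'   input vertex name -> output vertex name), `guard_count`, `extra_cost`.
#' @export
merge_and_guard <- function(g, k = Inf) {
  if (any(g$edges$sign == 1L)) stop("merge_and_guard expects an all-negative graph")
  v <- g$vertices
  reds <- which(v$color == "red")
  greens <- which(v$color == "green")
  greys <- which(v$color == "grey")
  new_names <- character(0)
  map_to <- integer(nrow(v))
  if (length(reds)) {
    new_names <- c(new_names, ".red")
    map_to[reds] <- length(new_names)
  }
  if (length(greens)) {
    new_names <- c(new_names, ".green")
    map_to[greens] <- length(new_names)
  }
  map_to[greys] <- length(new_names) + seq_along(greys)
  new_names <- c(new_names, v$name[greys])
  e <- g$edges
  if (is.null(e$orig)) e$orig <- seq_len(nrow(e))
  eu <- map_to[e$u]
  ev <- map_to[e$v]
  loop <- eu == ev
  extra <- sum(loop)
  edges <- data.frame(u = eu[!loop], v = ev[!loop],
                      sign = rep(-1L, sum(!loop)),
                      etype = e$etype[!loop],
                      prov_parent = e$prov_parent[!loop],
                      prov_child = e$prov_child[!loop],
                      orig = e$orig[!loop], stringsAsFactors = FALSE)
  guard_count <- 0L
  if (length(reds) && length(greens)) {
    guard_count <- if (is.finite(k)) as.integer(k) + 1L else nrow(e) + 1L
    guards <- data.frame(u = map_to[reds[1]], v = map_to[greens[1]],
                         sign = -1L, etype = "guard",
                         prov_parent = NA_character_,
                         prov_child = NA_character_, orig = NA_integer_,
                         stringsAsFactors = FALSE)
    edges <- rbind(edges, guards[rep(1L, guard_count), , drop = FALSE])
  }
  vertices <- data.frame(name = new_names, color = "grey", origin = "grey",
                         source = new_names, stringsAsFactors = FALSE)
  out <- signed_graph(vertices, edges)
  list(graph = out,
       map = stats::setNames(new_names[map_to], v$name),
       guard_count = guard_count, extra_cost = extra)
}

#' Reinterpret an all-negative signed graph as a bipartization instance
#'
#' Multiplying every weight by -1 turns the all-negative graph into a plain
#' unsigned multigraph in which a two-colouring's frustrated edges are
#' exactly the monochromatic ones, so the minimum number of edge deletions
#' that make the graph bipartite equals the line index of the input.
#'
#' @param g an all-negative [signed_graph()].
#' @return object of class `bipartization_instance`: list with `n`, `names`
#'   and `edges` (data.frame `u`, `v`, `tag`, `orig`).
#' @export
negate_weights <- function(g) {
  if (any(g$edges$sign == 1L)) stop("negate_weights expects an all-negative graph")
  e <- g$edges
  if (is.null(e$orig)) e$orig <- seq_len(nrow(e))
  structure(list(n = nrow(g$vertices), names = g$vertices$name,
                 edges = data.frame(u = e$u, v = e$v, tag = e$etype,
                                    orig = e$orig, stringsAsFactors = FALSE)),
            class = "bipartization_instance")
}

# Proper 2-colouring (1/2) of the graph spanned by the given edges, NULL if
# an odd cycle exists. Isolated vertices get side 1.
bipartite_sides <- function(n, eu, ev) {
  adj <- rep(list(integer(0)), n)
  m <- length(eu)
  if (m) {
    sp <- split(rep(seq_len(m), 2L), c(eu, ev))
    adj[as.integer(names(sp))] <- sp
  }
  side <- integer(n)
  for (s in seq_len(n)) {
    if (side[s] != 0L) next
    side[s] <- 1L
    queue <- s
    qi <- 1L
    while (qi <= length(queue)) {
      x <- queue[qi]
      qi <- qi + 1L
      for (e in adj[[x]]) {
        y <- if (eu[e] == x) ev[e] else eu[e]
        if (side[y] == 0L) {
          side[y] <- 3L - side[x]
          queue[length(queue) + 1L] <- y
        } else if (side[y] == side[x]) {
          return(NULL)
        }
      }
    }
  }
  side
}

#' Minimum edge cut between two vertex sets (unit capacities)
#'
#' BFS augmenting-path max-flow on an undirected unit-capacity multigraph
#' through a super-source/super-sink, aborting as soon as the flow exceeds
#' `limit`.
#'
#' @param edges two-column matrix/data.frame of vertex indices (one row per
#'   parallel edge).
#' @param n number of vertices.
#' @param sources,sinks disjoint vertex index sets.
#' @param limit abort threshold; `NULL` is returned (an OVERFLOW marker)
#'   when the minimum cut exceeds it.
#' @return integer vector of cut edge row indices, or `NULL` on overflow.
#' @export
min_edge_cut <- function(edges, n, sources, sinks, limit = Inf) {
  if (length(intersect(sources, sinks))) stop("sources and sinks must be disjoint")
  edges <- as.matrix(edges)[, 1:2, drop = FALSE]
  eu <- as.integer(edges[, 1])
  ev <- as.integer(edges[, 2])
  m <- length(eu)
  adj <- rep(list(integer(0)), n)
  if (m) {
    sp <- split(rep(seq_len(m), 2L), c(eu, ev))
    adj[as.integer(names(sp))] <- sp
  }
  is_sink <- rep(FALSE, n)
  is_sink[sinks] <- TRUE
  flow <- integer(m)
  flowval <- 0L
  repeat {
    visited <- rep(FALSE, n)
    par_edge <- integer(n)
    par_from <- integer(n)
    queue <- sources
    visited[sources] <- TRUE
    qi <- 1L
    found <- 0L
    while (qi <= length(queue) && found == 0L) {
      x <- queue[qi]
      qi <- qi + 1L
      for (e in adj[[x]]) {
        y <- if (eu[e] == x) ev[e] else eu[e]
        if (visited[y]) next
        fxy <- if (eu[e] == x) flow[e] else -flow[e]
        if (fxy > 0L) next          # saturated in this direction
        visited[y] <- TRUE
        par_edge[y] <- e
        par_from[y] <- x
        if (is_sink[y]) {
          found <- y
          break
        }
        queue[length(queue) + 1L] <- y
      }
    }
    if (found == 0L) break
    flowval <- flowval + 1L
    if (flowval > limit) return(NULL)
    x <- found
    while (par_edge[x] != 0L) {
      e <- par_edge[x]
      prev <- par_from[x]
      flow[e] <- flow[e] + (if (eu[e] == prev) 1L else -1L)
      x <- prev
    }
  }
  # `visited` from the last (failed) search marks the source side
  which(xor(visited[eu], visited[ev]))
}

#' Compression step: shrink a bipartization set by one
#'
#' Given a minimal edge-bipartization set `X'` of size `k' + 1`, each `X'`
#' edge is replaced by three consecutive edges (preserving all cycle
#' parities) with the middle edge taking its place in `X'`, which makes any
#' smaller solution disjoint from `X'`. All `2^{k'}` valid side assignments
#' of the subdivision endpoints are enumerated (the first edge's
#' orientation is fixed by colour symmetry); for each, a minimum edge cut
#' between the two sides in `G \ X'` is computed, and the best cut of size
#' at most `k'` is returned.
#'
#' @param edges two-column matrix of the graph's edges.
#' @param n number of vertices.
#' @param xprime indices (rows of `edges`) of the current bipartization set.
#' @return integer vector of edge rows forming a bipartization set of size
#'   `<= length(xprime) - 1`, or `NULL` if none exists.
#' @export
compress_bipartization <- function(edges, n, xprime) {
  edges <- as.matrix(edges)[, 1:2, drop = FALSE]
  kp <- length(xprime) - 1L
  t <- length(xprime)
  rest <- setdiff(seq_len(nrow(edges)), xprime)
  # subdivision endpoints: edge j in X' gets a_j = n + 2j - 1, b_j = n + 2j
  a <- n + 2L * seq_len(t) - 1L
  b <- n + 2L * seq_len(t)
  nv <- n + 2L * t
  hu <- c(edges[rest, 1], edges[xprime, 1], b)
  hv <- c(edges[rest, 2], a, edges[xprime, 2])
  hmap <- c(rest, xprime, xprime)  # cut edge -> original edge row
  best <- NULL
  for (code in 0:(2^max(0L, t - 1L) - 1L)) {
    bits <- c(0L, as.integer(intToBits(code))[seq_len(t - 1L)])
    srcs <- ifelse(bits == 0L, a, b)
    snks <- ifelse(bits == 0L, b, a)
    lim <- if (is.null(best)) kp else length(best) - 1L
    if (lim < 0L) break
    cut <- min_edge_cut(cbind(hu, hv), nv, srcs, snks, limit = lim)
    if (is.null(cut)) next
    y <- sort(unique(hmap[cut]))
    keep <- setdiff(seq_len(nrow(edges)), y)
    if (is.null(bipartite_sides(n, edges[keep, 1], edges[keep, 2]))) next
    if (is.null(best) || length(y) < length(best)) best <- y
  }
  best
}

#' Minimum edge bipartization by iterative compression
#'
#' Processes the edges one at a time in a deterministic order, maintaining
#' an optimal bipartization set `X` for the prefix graph: when the next
#' edge breaks bipartiteness of the prefix minus `X`, the set `X ∪ {e}` is
#' compressed with [compress_bipartization()]. Runs to the true optimum.
#'
#' @param inst a `bipartization_instance` (or a plain list with `n` and
#'   `edges` having columns `u`, `v`).
#' @return integer vector of edge row indices (into `inst$edges`) whose
#'   removal makes the graph bipartite, of minimum cardinality.
#' @export
edge_bipartization <- function(inst) {
  e <- inst$edges
  m <- nrow(e)
  if (!m) return(integer(0))
  lo <- pmin(e$u, e$v)
  hi <- pmax(e$u, e$v)
  ord <- order(lo, hi, seq_len(m))
  eu <- e$u[ord]
  ev <- e$v[ord]
  X <- integer(0)  # indices into the ordered prefix
  for (i in seq_len(m)) {
    act <- setdiff(seq_len(i), X)
    if (!is.null(bipartite_sides(inst$n, eu[act], ev[act]))) next
    xp <- c(X, i)
    y <- compress_bipartization(cbind(eu[seq_len(i)], ev[seq_len(i)]),
                                inst$n, xp)
    X <- if (is.null(y)) xp else y
  }
  sort(ord[X])
}

#' Two-colouring of a graph after removing a bipartization set
#'
#' BFS 2-colouring per connected component of the graph minus `C`; the
#' smallest-index vertex of each component takes side `"V1"`. Errors if an
#' odd cycle survives (i.e. `C` was not a bipartization set).
#'
#' @param inst a `bipartization_instance`.
#' @param C integer vector of removed edge rows.
#' @return character vector of `"V1"`/`"V2"` named by vertex name.
#' @export
two_coloring_from_removal <- function(inst, C) {
  keep <- setdiff(seq_len(nrow(inst$edges)), C)
  side <- bipartite_sides(inst$n, inst$edges$u[keep], inst$edges$v[keep])
  if (is.null(side)) stop("removal set does not bipartize the graph")
  stats::setNames(ifelse(side == 1L, "V1", "V2"), inst$names)
}
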