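# Kernelizing data-reduction rules for the signed pedigree graph.
#
# The working graph is held in an environment (vectors + incidence lists)
# so rule applications are O(degree). Every destructive step appends a
# trace record; replaying the trace in reverse recovers a colour for every
# deleted or merged vertex, which lets the solver count and localize the
# recombination events on the ORIGINAL graph.

flip_color <- function(col) ifelse(col == "red", "green", "red")

wg_new <- function(g, k, mode) {
  w <- new.env(parent = emptyenv())
  nv <- nrow(g$vertices)
  ne <- nrow(g$edges)
  w$name <- g$vertices$name
  w$color <- g$vertices$color
  w$active <- rep(TRUE, nv)
  w$eu <- g$edges$u
  w$ev <- g$edges$v
  w$esign <- g$edges$sign
  w$etype <- g$edges$etype
  w$eparent <- g$edges$prov_parent
  w$echild <- g$edges$prov_child
  w$ealive <- rep(TRUE, ne)
  inc <- rep(list(integer(0)), nv)
  if (ne) {
    sp <- split(rep(seq_len(ne), 2L), c(w$eu, w$ev))
    inc[as.integer(names(sp))] <- sp
  }
  w$inc <- inc
  w$deg <- tabulate(c(w$eu, w$ev), nv)
  w$k <- k
  w$spent <- 0L
  w$mode <- mode
  w$no_instance <- FALSE
  w$trace <- vector("list", 2L * nv + ne + 8L)
  w$tn <- 0L
  w$queue <- seq_len(nv)
  w$qhead <- 1L
  w$inq <- rep(TRUE, nv)
  w
}

wg_push <- function(w, x) {
  for (xi in x) {
    if (w$active[xi] && !w$inq[xi]) {
      w$queue[length(w$queue) + 1L] <- xi
      w$inq[xi] <- TRUE
    }
  }
}

wg_record <- function(w, rec) {
  w$tn <- w$tn + 1L
  if (w$tn > length(w$trace)) {
    w$trace <- c(w$trace, vector("list", length(w$trace)))
  }
  w$trace[[w$tn]] <- rec
}

wg_spend <- function(w, kd) {
  if (kd > 0L) {
    w$spent <- w$spent + kd
    if (w$mode == "decision" && w$spent > w$k) w$no_instance <- TRUE
  }
}

wg_inc_alive <- function(w, x) {
  ids <- w$inc[[x]]
  ids <- ids[w$ealive[ids]]
  w$inc[[x]] <- ids
  ids
}

wg_other <- function(w, e, x) {
  if (w$eu[e] == x) w$ev[e] else w$eu[e]
}

wg_delete_edge <- function(w, e, kd, rule) {
  if (!w$ealive[e]) return(invisible())
  w$ealive[e] <- FALSE
  w$deg[w$eu[e]] <- w$deg[w$eu[e]] - 1L
  w$deg[w$ev[e]] <- w$deg[w$ev[e]] - 1L
  wg_record(w, list(type = "edge", rule = rule,
                    u = w$name[w$eu[e]], v = w$name[w$ev[e]],
                    sign = w$esign[e], k_delta = kd))
  wg_spend(w, kd)
  invisible()
}

# Delete vertex x and any surviving incident edges; `directive` tells the
# replay how to colour x (kind "fixed" with a colour, or "same"/"opposite"
# with a reference vertex name). k_delta is the recombination cost the
# rule's proof charges for the deletion.
wg_delete_vertex <- function(w, x, rule, directive, kd = 0L) {
  for (e in wg_inc_alive(w, x)) {
    w$ealive[e] <- FALSE
    o <- wg_other(w, e, x)
    w$deg[o] <- w$deg[o] - 1L
    wg_push(w, o)
  }
  w$deg[x] <- 0L
  w$active[x] <- FALSE
  wg_record(w, list(type = "vertex", rule = rule, vertex = w$name[x],
                    directive = directive, k_delta = kd))
  wg_spend(w, kd)
  invisible()
}

# Merge grey x into `into` (x inherits into's final colour). The edge
# between them vanishes at zero cost; x's other edges are re-hung on
# `into`.
wg_merge <- function(w, x, into, rule) {
  for (e in wg_inc_alive(w, x)) {
    o <- wg_other(w, e, x)
    if (o == into) {
      w$ealive[e] <- FALSE
      w$deg[into] <- w$deg[into] - 1L
      next
    }
    if (w$eu[e] == x) w$eu[e] <- into else w$ev[e] <- into
    w$inc[[into]] <- c(w$inc[[into]], e)
    w$deg[into] <- w$deg[into] + 1L
    wg_push(w, o)
  }
  w$deg[x] <- 0L
  w$active[x] <- FALSE
  wg_record(w, list(type = "merge", rule = rule, vertex = w$name[x],
                    into = w$name[into]))
  wg_push(w, into)
  invisible()
}

wg_add_pos_edge <- function(w, u, v) {
  e <- length(w$eu) + 1L
  w$eu[e] <- u
  w$ev[e] <- v
  w$esign[e] <- 1L
  w$etype[e] <- "reduction"
  w$eparent[e] <- NA_character_
  w$echild[e] <- NA_character_
  w$ealive[e] <- TRUE
  w$inc[[u]] <- c(w$inc[[u]], e)
  w$inc[[v]] <- c(w$inc[[v]], e)
  w$deg[u] <- w$deg[u] + 1L
  w$deg[v] <- w$deg[v] + 1L
  invisible()
}

wg_set_color <- function(w, x, col) {
  w$color[x] <- col
  wg_push(w, x)
  for (e in wg_inc_alive(w, x)) wg_push(w, wg_other(w, e, x))
  invisible()
}

# Conflicts x would incur among its already-resolved neighbours if coloured
# red (positive edges to green + negative edges to red) and if coloured
# green (symmetric).
wg_conflicts <- function(w, x, ids) {
  R <- 0L
  G <- 0L
  for (e in ids) {
    o <- wg_other(w, e, x)
    oc <- w$color[o]
    if (oc == "grey") next
    pos <- w$esign[e] == 1L
    if ((pos && oc == "green") || (!pos && oc == "red")) R <- R + 1L
    else G <- G + 1L
  }
  c(R = R, G = G)
}

wg_rule7 <- function(w, x, e1, e2) {
  u <- wg_other(w, e1, x)
  v <- wg_other(w, e2, x)
  s1 <- w$esign[e1]
  s2 <- w$esign[e2]
  # normalize mixed case: positive edge first
  if (s1 == -1L && s2 == 1L) {
    tmp <- u; u <- v; v <- tmp
    tmp <- e1; e1 <- e2; e2 <- tmp
    s1 <- 1L; s2 <- -1L
  }
  ru <- w$color[u] != "grey"
  rv <- w$color[v] != "grey"
  nm <- function(i) w$name[i]
  if (s1 == 1L && s2 == 1L) {                       # case 1: pos + pos
    if (ru && rv) {
      kd <- if (w$color[u] == w$color[v]) 0L else 1L
      wg_delete_vertex(w, x, "7.1ab",
                       list(kind = "same", ref = nm(u)), kd)
    } else if (ru) {
      wg_merge(w, x, u, "7.1c")
    } else if (rv) {
      wg_merge(w, x, v, "7.1c")
    } else {
      wg_merge(w, x, min(u, v), "7.1d")
    }
  } else if (s1 == -1L && s2 == -1L) {              # case 2: neg + neg
    if (ru && rv) {
      kd <- if (w$color[u] == w$color[v]) 0L else 1L
      wg_delete_vertex(w, x, "7.2ab",
                       list(kind = "opposite", ref = nm(u)), kd)
    } else if (ru) {
      wg_set_color(w, x, flip_color(w$color[u]))
      wg_delete_edge(w, e1, 0L, "7.2c")
      wg_push(w, c(u, x))
    } else if (rv) {
      wg_set_color(w, x, flip_color(w$color[v]))
      wg_delete_edge(w, e2, 0L, "7.2c")
      wg_push(w, c(v, x))
    } else {
      a <- min(u, v)
      b <- max(u, v)
      wg_delete_vertex(w, x, "7.2d",
                       list(kind = "opposite", ref = nm(a)), 0L)
      wg_add_pos_edge(w, a, b)
      wg_push(w, c(a, b))
    }
  } else {                                          # case 3: pos(u) + neg(v)
    if (ru && rv) {
      kd <- if (w$color[u] == w$color[v]) 1L else 0L
      wg_delete_vertex(w, x, "7.3ab",
                       list(kind = "same", ref = nm(u)), kd)
    } else if (ru) {
      wg_merge(w, x, u, "7.3ci")
    } else if (rv) {
      wg_set_color(w, x, flip_color(w$color[v]))
      wg_delete_edge(w, e2, 0L, "7.3cii")
      wg_push(w, c(v, x))
    } else {
      wg_merge(w, x, u, "7.3d")
    }
  }
}

wg_process <- function(w, x) {
  if (!w$active[x]) return(invisible())
  ids <- wg_inc_alive(w, x)
  col <- w$color[x]
  if (col != "grey") {
    # Rules 3-6: edges between two resolved vertices carry a fixed cost
    for (e in ids) {
      if (!w$ealive[e]) next
      o <- wg_other(w, e, x)
      oc <- w$color[o]
      if (oc == "grey") next
      same <- oc == col
      pos <- w$esign[e] == 1L
      kd <- if ((pos && !same) || (!pos && same)) 1L else 0L
      rule <- if (!pos && same) "3" else if (pos && same) "4" else if (pos) "5" else "6"
      wg_delete_edge(w, e, kd, rule)
      wg_push(w, o)
      if (w$no_instance) return(invisible())
    }
    ids <- wg_inc_alive(w, x)
    if (length(ids) == 0L) {
      wg_delete_vertex(w, x, "1", list(kind = "fixed", ref = col), 0L)
    }
    return(invisible())
  }
  deg <- length(ids)
  if (deg == 0L) {
    # Rule 1: arbitrary colour, green by convention
    wg_delete_vertex(w, x, "1", list(kind = "fixed", ref = "green"), 0L)
    return(invisible())
  }
  if (deg == 1L) {
    e <- ids[1]
    o <- wg_other(w, e, x)
    kind <- if (w$esign[e] == 1L) "same" else "opposite"
    wg_delete_vertex(w, x, "2", list(kind = kind, ref = w$name[o]), 0L)
    return(invisible())
  }
  if (deg == 2L) {
    u <- wg_other(w, ids[1], x)
    v <- wg_other(w, ids[2], x)
    if (u != v) {
      wg_rule7(w, x, ids[1], ids[2])
      return(invisible())
    }
    # both edges parallel to the same neighbour u: the degree-2 logic
    # specializes — equal signs are both satisfiable by choosing x's label
    # relative to u's future label (no cost); mixed signs frustrate exactly
    # one edge whatever x is
    s1 <- w$esign[ids[1]]
    s2 <- w$esign[ids[2]]
    if (s1 == s2) {
      kind <- if (s1 == 1L) "same" else "opposite"
      wg_delete_vertex(w, x, "7.par", list(kind = kind, ref = w$name[u]), 0L)
    } else {
      wg_delete_vertex(w, x, "7.par", list(kind = "same", ref = w$name[u]), 1L)
    }
    return(invisible())
  }
  cf <- wg_conflicts(w, x, ids)
  if (cf["R"] > deg / 2) {
    wg_set_color(w, x, "green")
    return(invisible())
  }
  if (cf["G"] > deg / 2) {
    wg_set_color(w, x, "red")
    return(invisible())
  }
  if (w$mode == "decision") {
    krem <- w$k - w$spent
    red_ok <- cf["R"] <= krem
    green_ok <- cf["G"] <= krem
    if (!red_ok && !green_ok) {
      w$no_instance <- TRUE
    } else if (!red_ok) {
      wg_set_color(w, x, "green")
    } else if (!green_ok) {
      wg_set_color(w, x, "red")
    }
  }
  invisible()
}

#' Quick No-instance check from forced conflicts
#'
#' Counts the recombination events already forced by resolved vertices
#' alone: positive edges between a red and a green vertex, plus negative
#' edges between two same-coloured resolved vertices. If the total exceeds
#' the budget `k`, no colouring of the greys can succeed.
#'
#' @param g a [signed_graph()].
#' @param k recombination budget.
#' @return `TRUE` if `(g, k)` is already a No-instance.
#' @export
check_no_instance <- function(g, k) {
  forced_conflicts(g) > k
}

forced_conflicts <- function(g) {
  e <- g$edges
  if (!nrow(e)) return(0L)
  cu <- g$vertices$color[e$u]
  cv <- g$vertices$color[e$v]
  resolved <- cu != "grey" & cv != "grey"
  sum(resolved & ((e$sign == 1L & cu != cv) | (e$sign == -1L & cu == cv)))
}

#' Forced colours for grey vertices (majority and budget arguments)
#'
#' Mode-independent rule: a grey vertex whose conflicts-if-red among
#' resolved neighbours exceed half its degree must be green (flipping it
#' red could only increase frustration), and symmetrically for red. With a
#' finite budget `k` (decision mode) a colour is also forced when the
#' already-forced conflicts plus the conflicts that colour would incur
#' exceed `k`; if both colours are excluded the instance is a No-instance.
#'
#' @param g a [signed_graph()].
#' @param k optional recombination budget (decision mode).
#' @return named character vector of newly forced colours (possibly
#'   empty); attribute `no_instance` is `TRUE` when both colours of some
#'   grey are excluded.
#' @export
forced_label_rules <- function(g, k = NULL) {
  out <- character(0)
  no <- FALSE
  base <- forced_conflicts(g)
  e <- g$edges
  for (x in which(g$vertices$color == "grey")) {
    ids <- which(e$u == x | e$v == x)
    deg <- length(ids)
    if (!deg) next
    o <- ifelse(e$u[ids] == x, e$v[ids], e$u[ids])
    oc <- g$vertices$color[o]
    pos <- e$sign[ids] == 1L
    R <- sum((pos & oc == "green") | (!pos & oc == "red"))
    G <- sum((pos & oc == "red") | (!pos & oc == "green"))
    col <- NA_character_
    if (R > deg / 2) col <- "green"
    else if (G > deg / 2) col <- "red"
    else if (!is.null(k)) {
      red_ok <- base + R <= k
      green_ok <- base + G <= k
      if (!red_ok && !green_ok) no <- TRUE
      else if (!red_ok) col <- "green"
      else if (!green_ok) col <- "red"
    }
    if (!is.na(col)) out[g$vertices$name[x]] <- col
  }
  attr(out, "no_instance") <- no
  out
}

#' Apply the data-reduction rules to fixpoint
#'
#' Shrinks `(G, k)` to `(G', k')` preserving the decision answer (and, via
#' `spent = k - k'`, the optimum: `l(G) = spent + l(G')`). The rules:
#' degree-0 and degree-1 grey deletions; removal of edges between two
#' resolved vertices (charging 1 when the edge is frustrated); the nine
#' degree-2 grey cases (deletions, merges, and the negative-negative to
#' positive replacement); the majority rule for grey vertices; and, in
#' decision mode, budget-based forcing with early No detection. The
#' reduced graph contains no grey vertex of degree less than three.
#'
#' @param g a [signed_graph()].
#' @param k recombination budget; `Inf` (default) runs in optimization
#'   mode, where budget-dependent forcing is disabled.
#' @param mode `"optimization"` or `"decision"`; defaults to decision
#'   exactly when `k` is finite.
#' @return object of class `reduction_result`: list with `graph` (the
#'   reduced [signed_graph()]), `k` (remaining budget), `spent`
#'   (recombinations charged by the rules), `trace` (replayable record
#'   list), `no_instance`, and `stats` (initial/reduced vertex and signed
#'   edge counts, the shape of a kernelization report).
#' @export
reduce_to_fixpoint <- function(g, k = Inf,
                               mode = if (is.finite(k)) "decision" else "optimization") {
  mode <- match.arg(mode, c("optimization", "decision"))
  if (mode == "decision" && !is.finite(k)) stop("decision mode needs finite k")
  if (is.finite(k) && k < 0) stop("k must be >= 0")
  stats0 <- c(vertices = nrow(g$vertices),
              pos_edges = sum(g$edges$sign == 1L),
              neg_edges = sum(g$edges$sign == -1L))
  w <- wg_new(g, k, mode)
  while (w$qhead <= length(w$queue) && !w$no_instance) {
    x <- w$queue[w$qhead]
    w$qhead <- w$qhead + 1L
    w$inq[x] <- FALSE
    wg_process(w, x)
  }
  trace <- w$trace[seq_len(w$tn)]
  if (w$no_instance) {
    return(structure(list(graph = NULL, k = k - w$spent, spent = w$spent,
                          trace = trace, no_instance = TRUE,
                          stats = list(initial = stats0, reduced = NULL)),
                     class = "reduction_result"))
  }
  keep <- which(w$active)
  remap <- integer(length(w$name))
  remap[keep] <- seq_along(keep)
  ea <- which(w$ealive)
  vertices <- data.frame(name = w$name[keep], color = w$color[keep],
                         origin = w$color[keep], source = w$name[keep],
                         stringsAsFactors = FALSE)
  edges <- data.frame(u = remap[w$eu[ea]], v = remap[w$ev[ea]],
                      sign = w$esign[ea], etype = w$etype[ea],
                      prov_parent = w$eparent[ea], prov_child = w$echild[ea],
                      stringsAsFactors = FALSE)
  gr <- signed_graph(vertices, edges)
  stats1 <- c(vertices = nrow(vertices),
              pos_edges = sum(edges$sign == 1L),
              neg_edges = sum(edges$sign == -1L))
  structure(list(graph = gr, k = k - w$spent, spent = w$spent, trace = trace,
                 no_instance = FALSE,
                 stats = list(initial = stats0, reduced = stats1)),
            class = "reduction_result")
}

#' @export
print.reduction_result <- function(x, ...) {
  if (x$no_instance) {
    cat("<reduction_result> No-instance (forced recombinations exceed budget)\n")
    return(invisible(x))
  }
  i <- x$stats$initial
  r <- x$stats$reduced
  cat(sprintf(
    "<reduction_result> vertices %d -> %d, pos edges %d -> %d, neg edges %d -> %d, spent %d\n",
    i["vertices"], r["vertices"], i["pos_edges"], r["pos_edges"],
    i["neg_edges"], r["neg_edges"], x$spent))
  invisible(x)
}

#' Recover colours for every original vertex from a reduction trace
#'
#' Replays the trace in reverse, starting from a full red/green colouring
#' of the reduced graph: merged vertices inherit the colour of their merge
#' target; deleted vertices are coloured by the directive their rule's
#' proof dictates (same as / opposite of a reference vertex, or a fixed
#' colour). The result, evaluated with [line_index_of_labeling()] on the
#' original graph, reproduces `spent + l(reduced)` exactly.
#'
#' @param trace the `trace` component of a [reduce_to_fixpoint()] result.
#' @param reduced_colors named character vector colouring every vertex of
#'   the reduced graph red/green.
#' @return named character vector covering all original vertices.
#' @export
replay_trace <- function(trace, reduced_colors) {
  colors <- as.list(reduced_colors)
  if (length(trace)) {
    for (i in rev(seq_along(trace))) {
      rec <- trace[[i]]
      if (rec$type == "edge") next
      if (rec$type == "merge") {
        ref <- colors[[rec$into]]
        if (is.null(ref)) stop("trace/colouring mismatch at merge into ", rec$into)
        colors[[rec$vertex]] <- ref
      } else {
        d <- rec$directive
        val <- switch(d$kind,
          fixed = if (d$ref == "grey") "green" else d$ref,
          same = colors[[d$ref]],
          opposite = flip_color(colors[[d$ref]]),
          stop("unknown directive kind: ", d$kind))
        if (is.null(val)) stop("trace/colouring mismatch at vertex ", rec$vertex)
        colors[[rec$vertex]] <- val
      }
    }
  }
  unlist(colors)
}
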