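#' Label a member from its two-site genotype
#'
#' Both sites homozygous with the same value -> `"green"`; both homozygous
#' with different values -> `"red"`; both heterozygous -> `"grey"`; exactly
#' one heterozygous site -> `"unlabeled"` (such members get no vertex: a
#' recombination in them is undetectable and, as children, they only induce
#' a negative edge between their parents). Vectorized over members.
#'
#' @param g1,g2 per-site genotype codes in `{0, 1, 2}`.
#' @return character vector over `{"green", "red", "grey", "unlabeled"}`.
#' @export
label_member <- function(g1, g2) {
  stopifnot(all(g1 %in% 0:2), all(g2 %in% 0:2))
  out <- rep("unlabeled", length(g1))
  out[g1 != 2L & g2 != 2L & g1 == g2] <- "green"
  out[g1 != 2L & g2 != 2L & g1 != g2] <- "red"
  out[g1 == 2L & g2 == 2L] <- "grey"
  out
}

#' Build the signed pedigree graph
#'
#' One vertex per labeled member. For every parent-child pair with both
#' endpoints labeled, a positive edge (labels should agree unless a
#' recombination occurs in the parent's transmission). For every trio whose
#' parents are both labeled and whose child is unlabeled, a negative edge
#' between the parents (their labels should differ unless one transmission
#' recombines). Forced colours are then propagated with
#' [propagate_resolved()]. The graph has at most `n` vertices and `O(n)`
#' edges.
#'
#' @param ped a [new_pedigree()] object.
#' @return a [signed_graph()]; unlabeled member ids are kept in
#'   `attr(, "unlabeled")` for later haplotype reconstruction.
#' @export
build_graph <- function(ped) {
  m <- ped$members
  lab <- label_member(m$g1, m$g2)
  keep <- lab != "unlabeled"
  vertices <- data.frame(name = m$id[keep], color = lab[keep],
                         origin = lab[keep], source = m$id[keep],
                         stringsAsFactors = FALSE)
  vid <- stats::setNames(seq_len(nrow(vertices)), vertices$name)
  labv <- stats::setNames(lab, m$id)

  tr <- ped$trios
  # positive edges: labeled parent -- labeled child
  pc <- rbind(
    data.frame(parent = tr$father, child = tr$child, stringsAsFactors = FALSE),
    data.frame(parent = tr$mother, child = tr$child, stringsAsFactors = FALSE)
  )
  pos_keep <- labv[pc$parent] != "unlabeled" & labv[pc$child] != "unlabeled"
  pos <- pc[pos_keep, , drop = FALSE]
  # negative edges: both parents labeled, child unlabeled
  neg_keep <- labv[tr$father] != "unlabeled" & labv[tr$mother] != "unlabeled" &
    labv[tr$child] == "unlabeled"
  neg <- tr[neg_keep, , drop = FALSE]

  # Unary transmission constraints: for a trio with an unlabeled child c
  # heterozygous at site s, a grey parent p, and an unlabeled co-parent q
  # heterozygous at the OTHER site, q's transmitted allele at site s is
  # fixed, so the haplotype p must pass to c is fully determined; p avoids
  # a recombination exactly when its phase matches that haplotype's colour
  # (green iff the child's and q's homozygous-site values differ). Encoded
  # as a positive edge from p to a shared resolved anchor vertex of that
  # colour. (A doubly-homozygous p satisfies the constraint automatically
  # by Mendelian consistency, so only grey p need an edge.)
  gmat <- rbind(stats::setNames(m$g1, m$id), stats::setNames(m$g2, m$id))
  un <- NULL
  cand <- which((labv[tr$father] == "grey") + (labv[tr$mother] == "grey") == 1L &
                  (labv[tr$father] == "unlabeled") +
                  (labv[tr$mother] == "unlabeled") == 1L &
                  labv[tr$child] == "unlabeled")
  if (length(cand)) {
    urows <- lapply(cand, function(t) {
      p <- if (labv[tr$father[t]] == "grey") tr$father[t] else tr$mother[t]
      q <- if (labv[tr$father[t]] == "grey") tr$mother[t] else tr$father[t]
      cid <- tr$child[t]
      s_c <- which(gmat[, cid] == 2L)
      s_q <- which(gmat[, q] == 2L)
      if (s_q == s_c) return(NULL)
      a <- gmat[3L - s_c, cid]   # child's homozygous-site value
      b <- gmat[3L - s_q, q]     # co-parent's homozygous-site value
      data.frame(p = p, child = cid, chi = if (a != b) "green" else "red",
                 stringsAsFactors = FALSE)
    })
    un <- do.call(rbind, urows)
  }
  anchor <- c(green = NA_integer_, red = NA_integer_)
  if (!is.null(un) && nrow(un)) {
    for (col in intersect(c("green", "red"), unique(un$chi))) {
      vertices <- rbind(vertices, data.frame(
        name = paste0(".f", col), color = col, origin = col,
        source = "unary_anchor", stringsAsFactors = FALSE))
      anchor[col] <- nrow(vertices)
      vid <- stats::setNames(seq_len(nrow(vertices)), vertices$name)
    }
  }

  edges <- rbind(
    if (nrow(pos)) data.frame(
      u = unname(vid[pos$parent]), v = unname(vid[pos$child]), sign = 1L,
      etype = "parent_child", prov_parent = pos$parent,
      prov_child = pos$child, stringsAsFactors = FALSE),
    if (nrow(neg)) data.frame(
      u = unname(vid[neg$father]), v = unname(vid[neg$mother]), sign = -1L,
      etype = "trio", prov_parent = neg$father, prov_child = neg$child,
      stringsAsFactors = FALSE),
    if (!is.null(un) && nrow(un)) data.frame(
      u = unname(anchor[un$chi]), v = unname(vid[un$p]), sign = 1L,
      etype = "unary", prov_parent = un$p, prov_child = un$child,
      stringsAsFactors = FALSE)
  )
  if (is.null(edges)) {
    edges <- data.frame(u = integer(0), v = integer(0), sign = integer(0))
  }
  g <- signed_graph(vertices, edges)
  g <- propagate_resolved(g)
  g <- force_unlabeled_parent_pairs(g, ped)
  attr(g, "unlabeled") <- m$id[!keep]
  g
}

# A grey child both of whose parents are unlabeled at COMPLEMENTARY sites
# has a forced phase: a parent heterozygous only at site 1 with homozygous
# value a at site 2 can transmit only (x, a), and one heterozygous only at
# site 2 with homozygous value b at site 1 only (b, y) — recombinants
# included — so the child's complementary pair must be {(b̄, a), (b, ā)},
# i.e. green exactly when a != b. Like doubly-homozygous propagation this
# is a zero-cost hard constraint invisible to the edge set (the parents
# have no vertices), so the child is coloured at build time.
force_unlabeled_parent_pairs <- function(g, ped) {
  m <- ped$members
  lab <- stats::setNames(label_member(m$g1, m$g2), m$id)
  g1 <- stats::setNames(m$g1, m$id)
  g2 <- stats::setNames(m$g2, m$id)
  tr <- ped$trios
  sel <- lab[tr$child] == "grey" & lab[tr$father] == "unlabeled" &
    lab[tr$mother] == "unlabeled"
  for (t in which(sel)) {
    pf <- tr$father[t]
    pm <- tr$mother[t]
    f_het1 <- g1[[pf]] == 2L
    m_het1 <- g1[[pm]] == 2L
    if (f_het1 == m_het1) next  # same heterozygous site: phase not forced
    p1 <- if (f_het1) pf else pm       # heterozygous at site 1
    p2 <- if (f_het1) pm else pf       # heterozygous at site 2
    a <- g2[[p1]]
    b <- g1[[p2]]
    col <- if (a != b) "green" else "red"
    ci <- vertex_index(g, tr$child[t])
    if (g$vertices$color[ci] == "grey") {
      g$vertices$color[ci] <- col
    }
  }
  g
}

#' Propagate forced colours from doubly-homozygous parents
#'
#' A parent that is homozygous at both sites carries two identical
#' haplotypes, so it always transmits the same haplotype and no
#' recombination in it is detectable; a grey child joined to it by a
#' positive edge is therefore forced to the parent's colour (the child
#' necessarily carries the transmitted haplotype). Only genotype-resolved
#' parents (vertex `origin` red/green) force: a grey vertex coloured by
#' propagation still has two distinct haplotypes and its own transmissions
#' can recombine, so the forcing does not cascade through it. Repeated to
#' fixpoint (a single pass, since propagation targets never become
#' sources).
#'
#' @param g a [signed_graph()] whose positive edges carry
#'   `prov_parent`/`prov_child` provenance.
#' @return the graph with forced greys recoloured.
#' @export
propagate_resolved <- function(g) {
  if (!nrow(g$edges)) return(g)
  repeat {
    pos <- g$edges$sign == 1L & !is.na(g$edges$prov_parent)
    if (!any(pos)) break
    pid <- vertex_index(g, g$edges$prov_parent[pos])
    cid <- vertex_index(g, g$edges$prov_child[pos])
    forcing <- !is.na(pid) & !is.na(cid) &
      g$vertices$origin[pid] %in% c("red", "green") &
      g$vertices$color[cid] == "grey"
    if (!any(forcing)) break
    g$vertices$color[cid[forcing]] <- g$vertices$color[pid[forcing]]
  }
  g
}

#' Frustration of a full colouring (line index of a labelled cut)
#'
#' Given a colour for every vertex, counts the frustrated edges: positive
#' edges with differently-coloured endpoints plus negative edges with
#' same-coloured endpoints. Each frustrated edge represents one
#' recombination event; the minimum over colourings that respect the
#' resolved vertices is the line index of the graph and the minimum
#' recombination count of the pedigree.
#'
#' @param g a [signed_graph()].
#' @param colors character vector of `"red"`/`"green"`, either named by
#'   vertex name or in vertex order.
#' @return list with `value` (frustrated edge count), `frustrated`
#'   (edge indices), `partition` (named sides `V1` = red, `V2` = green).
#' @export
line_index_of_labeling <- function(g, colors) {
  if (!is.null(names(colors))) {
    colors <- colors[g$vertices$name]
  }
  if (length(colors) != nrow(g$vertices) || any(is.na(colors))) {
    stop("colors must cover every vertex")
  }
  if (!all(colors %in% c("red", "green"))) {
    stop("every vertex (including greys) must be coloured red or green")
  }
  e <- g$edges
  if (!nrow(e)) {
    return(list(value = 0L, frustrated = integer(0),
                partition = stats::setNames(
                  ifelse(colors == "red", "V1", "V2"), g$vertices$name)))
  }
  same <- colors[e$u] == colors[e$v]
  frus <- which((e$sign == 1L & !same) | (e$sign == -1L & same))
  list(value = length(frus), frustrated = frus,
       partition = stats::setNames(ifelse(colors == "red", "V1", "V2"),
                                   g$vertices$name))
}
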