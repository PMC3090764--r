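# Orchestration: decision (at most k recombinations?) and optimization
# (minimum k*) runs, plus reconstruction of a full haplotype configuration
# with localized recombination events.

# Solve a reduced signed graph: transform to an all-negative graph, merge
# the colour classes into guarded supernodes, and run edge bipartization.
# Returns the line index of the graph and an optimal full colouring.
solve_reduced <- function(gr, k = Inf) {
  if (!nrow(gr$vertices)) return(list(l = 0L, colors = character(0)))
  if (!nrow(gr$edges)) {
    cols <- ifelse(gr$vertices$color == "grey", "green", gr$vertices$color)
    return(list(l = 0L, colors = stats::setNames(cols, gr$vertices$name)))
  }
  gneg <- to_all_negative(gr)
  mg <- merge_and_guard(gneg, k)
  inst <- negate_weights(mg$graph)
  C <- edge_bipartization(inst)
  sides <- two_coloring_from_removal(inst, C)
  red_side <- if (".red" %in% names(sides)) {
    sides[[".red"]]
  } else if (".green" %in% names(sides)) {
    setdiff(c("V1", "V2"), sides[[".green"]])
  } else {
    "V1"
  }
  vnames <- gr$vertices$name
  vsides <- sides[mg$map[vnames]]
  colors <- stats::setNames(ifelse(vsides == red_side, "red", "green"), vnames)
  n_guard_cut <- sum(is.na(inst$edges$orig[C]))
  list(l = length(C) + mg$extra_cost, colors = colors,
       guards_cut = n_guard_cut)
}

#' Decide whether k recombination events suffice
#'
#' Runs the full pipeline: signed-graph construction, data reduction in
#' decision mode with budget `k`, transformation to Bipartization by Edge
#' Removal (guarded supernodes), iterative-compression solve, and — on a
#' Yes answer — colour recovery through the reduction trace and haplotype
#' reconstruction.
#'
#' @param ped a [new_pedigree()] object.
#' @param k non-negative recombination budget.
#' @return list with `answer` (`"YES"`/`"NO"`), and on YES `config` (a
#'   `haplotype_config` witness with at most `k` events) and `k_events`
#'   (its event count).
#' @export
mrhc_decide <- function(ped, k) {
  stopifnot(k >= 0)
  g <- build_graph(ped)
  decide_on_graph(ped, g, k)
}

decide_on_graph <- function(ped, g, k) {
  red <- reduce_to_fixpoint(g, k, mode = "decision")
  if (red$no_instance) return(list(answer = "NO"))
  sol <- solve_reduced(red$graph, red$k)
  if (sol$l > red$k) return(list(answer = "NO"))
  full <- replay_trace(red$trace, sol$colors)
  li <- line_index_of_labeling(g, full)
  if (li$value != red$spent + sol$l) {
    stop("internal error: replayed colouring has frustration ", li$value,
         " but reduction + solver accounted ", red$spent + sol$l)
  }
  config <- labels_to_haplotypes(ped, full, graph = g)
  list(answer = "YES", config = config, k_events = li$value)
}

#' Minimum-recombinant haplotype configuration
#'
#' Finds the smallest `k*` for which the decision problem answers Yes, by
#' incrementing `k` from the lower bound given by the recombinations that
#' resolved vertices already force, and returns a witness configuration.
#'
#' @param ped a [new_pedigree()] object.
#' @return list with `k_star` and `config` (a `haplotype_config` whose
#'   independently counted events equal `k_star`).
#' @export
mrhc_minimize <- function(ped) {
  g <- build_graph(ped)
  k <- forced_conflicts(g)
  cap <- nrow(g$edges)
  repeat {
    res <- decide_on_graph(ped, g, k)
    if (res$answer == "YES") {
      return(list(k_star = res$k_events, config = res$config))
    }
    k <- k + 1L
    if (k > cap) stop("internal error: no solution within |E| events")
  }
}

#' Reconstruct haplotypes and recombination events from vertex colours
#'
#' Grey members resolve to `{00, 11}` (green) or `{01, 10}` (red); members
#' with a homozygous site have a unique unordered pair. Haplotypes are
#' ordered paternal-first where parents exist (per-trio parental origins
#' are chosen to minimize transmission cost), otherwise lexicographically.
#' Events are localized on the frustrated edges of the colouring: a
#' frustrated positive edge charges the parent of its parent-child pair; a
#' frustrated negative edge charges, by convention, the father of the trio
#' whose unlabeled child induced it.
#'
#' @param ped a [new_pedigree()] object.
#' @param colors named red/green colouring of every labeled member.
#' @param graph optionally the pedigree's [build_graph()] result (rebuilt
#'   when omitted).
#' @return object of class `haplotype_config`: list with `phased` (named
#'   list of ordered haplotype pairs), `origins` (per-trio transmission
#'   sources), `events` (data.frame `child`, `parent`) and `k` (event
#'   count, equal to the colouring's frustration).
#' @export
labels_to_haplotypes <- function(ped, colors, graph = NULL) {
  if (is.null(graph)) graph <- build_graph(ped)
  m <- ped$members
  lab <- label_member(m$g1, m$g2)
  resolved_clash <- lab %in% c("red", "green") & !is.na(colors[m$id]) &
    colors[m$id] != lab
  if (any(resolved_clash)) {
    stop("internal error: resolved member recoloured differently: ",
         paste(m$id[resolved_clash], collapse = ", "))
  }
  phased <- vector("list", nrow(m))
  names(phased) <- m$id
  for (i in seq_len(nrow(m))) {
    phase <- if (lab[i] == "grey") {
      col <- colors[[m$id[i]]]
      if (is.null(col) || is.na(col)) stop("no colour for grey member ", m$id[i])
      col
    } else NULL
    phased[[i]] <- sort(geno_to_haps(m$g1[i], m$g2[i], phase))
  }
  # orient each child's pair paternal-first, choosing the cheaper of the
  # two parental-origin assignments
  origins <- NULL
  if (nrow(ped$trios)) {
    orows <- vector("list", nrow(ped$trios))
    for (t in seq_len(nrow(ped$trios))) {
      f <- phased[[ped$trios$father[t]]]
      mo <- phased[[ped$trios$mother[t]]]
      ch <- phased[[ped$trios$child[t]]]
      a <- transmit_cost(ch[1], f[1], f[2]) + transmit_cost(ch[2], mo[1], mo[2])
      b <- transmit_cost(ch[2], f[1], f[2]) + transmit_cost(ch[1], mo[1], mo[2])
      if (b < a) ch <- ch[2:1]
      phased[[ped$trios$child[t]]] <- ch
      src <- function(h, par) {
        if (h == par[1]) "h1" else if (h == par[2]) "h2" else "recombinant"
      }
      orows[[t]] <- data.frame(
        child = ped$trios$child[t],
        father = ped$trios$father[t], from_father = ch[1],
        father_source = src(ch[1], f),
        mother = ped$trios$mother[t], from_mother = ch[2],
        mother_source = src(ch[2], mo),
        stringsAsFactors = FALSE)
    }
    origins <- do.call(rbind, orows)
  }
  li <- line_index_of_labeling(graph, colors)
  e <- graph$edges[li$frustrated, , drop = FALSE]
  fathers <- stats::setNames(ped$trios$father, ped$trios$child)
  events <- data.frame(child = character(0), parent = character(0),
                       stringsAsFactors = FALSE)
  if (nrow(e)) {
    events <- data.frame(
      child = e$prov_child,
      parent = ifelse(e$sign == 1L, e$prov_parent,
                      unname(fathers[e$prov_child])),
      stringsAsFactors = FALSE)
  }
  structure(list(phased = phased, origins = origins, events = events,
                 k = li$value),
            class = "haplotype_config")
}

#' @export
print.haplotype_config <- function(x, ...) {
  cat(sprintf("<haplotype_config> %d members phased, %d recombination event(s)\n",
              length(x$phased), x$k))
  invisible(x)
}

#' Independently count the recombination events of a configuration
#'
#' For each trio, each transmitted haplotype costs 0 if it equals a
#' parental haplotype and 1 if it is a between-site recombinant of the
#' parent's pair (with two sites at most one crossover is detectable per
#' transmission); the cost is minimized over the two ways of assigning the
#' child's haplotypes to the parents. This count is computed straight from
#' the haplotypes, independent of the signed-graph machinery, and equals
#' the frustration of the colouring that produced the configuration.
#'
#' @param ped a [new_pedigree()] object.
#' @param config a `haplotype_config` (or any list with a `phased`
#'   component of per-member haplotype pairs).
#' @return list with `count` and `events` (data.frame `child`, `parent`).
#' @export
count_recombinations <- function(ped, config) {
  phased <- config$phased
  m <- ped$members
  for (i in seq_len(nrow(m))) {
    h <- phased[[m$id[i]]]
    if (is.null(h)) stop("no haplotypes for member ", m$id[i])
    gg <- c(geno_code(as.integer(hap_site(h[1], 1)), as.integer(hap_site(h[2], 1))),
            geno_code(as.integer(hap_site(h[1], 2)), as.integer(hap_site(h[2], 2))))
    if (gg[1] != m$g1[i] || gg[2] != m$g2[i]) {
      stop("haplotypes of member ", m$id[i], " are inconsistent with its genotype")
    }
  }
  total <- 0L
  ev <- list()
  for (t in seq_len(nrow(ped$trios))) {
    fid <- ped$trios$father[t]
    mid <- ped$trios$mother[t]
    cid <- ped$trios$child[t]
    f <- phased[[fid]]
    mo <- phased[[mid]]
    ch <- phased[[cid]]
    ca <- c(transmit_cost(ch[1], f[1], f[2]), transmit_cost(ch[2], mo[1], mo[2]))
    cb <- c(transmit_cost(ch[2], f[1], f[2]), transmit_cost(ch[1], mo[1], mo[2]))
    use <- if (sum(cb) < sum(ca)) cb else ca
    if (!all(is.finite(use))) {
      stop("configuration violates Mendelian transmission in trio with child ", cid)
    }
    total <- total + sum(use)
    if (use[1] > 0) ev[[length(ev) + 1L]] <- c(cid, fid)
    if (use[2] > 0) ev[[length(ev) + 1L]] <- c(cid, mid)
  }
  events <- if (length(ev)) {
    data.frame(child = vapply(ev, `[`, "", 1), parent = vapply(ev, `[`, "", 2),
               stringsAsFactors = FALSE)
  } else {
    data.frame(child = character(0), parent = character(0),
               stringsAsFactors = FALSE)
  }
  list(count = as.integer(total), events = events)
}
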