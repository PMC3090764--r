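# Brute-force reference implementations. These are deliberately independent
# of the reduction/bipartization pipeline: they enumerate colourings or
# phase configurations directly and are used as oracles in the test suite.

#' Line index by exhaustive enumeration
#'
#' Enumerates all `2^{#grey}` red/green colourings of the grey vertices
#' (resolved vertices keep their colours) and returns the minimum
#' frustrated-edge count.
#'
#' @param g a [signed_graph()].
#' @param max_grey size guard on the number of grey vertices.
#' @return list with `value` and `colors` (a full optimal colouring, named).
#' @export
line_index_bruteforce <- function(g, max_grey = 24L) {
  grey <- which(g$vertices$color == "grey")
  ng <- length(grey)
  if (ng > max_grey) {
    stop("too many grey vertices for brute force: ", ng, " > ", max_grey)
  }
  colors <- g$vertices$color
  e <- g$edges
  ncfg <- 2L^ng
  if (!nrow(e)) {
    colors[grey] <- "green"
    colors[colors == "grey"] <- "green"
    return(list(value = 0L,
                colors = stats::setNames(colors, g$vertices$name)))
  }
  pos <- e$sign == 1L
  best <- Inf
  best_cfg <- NULL
  # colour index: 0 = red, 1 = green
  base <- ifelse(colors == "green", 1L, 0L)
  for (cfg in 0:(ncfg - 1L)) {
    cur <- base
    if (ng) cur[grey] <- as.integer(intToBits(cfg))[seq_len(ng)]
    same <- cur[e$u] == cur[e$v]
    val <- sum(pos & !same) + sum(!pos & same)
    if (val < best) {
      best <- val
      best_cfg <- cur
    }
  }
  out <- ifelse(best_cfg == 1L, "green", "red")
  list(value = as.integer(best),
       colors = stats::setNames(out, g$vertices$name))
}

#' Minimum edge bipartization by exhaustive enumeration
#'
#' Enumerates all two-colourings of the vertices (the first vertex's side
#' is fixed) and returns the smallest set of monochromatic edges.
#'
#' @param inst a `bipartization_instance` (or list with `n` and `edges`).
#' @param max_vertices size guard.
#' @return list with `size` and `C` (edge row indices).
#' @export
bipartization_bruteforce <- function(inst, max_vertices = 24L) {
  n <- inst$n
  if (n > max_vertices) {
    stop("too many vertices for brute force: ", n, " > ", max_vertices)
  }
  e <- inst$edges
  if (!nrow(e)) return(list(size = 0L, C = integer(0)))
  best <- Inf
  bestC <- NULL
  for (cfg in 0:(2L^(max(0L, n - 1L)) - 1L)) {
    side <- c(0L, as.integer(intToBits(cfg))[seq_len(n - 1L)])
    mono <- which(side[e$u] == side[e$v])
    if (length(mono) < best) {
      best <- length(mono)
      bestC <- mono
    }
  }
  list(size = as.integer(best), C = bestC)
}

#' Minimum-recombinant haplotype configuration by enumeration
#'
#' Enumerates the phase of every doubly-heterozygous (grey) member — the
#' only free choice, since all other members have a unique unordered
#' haplotype pair — and, for each configuration, sums per-trio minimum
#' transmission costs (0 for a parental haplotype, 1 for a between-site
#' recombinant, minimized over the two ways of assigning the child's
#' haplotypes to the parents). Returns the global minimum.
#'
#' @param ped a [new_pedigree()] object.
#' @param max_members size guard.
#' @return minimum number of recombination events (integer).
#' @export
mrhc_bruteforce <- function(ped, max_members = 12L) {
  m <- ped$members
  if (nrow(m) > max_members) {
    stop("too many members for brute force: ", nrow(m), " > ", max_members)
  }
  lab <- label_member(m$g1, m$g2)
  grey <- which(lab == "grey")
  ng <- length(grey)
  idx <- stats::setNames(seq_len(nrow(m)), m$id)
  haps_for <- function(i, phase_bit) {
    if (lab[i] == "grey") {
      geno_to_haps(m$g1[i], m$g2[i], if (phase_bit) "red" else "green")
    } else {
      geno_to_haps(m$g1[i], m$g2[i])
    }
  }
  trio_cost <- function(haps, t) {
    f <- haps[[idx[[ped$trios$father[t]]]]]
    mo <- haps[[idx[[ped$trios$mother[t]]]]]
    ch <- haps[[idx[[ped$trios$child[t]]]]]
    a <- transmit_cost(ch[1], f[1], f[2]) + transmit_cost(ch[2], mo[1], mo[2])
    b <- transmit_cost(ch[2], f[1], f[2]) + transmit_cost(ch[1], mo[1], mo[2])
    min(a, b)
  }
  best <- Inf
  for (cfg in 0:(2L^ng - 1L)) {
    bits <- if (ng) as.integer(intToBits(cfg))[seq_len(ng)] else integer(0)
    phase <- integer(nrow(m))
    phase[grey] <- bits
    haps <- lapply(seq_len(nrow(m)), function(i) haps_for(i, phase[i]))
    tot <- 0
    for (t in seq_len(nrow(ped$trios))) {
      tot <- tot + trio_cost(haps, t)
      if (tot >= best) break
    }
    if (tot < best) best <- tot
  }
  if (!is.finite(best)) stop("no feasible haplotype configuration found")
  as.integer(best)
}
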