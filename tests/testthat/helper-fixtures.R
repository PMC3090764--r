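# Shared fixture builders: everything is generated in code at test time.

# Random signed multigraph with mixed vertex colours.
rand_signed_graph <- function(seed, max_v = 10L, max_e = 14L, p_grey = 0.5) {
  set.seed(seed)
  n <- sample(3:max_v, 1)
  other <- (1 - p_grey) / 2
  cols <- sample(c("red", "green", "grey"), n, replace = TRUE,
                 prob = c(other, other, p_grey))
  m <- sample(0:max_e, 1)
  if (m > 0) {
    u <- integer(m)
    v <- integer(m)
    for (j in seq_len(m)) {
      pr <- sample(n, 2)
      u[j] <- pr[1]
      v[j] <- pr[2]
    }
    e <- data.frame(u = u, v = v, sign = sample(c(1L, -1L), m, replace = TRUE))
  } else {
    e <- data.frame(u = integer(0), v = integer(0), sign = integer(0))
  }
  signed_graph(data.frame(name = paste0("v", seq_len(n)), color = cols), e)
}

# Random unsigned multigraph wrapped as a bipartization instance.
rand_multigraph_inst <- function(seed, max_v = 10L, max_e = 16L) {
  set.seed(seed)
  n <- sample(3:max_v, 1)
  m <- sample(1:max_e, 1)
  u <- integer(m)
  v <- integer(m)
  for (j in seq_len(m)) {
    pr <- sample(n, 2)
    u[j] <- pr[1]
    v[j] <- pr[2]
  }
  structure(list(n = n, names = paste0("v", seq_len(n)),
                 edges = data.frame(u = u, v = v, tag = "graph",
                                    orig = seq_len(m))),
            class = "bipartization_instance")
}

# Compact pedigree builder: mem("id", g1, g2, father, mother).
mem <- function(id, g1, g2, father = NA, mother = NA, sex = "1") {
  data.frame(id = id, father = father, mother = mother, sex = sex,
             g1 = g1, g2 = g2, stringsAsFactors = FALSE)
}

ped_of <- function(...) new_pedigree(do.call(rbind, list(...)))

# Small random Mendelian-consistent pedigree via the simulator.
rand_small_ped <- function(seed, n_range = 3:12, max_loop = 0.3,
                           max_rate = 0.25) {
  set.seed(seed)
  p <- sim_params(n_members = sample(n_range, 1),
                  loop_rate = stats::runif(1, 0, max_loop),
                  rate = stats::runif(1, 0, max_rate),
                  seed = seed)
  simulate_pedigree(p)
}

# Frustration of an explicit colouring without package internals (test-side
# oracle double-check).
naive_frustration <- function(g, colors) {
  e <- g$edges
  if (!nrow(e)) return(0L)
  same <- colors[e$u] == colors[e$v]
  sum((e$sign == 1L & !same) | (e$sign == -1L & same))
}
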