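# Simulation of random complex looped pedigrees with two-site genotypes
# produced by gene dropping, with optional planted recombinations.

#' Simulation parameters
#'
#' Defaults emulate large, highly complex looped pedigrees: families are
#' founded either by a new external spouse or, at the loop rate, by a
#' mating between two existing members — who may be blood relatives,
#' including a member's own descendants — so members can accumulate many
#' spouses and the pedigree graph acquires cycles. Children per family are
#' `1 + Poisson(mean_children - 1)`. Founder haplotypes are drawn from
#' `founder_freqs` (uniform over 00/01/10/11 by default, which maximizes
#' the diversity of member labels). Recombination is either a per-
#' transmission `rate` or an exact planted `count`.
#'
#' @param n_members total pedigree size (>= 3).
#' @param mean_children expected children per family.
#' @param loop_rate probability that a new family mates two existing
#'   members instead of adding an external spouse.
#' @param founder_freqs named haplotype frequencies for founders.
#' @param rate per-transmission recombination probability.
#' @param count exact number of planted recombination events (overrides
#'   `rate` when non-NULL).
#' @param seed integer seed; the seed fully determines the output.
#' @return object of class `sim_params`.
#' @export
sim_params <- function(n_members, mean_children = 2.33, loop_rate = 0.15,
                       founder_freqs = c(`00` = 0.25, `01` = 0.25,
                                         `10` = 0.25, `11` = 0.25),
                       rate = 0, count = NULL, seed = 1L) {
  stopifnot(n_members >= 3, mean_children > 1, loop_rate >= 0, loop_rate <= 1,
            length(founder_freqs) == 4,
            setequal(names(founder_freqs), c("00", "01", "10", "11")),
            rate >= 0, rate <= 1)
  structure(list(n_members = as.integer(n_members),
                 mean_children = mean_children, loop_rate = loop_rate,
                 founder_freqs = founder_freqs / sum(founder_freqs),
                 rate = rate, count = count, seed = as.integer(seed)),
            class = "sim_params")
}

#' Generate a random looped pedigree structure (no genotypes)
#'
#' Grows the pedigree family by family from a single founder couple. Each
#' family picks one parent uniformly from the existing members and, with
#' probability `loop_rate`, a second existing member of the opposite sex
#' (possibly a relative or descendant — this is what creates cycles and
#' multi-spouse members); otherwise a fresh external founder spouse is
#' created. The parent DAG is acyclic by construction and the pedigree is
#' connected.
#'
#' @param params a [sim_params()] object.
#' @return data.frame with columns `id`, `father`, `mother`, `sex`
#'   (`"1"` male / `"2"` female), in creation (hence topological) order.
#' @export
generate_pedigree <- function(params) {
  set.seed(params$seed)
  n <- params$n_members
  id <- character(n)
  father <- rep(NA_character_, n)
  mother <- rep(NA_character_, n)
  sex <- character(n)
  cnt <- 2L
  id[1:2] <- c("m1", "m2")
  sex[1:2] <- c("1", "2")
  males <- 1L
  females <- 2L
  while (cnt < n) {
    a <- c(males, females)[sample.int(length(males) + length(females), 1L)]
    want <- if (sex[a] == "1") "2" else "1"
    pool <- if (want == "1") males else females
    pool <- setdiff(pool, a)
    b <- NA_integer_
    # mate internally at the loop rate, or when creating an external
    # spouse would exhaust the member budget before any child fits
    if (length(pool) &&
        (stats::runif(1) < params$loop_rate || cnt + 1L >= n)) {
      b <- pool[sample.int(length(pool), 1L)]
    } else {
      cnt <- cnt + 1L
      b <- cnt
      id[b] <- paste0("m", b)
      sex[b] <- want
      if (want == "1") males <- c(males, b) else females <- c(females, b)
      if (cnt == n) break
    }
    fa <- if (sex[a] == "1") a else b
    mo <- if (sex[a] == "1") b else a
    nkids <- min(1L + stats::rpois(1L, params$mean_children - 1), n - cnt)
    for (j in seq_len(nkids)) {
      cnt <- cnt + 1L
      id[cnt] <- paste0("m", cnt)
      father[cnt] <- id[fa]
      mother[cnt] <- id[mo]
      sex[cnt] <- sample(c("1", "2"), 1L)
      if (sex[cnt] == "1") males <- c(males, cnt) else females <- c(females, cnt)
    }
  }
  data.frame(id = id, father = father, mother = mother, sex = sex,
             stringsAsFactors = FALSE)
}

#' Gene-drop two-site haplotypes down a pedigree structure
#'
#' Founders draw two haplotypes from the founder frequencies; every
#' transmission picks one parental haplotype uniformly and, when a
#' recombination fires (per-transmission rate, or exactly `count` planted
#' transmissions sampled without replacement), transmits the between-site
#' recombinant instead. Genotypes are read off the resulting haplotypes,
#' so they are Mendelian-consistent by construction.
#'
#' @param struct a structure from [generate_pedigree()] (or any data.frame
#'   with `id`, `father`, `mother`, `sex` in topological order).
#' @param params a [sim_params()] object.
#' @return list with `pedigree` (a validated [new_pedigree()]) and `truth`
#'   (true haplotypes per member, the planted event list as a data.frame
#'   `child`/`parent`, and the parameters).
#' @export
drop_genes <- function(struct, params) {
  set.seed(params$seed + 1L)
  n <- nrow(struct)
  haps <- c("00", "01", "10", "11")
  h1 <- character(n)
  h2 <- character(n)
  is_child <- !is.na(struct$father)
  n_trans <- 2L * sum(is_child)
  recomb <- rep(FALSE, n_trans)
  if (!is.null(params$count)) {
    if (params$count > n_trans) {
      stop("cannot plant ", params$count, " events in ", n_trans, " transmissions")
    }
    recomb[sample.int(n_trans, params$count)] <- TRUE
  } else if (params$rate > 0) {
    recomb <- stats::runif(n_trans) < params$rate
  }
  idx <- stats::setNames(seq_len(n), struct$id)
  transmit <- function(p, rec) {
    pick <- sample.int(2L, 1L)
    ha <- if (pick == 1L) h1[p] else h2[p]
    hb <- if (pick == 1L) h2[p] else h1[p]
    if (rec) paste0(hap_site(ha, 1), hap_site(hb, 2)) else ha
  }
  tcount <- 0L
  ev <- list()
  for (i in seq_len(n)) {
    if (!is_child[i]) {
      h1[i] <- sample(haps, 1L, prob = params$founder_freqs)
      h2[i] <- sample(haps, 1L, prob = params$founder_freqs)
    } else {
      f <- idx[[struct$father[i]]]
      mo <- idx[[struct$mother[i]]]
      tcount <- tcount + 1L
      rf <- recomb[tcount]
      h1[i] <- transmit(f, rf)
      if (rf) ev[[length(ev) + 1L]] <- c(struct$id[i], struct$id[f])
      tcount <- tcount + 1L
      rm_ <- recomb[tcount]
      h2[i] <- transmit(mo, rm_)
      if (rm_) ev[[length(ev) + 1L]] <- c(struct$id[i], struct$id[mo])
    }
  }
  g1 <- geno_code(as.integer(substr(h1, 1, 1)), as.integer(substr(h2, 1, 1)))
  g2 <- geno_code(as.integer(substr(h1, 2, 2)), as.integer(substr(h2, 2, 2)))
  members <- data.frame(id = struct$id, father = struct$father,
                        mother = struct$mother, sex = struct$sex,
                        g1 = g1, g2 = g2, stringsAsFactors = FALSE)
  events <- if (length(ev)) {
    data.frame(child = vapply(ev, `[`, "", 1), parent = vapply(ev, `[`, "", 2),
               stringsAsFactors = FALSE)
  } else {
    data.frame(child = character(0), parent = character(0),
               stringsAsFactors = FALSE)
  }
  truth <- list(haplotypes = stats::setNames(Map(c, h1, h2), struct$id),
                events = events, params = params)
  list(pedigree = new_pedigree(members), truth = truth)
}

#' Simulate a complete pedigree with genotypes
#'
#' Convenience wrapper: [generate_pedigree()] then [drop_genes()].
#'
#' @param params a [sim_params()] object.
#' @return list with `pedigree` and `truth` (see [drop_genes()]).
#' @export
simulate_pedigree <- function(params) {
  drop_genes(generate_pedigree(params), params)
}
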