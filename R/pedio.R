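#' Construct and validate a two-site pedigree
#'
#' Builds a `pedigree` object from a member table. Every member carries a
#' two-site genotype (per-site codes 0 = homozygous 0/0, 1 = homozygous 1/1,
#' 2 = heterozygous). A member either has both parents present in the table
#' or is a founder (both parents `NA`). Looped pedigrees (multiple
#' inheritance paths, spouses that are descendants) are permitted.
#'
#' @param members data.frame with columns `id`, `father`, `mother`, `sex`,
#'   `g1`, `g2`. `father`/`mother` are member ids or `NA`; `sex` is kept but
#'   never used for inheritance (parental roles come from the columns).
#' @return A `pedigree`: list with `members` (validated data.frame) and
#'   `trios` (data.frame `father`, `mother`, `child`, one row per child).
#' @export
new_pedigree <- function(members) {
  req <- c("id", "father", "mother", "sex", "g1", "g2")
  if (!all(req %in% names(members))) {
    stop("members must have columns: ", paste(req, collapse = ", "))
  }
  members$id <- as.character(members$id)
  members$father <- as.character(members$father)
  members$mother <- as.character(members$mother)
  members$g1 <- as.integer(members$g1)
  members$g2 <- as.integer(members$g2)
  if (anyDuplicated(members$id)) {
    stop("duplicate member ids: ",
         paste(unique(members$id[duplicated(members$id)]), collapse = ", "))
  }
  if (!all(members$g1 %in% 0:2) || !all(members$g2 %in% 0:2)) {
    stop("genotype codes must be 0, 1 or 2")
  }
  one_parent <- xor(is.na(members$father), is.na(members$mother))
  if (any(one_parent)) {
    stop("members with exactly one parent: ",
         paste(members$id[one_parent], collapse = ", "))
  }
  has_par <- !is.na(members$father)
  refs <- unique(c(members$father[has_par], members$mother[has_par]))
  missing_ref <- setdiff(refs, members$id)
  if (length(missing_ref)) {
    stop("unknown parent ids: ", paste(missing_ref, collapse = ", "))
  }
  bad_self <- has_par &
    (members$father == members$id | members$mother == members$id |
       members$father == members$mother)
  if (any(bad_self)) {
    stop("father, mother and child must be distinct for: ",
         paste(members$id[bad_self], collapse = ", "))
  }
  trios <- data.frame(father = members$father[has_par],
                      mother = members$mother[has_par],
                      child = members$id[has_par],
                      stringsAsFactors = FALSE)
  ped <- structure(list(members = members, trios = trios),
                   class = "pedigree")
  check_mendelian(ped)
  ped
}

# Per-site Mendelian consistency for every trio: the child's allele pair
# must be formable by taking one allele from each parent.
check_mendelian <- function(ped) {
  m <- ped$members
  idx <- stats::setNames(seq_len(nrow(m)), m$id)
  # transmissible alleles by genotype code: 0 -> "0", 1 -> "1", 2 -> both
  can_give <- list(`0` = "0", `1` = "1", `2` = c("0", "1"))
  child_pair <- list(`0` = c("0", "0"), `1` = c("1", "1"), `2` = c("0", "1"))
  for (t in seq_len(nrow(ped$trios))) {
    f <- idx[[ped$trios$father[t]]]
    mo <- idx[[ped$trios$mother[t]]]
    c_ <- idx[[ped$trios$child[t]]]
    for (site in c("g1", "g2")) {
      fa <- can_give[[as.character(m[[site]][f])]]
      ma <- can_give[[as.character(m[[site]][mo])]]
      cp <- child_pair[[as.character(m[[site]][c_])]]
      ok <- (cp[1] %in% fa && cp[2] %in% ma) ||
        (cp[2] %in% fa && cp[1] %in% ma)
      if (!ok) {
        stop(sprintf(
          "Mendelian inconsistency at site %s in trio (father=%s, mother=%s, child=%s)",
          sub("g", "", site), ped$trios$father[t], ped$trios$mother[t],
          ped$trios$child[t]))
      }
    }
  }
  invisible(ped)
}

#' @export
print.pedigree <- function(x, ...) {
  cat(sprintf("<pedigree> %d members, %d trios, %d founders\n",
              nrow(x$members), nrow(x$trios),
              sum(is.na(x$members$father))))
  invisible(x)
}

#' Read a LINKAGE/PED-style two-site pedigree file
#'
#' Expects whitespace-separated rows `family individual father mother sex
#' a1 a2 a3 a4`: two allele columns per site, alleles coded 1/2 (0 denotes
#' missing data and is rejected, since the method assumes complete,
#' error-free genotypes). Internally alleles 1/2 map to 0/1 and each site
#' collapses to a genotype code (1/1 -> 0, 2/2 -> 1, 1/2 or 2/1 -> 2).
#' Founders have father and mother coded 0. A file with more than four
#' allele columns (more than two sites) is rejected: multi-site pedigrees
#' need parity-consistent multi-pair vertices and are out of scope.
#'
#' @param path path to the PED file.
#' @return A validated [new_pedigree()] object.
#' @export
read_pedigree <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- utils::read.table(path, header = FALSE, colClasses = "character",
                           comment.char = "#")
  if (ncol(tab) < 9) {
    stop("expected 9 columns (family id father mother sex + 4 alleles), got ",
         ncol(tab))
  }
  if (ncol(tab) > 9) {
    stop("more than two sites per member: only two-site pedigrees are ",
         "supported (multi-site phasing is future work)")
  }
  names(tab) <- c("family", "id", "father", "mother", "sex",
                  "a11", "a12", "a21", "a22")
  al <- as.matrix(tab[, c("a11", "a12", "a21", "a22")])
  if (any(al == "0")) {
    bad <- tab$id[apply(al == "0", 1, any)]
    stop("missing genotype data (allele code 0) for member(s): ",
         paste(bad, collapse = ", "),
         "; the method assumes no missing data")
  }
  if (!all(al %in% c("1", "2"))) {
    stop("alleles must be coded 1/2 (0 = missing)")
  }
  av <- matrix(as.integer(al) - 1L, ncol = 4)  # map {1,2} -> {0,1}
  members <- data.frame(
    id = tab$id,
    father = ifelse(tab$father == "0", NA_character_, tab$father),
    mother = ifelse(tab$mother == "0", NA_character_, tab$mother),
    sex = tab$sex,
    g1 = geno_code(av[, 1], av[, 2]),
    g2 = geno_code(av[, 3], av[, 4]),
    stringsAsFactors = FALSE
  )
  ped <- new_pedigree(members)
  attr(ped, "family") <- tab$family[1]
  ped
}

#' Write a pedigree as a LINKAGE/PED-style file
#'
#' Inverse of [read_pedigree()]: genotype codes expand to allele pairs coded
#' 1/2 (heterozygous sites are written 1 2). Rows are sorted by member id
#' for reproducible output.
#'
#' @param ped a [new_pedigree()] object.
#' @param path output path.
#' @param family family identifier for column 1.
#' @export
write_pedigree <- function(ped, path, family = "F1") {
  m <- ped$members[order(ped$members$id), , drop = FALSE]
  code_alleles <- function(g) {
    cbind(ifelse(g == 1L, 2L, 1L), ifelse(g == 0L, 1L, 2L))
  }
  a1 <- code_alleles(m$g1)
  a2 <- code_alleles(m$g2)
  out <- data.frame(family, m$id,
                    ifelse(is.na(m$father), "0", m$father),
                    ifelse(is.na(m$mother), "0", m$mother),
                    m$sex, a1[, 1], a1[, 2], a2[, 1], a2[, 2])
  utils::write.table(out, path, quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Write a haplotype configuration and its recombination events
#'
#' Writes a TSV of per-member ordered haplotypes (`member_id`, `h1`, `h2`)
#' plus a JSON sidecar (`<path>.json`) holding the recombination events and
#' the optimal event count `k_star`. [read_results()] round-trips the pair.
#'
#' @param config a `haplotype_config` (see [labels_to_haplotypes()]).
#' @param k_star minimum number of recombination events.
#' @param path output TSV path; the sidecar is written to `paste0(path, ".json")`.
#' @export
write_results <- function(config, k_star, path) {
  ids <- sort(names(config$phased))
  tab <- data.frame(
    member_id = ids,
    h1 = vapply(config$phased[ids], `[`, "", 1),
    h2 = vapply(config$phased[ids], `[`, "", 2),
    stringsAsFactors = FALSE
  )
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  ev <- config$events
  if (is.null(ev) || nrow(ev) == 0) {
    ev <- data.frame(child = character(0), parent = character(0))
  }
  sidecar <- list(k_star = k_star,
                  events = ev[, c("child", "parent"), drop = FALSE])
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(path)
}

#' Read back a haplotype configuration written by [write_results()]
#'
#' @param path the TSV path given to [write_results()].
#' @return list with `phased` (named list of ordered haplotype pairs),
#'   `events` (data.frame `child`, `parent`) and `k_star`.
#' @export
read_results <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           colClasses = "character")
  phased <- lapply(seq_len(nrow(tab)), function(i) c(tab$h1[i], tab$h2[i]))
  names(phased) <- tab$member_id
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  ev <- side$events
  if (is.null(ev) || length(ev) == 0 || NROW(ev) == 0) {
    ev <- data.frame(child = character(0), parent = character(0),
                     stringsAsFactors = FALSE)
  }
  list(phased = phased, events = ev, k_star = side$k_star)
}
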