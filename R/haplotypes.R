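# Internal haplotype helpers. Haplotypes are 2-character strings over {0,1}
# ("01" = allele 0 at site 1, allele 1 at site 2). Genotype codes per site:
# 0 = homozygous 0/0, 1 = homozygous 1/1, 2 = heterozygous.

hap_site <- function(h, i) substr(h, i, i)

hap_complement <- function(h) {
  chartr("01", "10", h)
}

#' @noRd
geno_code <- function(a1, a2) {
  ifelse(a1 == 0 & a2 == 0, 0L, ifelse(a1 == 1 & a2 == 1, 1L, 2L))
}

# The unordered haplotype pair compatible with a two-site genotype.
# Doubly-heterozygous members need a phase ("green" -> {00,11},
# "red" -> {01,10}); everyone else is forced.
geno_to_haps <- function(g1, g2, phase = NULL) {
  if (g1 != 2L && g2 != 2L) {
    h <- paste0(g1, g2)
    return(c(h, h))
  }
  if (g1 == 2L && g2 == 2L) {
    if (is.null(phase)) stop("doubly-heterozygous genotype needs a phase")
    if (phase == "green") return(c("00", "11")) else return(c("01", "10"))
  }
  if (g1 == 2L) {
    return(c(paste0("0", g2), paste0("1", g2)))
  }
  c(paste0(g1, "0"), paste0(g1, "1"))
}

# Alleles a parent can place on a transmitted haplotype at each site.
parent_site_alleles <- function(h1, h2, i) {
  unique(c(hap_site(h1, i), hap_site(h2, i)))
}

# Cost of transmitting haplotype `h` from a parent with haplotypes h1/h2:
# 0 if h is one of them, 1 if h is a between-site recombinant of them,
# Inf if h is not per-site compatible.
transmit_cost <- function(h, h1, h2) {
  if (h == h1 || h == h2) return(0L)
  ok1 <- hap_site(h, 1) %in% parent_site_alleles(h1, h2, 1)
  ok2 <- hap_site(h, 2) %in% parent_site_alleles(h1, h2, 2)
  if (ok1 && ok2) 1L else Inf
}
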