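# Shared fixtures, built in code.

# The five-chromosome demonstration genome: 1.0-3.0 Morgans, founder labels
# evaluated on a 5 cM grid.
demo_map <- function() genome_map(c(100, 150, 200, 250, 300),
                                  marker_spacing = 5, interval = 5)

tiny_map <- function(len = 100) genome_map(len, marker_spacing = 5, interval = 5)

make_hap <- function(ends, founder) list(ends = as.numeric(ends),
                                         founder = as.integer(founder))

# A diploid individual from explicit per-chromosome haplotypes:
# haps = list of list(h1 =, h2 =) matching map$chr_len.
make_ind <- function(map, haps, id = NA_character_) {
  structure(list(hap = haps, map = map, id = id), class = "magic_individual")
}

# Apply a random sequence of legal within-node swaps to a funnel: an
# equivalent leaf order that must canonicalize identically.
random_equivalent <- function(perm) {
  sh <- magicpop:::funnel_shape(length(perm))
  for (nd in sh$nodes) {
    if (nd$sym && stats::runif(1) < 0.5) {
      li <- nd$ls:(nd$ls + nd$ll - 1L)
      ri <- nd$rs:(nd$rs + nd$rl - 1L)
      perm[c(li, ri)] <- perm[c(ri, li)]
    }
  }
  perm
}

# Founder label of a segment haplotype at a position (half-open convention).
hap_label_at <- function(h, pos) h$founder[pmin(
  findInterval(pos, h$ends) + 1L, length(h$founder))]
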