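# Recombinant-haplotype and founder-genome metrics on constructed mosaics.

# Two-RIL toy population on one 100 cM chromosome:
#  - RIL A: founder 1 on [0,50), founder 2 on [50,100), both homologs;
#  - RIL B: homozygous founder 1 throughout.
toy_pop <- function() {
  map <- genome_map(100, marker_spacing = 5, interval = 5)
  hA <- make_hap(c(50, 100), c(1, 2))
  A <- make_ind(map, list(list(h1 = hA, h2 = hA)), "A")
  hB <- make_hap(100, 1)
  B <- make_ind(map, list(list(h1 = hB, h2 = hB)), "B")
  population_from_individuals(list(A, B), map, n_founders = 4)
}

test_that("recombinant haplotypes are scored per flanking interval", {
  rh <- recombinant_haplotypes(toy_pop())
  # RIL A switches in 1 of 20 intervals on both homologs, RIL B in none
  expect_equal(rh$prop_total, (1 / 20 + 0) / 2)
  expect_equal(rh$n_intervals, 20L)
  expect_equal(nrow(rh$events), 2L)            # one per homolog of A
  expect_equal(unique(rh$events$pos), 45)      # switch between 45 and 50
  expect_equal(unique(rh$events$from), 1L)
  expect_equal(unique(rh$events$to), 2L)
  expect_equal(unname(rh$per_pair["1_2"]), 2 / (2 * 2))
  expect_equal(sum(rh$per_pair), rh$prop_total * rh$n_intervals)
  expect_equal(rh$pairs_observed, 1L)
  # one interval shows one distinct pair, nineteen show none
  expect_equal(rh$unique_per_interval, 1 / 20)
  expect_equal(unique_rh_count(rh), rh$unique_per_interval)
})

test_that("a homozygous population has no recombinant haplotypes", {
  map <- genome_map(100, marker_spacing = 5, interval = 5)
  hB <- make_hap(100, 3)
  B <- make_ind(map, list(list(h1 = hB, h2 = hB)))
  rh <- recombinant_haplotypes(population_from_individuals(list(B), map, 4))
  expect_equal(rh$prop_total, 0)
  expect_equal(nrow(rh$events), 0L)
  expect_equal(unique_rh_count(rh), 0)
})

test_that("interval size must be a multiple of the marker spacing", {
  expect_error(recombinant_haplotypes(toy_pop(), interval = 7),
               "not a multiple")
  expect_error(recombinant_haplotypes(toy_pop(), interval = 2),
               "at least the marker spacing")
})

test_that("the ordered-pair space has n^2 - n elements", {
  expect_length(magicpop:::ordered_pair_names(8), 56L)
  expect_length(magicpop:::ordered_pair_names(4), 12L)
  rh <- recombinant_haplotypes(toy_pop())
  expect_length(rh$per_pair, 12L)
  # a biparental population with breakpoints in both orientations sees 2
  map <- genome_map(100, marker_spacing = 5, interval = 5)
  h1 <- make_hap(c(50, 100), c(1, 2))
  h2 <- make_hap(c(50, 100), c(2, 1))
  ind <- make_ind(map, list(list(h1 = h1, h2 = h2)))
  rh2 <- recombinant_haplotypes(population_from_individuals(list(ind), map, 2))
  expect_equal(rh2$pairs_observed, 2L)
  expect_lte(rh2$pairs_observed, 2^2 - 2)
})

test_that("founder proportions are exact genome fractions", {
  fp <- founder_proportions(toy_pop())
  expect_equal(unname(fp$per_ril[, 1]), c(0.5, 1))
  expect_equal(unname(fp$per_ril[, 2]), c(0.5, 0))
  expect_equal(unname(fp$mean), c(0.75, 0.25, 0, 0))
  expect_equal(fp$founder_mean, 1 / 4)
})

test_that("founder tracts count distinct founders per chromosome", {
  tr <- founder_tracts(toy_pop())
  expect_equal(unname(tr$per_ril[, 1]), c(2L, 1L))
  expect_equal(unname(tr$distribution[1, 1:2]), c(0.5, 0.5))
  expect_equal(rowSums(tr$distribution), c(chr1 = 1))
})

test_that("segment lengths average maximal single-founder runs", {
  expect_equal(segment_lengths(toy_pop()), (50 + 100) / 2)
  map <- genome_map(100, marker_spacing = 5, interval = 5)
  h <- make_hap(100, 1)
  one <- make_ind(map, list(list(h1 = h, h2 = h)))
  expect_equal(segment_lengths(population_from_individuals(list(one), map, 2)),
               100)
})

test_that("positional bins separate unique from identical haplotypes", {
  ev <- data.frame(chrom = 1, pos = c(10.2, 10.7), from = 1, to = 2)
  out <- unique_identical_bins(ev, 1)
  expect_equal(as.integer(names(out$multiplicity)), 2L)
  expect_equal(out$prop_unique, 0)
  ev2 <- data.frame(chrom = 1, pos = c(10.2, 11.7), from = 1, to = 2)
  out2 <- unique_identical_bins(ev2, 1)
  expect_equal(out2$prop_unique, 1)
  expect_equal(out2$n_distinct, 2L)
  # same bin but different ordered pair stays unique
  ev3 <- data.frame(chrom = 1, pos = c(10.2, 10.7), from = c(1, 2), to = c(2, 1))
  expect_equal(unique_identical_bins(ev3, 1)$prop_unique, 1)
  # replication makes a basic design less unique than a multi-funnel one
  map <- genome_map(c(100, 150), marker_spacing = 1, interval = 5)
  basic <- build_scheme(magic_design(8, "basic", replicates = c(1, 1, 40),
                                     selfing = c(0, 0, 2)))
  part <- build_scheme(magic_design(8, "partial_unbalanced", n_funnels = 20,
                                    replicates = c(1, 1, 2),
                                    selfing = c(0, 0, 2), seed = 2))
  u <- vapply(list(basic, part), function(ped) {
    pop <- simulate_population(ped, map, seed = 30)
    unique_identical_bins(recombinant_haplotypes(pop)$events, 1)$prop_unique
  }, numeric(1))
  expect_lt(u[1], u[2])
})

test_that("PRHR is the observed-over-true ratio", {
  expect_equal(prhr(30, 100), 0.3)
  expect_equal(prhr(7, 7), 1)
  expect_error(prhr(5, 0), "positive")
})

test_that("PRHR never increases when the marker grid coarsens", {
  map <- genome_map(c(100, 150), marker_spacing = 5, interval = 5)
  ped <- build_scheme(magic_design(8, "basic", replicates = c(1, 2, 10),
                                   selfing = c(0, 0, 3)))
  pop <- simulate_population(ped, map, seed = 17)
  truth <- nrow(breakpoints(pop))
  detected <- vapply(c(5, 10, 25, 50), function(d)
    nrow(recombinant_haplotypes(pop, interval = d)$events), numeric(1))
  ratios <- prhr(detected, truth)
  expect_true(all(diff(ratios) <= 0))
  expect_true(all(ratios <= 1 & ratios > 0))
})

test_that("founder-call matrices import and convert to events", {
  f <- file.path(tempdir(), "calls.csv")
  utils::write.csv(data.frame(chr = c(1, 1, 1, 2, 2),
                              pos_cM = c(0, 5, 10, 0, 5),
                              rilA = c(1, 1, 3, 2, 2),
                              rilB = c(4, NA, 4, 1, 2)),
                   f, row.names = FALSE)
  calls <- read_founder_calls(f)
  expect_equal(dim(calls$calls), c(5L, 2L))
  ev <- calls_to_events(calls)
  # rilA: 1->3 at chr1 pos 5; rilB: missing call bridged (no event), 1->2
  # on chr2 at pos 0
  expect_equal(nrow(ev), 2L)
  expect_equal(ev$pos[ev$ril == 1], 5)
  expect_equal(ev$from[ev$ril == 2], 1L)
  expect_equal(ev$to[ev$ril == 2], 2L)
  expect_equal(ev$chrom[ev$ril == 2], 2)
})

test_that("metrics_summary collects all statistics consistently", {
  map <- genome_map(c(100, 150), marker_spacing = 5, interval = 5)
  ped <- build_scheme(magic_design(4, "full", replicates = c(1, 5),
                                   selfing = c(0, 2)))
  pop <- simulate_population(ped, map, seed = 21)
  ms <- metrics_summary(pop)
  expect_equal(sum(ms$founder_proportions), 1)
  expect_equal(unname(rowSums(ms$tract_distribution)), c(1, 1))
  expect_equal(sum(ms$per_pair_mean_count),
               ms$total_rh_proportion * (20 + 30))
  expect_lte(ms$pairs_observed, 12)
  expect_length(ms$mean_segment_length, 2L)
})
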