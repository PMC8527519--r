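# Meiosis and population simulation under the Haldane model.

test_that("genome_map validates its inputs", {
  expect_error(genome_map(c(100, -5)), "positive")
  expect_error(genome_map(100, marker_spacing = 10, interval = 5),
               "must not exceed")
  expect_error(genome_map(100, marker_spacing = 3, interval = 5),
               "not a multiple")
  m <- genome_map(c(100, 150), marker_spacing = 1, interval = 5)
  expect_equal(m$chr_len, c(100, 150))
})

test_that("meiosis of a homozygous parent returns a single segment", {
  map <- tiny_map(c(120, 80))
  f3 <- founder_individual(map, 3)
  set.seed(1)
  g <- meiosis(f3)
  for (c in 1:2) {
    expect_equal(g[[c]]$ends, map$chr_len[c])
    expect_equal(g[[c]]$founder, 3L)
  }
})

test_that("a biparental cross is heterozygous genome-wide", {
  map <- tiny_map(100)
  set.seed(2)
  f1 <- cross_individuals(founder_individual(map, 1),
                          founder_individual(map, 2))
  expect_equal(f1$hap[[1]]$h1, list(ends = 100, founder = 1L))
  expect_equal(f1$hap[[1]]$h2, list(ends = 100, founder = 2L))
  expect_error(cross_individuals(founder_individual(map, 1),
                                 founder_individual(tiny_map(50), 2)),
               "different genome maps")
})

test_that("recombinant fractions follow the Haldane map function", {
  map <- tiny_map(100)
  set.seed(3)
  f1 <- cross_individuals(founder_individual(map, 1),
                          founder_individual(map, 2))
  n <- 20000
  at <- c(0, 5, 10, 20)
  lab <- matrix(0L, n, length(at))
  for (i in seq_len(n))
    lab[i, ] <- hap_label_at(meiosis(f1)[[1]], at)
  for (j in 2:length(at)) {
    d <- at[j]
    r <- (1 - exp(-2 * d / 100)) / 2
    r_hat <- mean(lab[, 1] != lab[, j])
    expect_lt(abs(r_hat - r), 3 * sqrt(r * (1 - r) / n))
  }
})

test_that("crossover counts are Poisson with mean equal to Morgans", {
  map <- tiny_map(200)
  set.seed(4)
  f1 <- cross_individuals(founder_individual(map, 1),
                          founder_individual(map, 2))
  # in an F1 every crossover switches the founder label, so junction count
  # equals crossover count
  n <- 4000
  k <- vapply(seq_len(n), function(i)
    length(meiosis(f1)[[1]]$founder) - 1L, integer(1))
  expect_lt(abs(mean(k) - 2), 3 * sqrt(2 / n))
  # no interference: inter-junction spacings are exponential, mean 100 cM
  long <- tiny_map(10000)
  set.seed(5)
  f1l <- cross_individuals(founder_individual(long, 1),
                           founder_individual(long, 2))
  # drop the final (right-censored) gap of every gamete
  gaps <- unlist(lapply(1:60, function(i)
    utils::head(diff(meiosis(f1l)[[1]]$ends), -1L)))
  ks <- stats::ks.test(gaps, "pexp", rate = 1 / 100)
  expect_gt(ks$p.value, 0.01)
})

test_that("selfing drives heterozygosity to zero at rate one half", {
  map <- tiny_map(100)
  het_after <- function(g, nrep = 150) {
    ped <- do.call(rbind, lapply(seq_len(nrep), function(r) {
      rows <- data.frame(id = paste0("l", r, "_", 0:g),
                         parent1 = c("F1", paste0("l", r, "_", seq_len(g) - 1)),
                         parent2 = c("F2", paste0("l", r, "_", seq_len(g) - 1)))
      rows$parent1[1] <- "F1"; rows$parent2[1] <- "F2"
      rows
    }))
    ped <- rbind(data.frame(id = c("F1", "F2"), parent1 = NA, parent2 = NA), ped)
    pop <- simulate_population(validate_pedigree(ped), map, seed = g)
    lab <- to_marker_labels(pop, spacing = 1)
    mean(lab[[1]][[1]] != lab[[1]][[2]])
  }
  h <- vapply(c(2, 6, 10), het_after, numeric(1))
  expect_true(all(diff(h) < 0))
  expect_lt(abs(h[1] - 0.25), 0.05)  # E[het] = (1/2)^g
  expect_lt(h[3], 0.01)
})

test_that("selfed biparental RILs approach two junctions per Morgan", {
  # Haldane-Waddington: junction density of a fully inbred selfed RIL is
  # R = 2r/(1+2r) summed over the map, i.e. ~2 per Morgan without
  # interference
  map <- tiny_map(200)
  nrep <- 200
  ped <- rbind(
    data.frame(id = c("F1", "F2"), parent1 = NA, parent2 = NA),
    do.call(rbind, lapply(seq_len(nrep), function(r) {
      ids <- paste0("l", r, "_", 0:18)
      data.frame(id = ids,
                 parent1 = c("F1", ids[-19]),
                 parent2 = c("F2", ids[-19]))
    })))
  pop <- simulate_population(validate_pedigree(ped), map, seed = 8)
  bp <- breakpoints(pop)
  density <- nrow(bp) / (2 * pop$n_ind) / 2  # per homolog per Morgan
  expect_lt(abs(density - 2), 0.2)
})

test_that("population simulation is deterministic and conservative", {
  map <- tiny_map(c(100, 150))
  ped <- build_scheme(magic_design(4, "full", replicates = c(1, 3),
                                   selfing = c(0, 2)))
  pop1 <- simulate_population(ped, map, seed = 42)
  pop2 <- simulate_population(ped, map, seed = 42)
  expect_identical(pop1$geno, pop2$geno)
  expect_false(identical(simulate_population(ped, map, seed = 43)$geno,
                         pop1$geno))
  expect_equal(pop1$n_ind, count_rils(ped))
  # founder proportions tile the genome exactly
  fp <- founder_proportions(pop1)
  expect_equal(unname(rowSums(fp$per_ril)), rep(1, pop1$n_ind))
  expect_equal(fp$founder_mean, 0.25)
  # all labels come from the founder set
  expect_true(all(unlist(lapply(pop1$geno, function(ch)
    lapply(ch, `[[`, "founder"))) %in% 1:4))
})

test_that("marker grids can hide but never create breakpoints", {
  map <- genome_map(120, marker_spacing = 1, interval = 5)
  ped <- build_scheme(magic_design(8, "basic", replicates = c(1, 1, 10),
                                   selfing = c(0, 0, 2)))
  pop <- simulate_population(ped, map, seed = 9)
  lab <- to_marker_labels(pop)[[1]]
  bp <- breakpoints(pop)
  for (h in 1:2) {
    switches <- rowSums(lab[[h]][, -1, drop = FALSE] !=
                          lab[[h]][, -ncol(lab[[h]]), drop = FALSE])
    true_bp <- tabulate(bp$ril[bp$homolog == h], pop$n_ind)
    expect_true(all(switches <= true_bp))
  }
})

test_that("marker labels follow the half-open segment convention", {
  map <- genome_map(100, marker_spacing = 5, interval = 5)
  h <- list(h1 = make_hap(c(50, 100), c(1, 2)),
            h2 = make_hap(100, 3))
  ind <- make_ind(map, list(h))
  lab <- to_marker_labels(ind, map)
  expect_equal(lab[[1]][1, ], rep(c(1L, 2L), c(10, 11)))  # switch at 50
  expect_equal(lab[[1]][2, ], rep(3L, 21))
})

test_that("population export writes labels and a manifest", {
  map <- genome_map(50, marker_spacing = 10, interval = 10)
  ped <- build_scheme(magic_design(4, "basic", replicates = c(1, 2),
                                   selfing = c(0, 1)))
  pop <- simulate_population(ped, map, seed = 10)
  f <- file.path(tempdir(), "pop.csv")
  write_population(pop, f)
  m <- utils::read.csv(f, row.names = 1)
  expect_equal(dim(m), c(2 * pop$n_ind, 6))
  manifest <- jsonlite::read_json(sub("csv$", "json", f))
  expect_equal(manifest$n_ind, pop$n_ind)
})
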