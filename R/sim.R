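# Meiosis, crossing and population simulation through a pedigree.
#
# Recombination model: per chromosome the crossover count is Poisson with
# mean L/100 (L in cM, i.e. the length in Morgans), crossover positions are
# independent uniform, the starting homolog is a fair coin and the homolog
# alternates at each crossover -- no interference and no obligate chiasma,
# the process implied by the Haldane map function.  Founder genomes are
# tracked as segment lists in cM (0-based, half-open), which is exact and
# equivalent to tracking fully informative markers.

#' Genome map for simulation
#'
#' @param chr_len Positive genetic chromosome lengths in cM.
#' @param marker_spacing Distance between evenly spaced markers in cM;
#'   markers sit at 0, d, 2d, ... up to the chromosome length.
#' @param interval Recombinant-haplotype interval size in cM: the distance
#'   between the two markers whose founder labels are compared when scoring
#'   recombinant haplotypes.  Must be a multiple of `marker_spacing`.
#' @return A `genome_map` object.
#' @examples
#' genome_map(c(100, 150, 200, 250, 300), marker_spacing = 1, interval = 5)
#' @export
genome_map <- function(chr_len, marker_spacing = 1, interval = 5) {
  chr_len <- as.numeric(chr_len)
  if (length(chr_len) < 1L || anyNA(chr_len) || any(chr_len <= 0))
    stop("`chr_len` must be positive chromosome lengths in cM")
  if (marker_spacing <= 0 || interval <= 0)
    stop("`marker_spacing` and `interval` must be positive")
  if (marker_spacing > interval)
    stop("`marker_spacing` must not exceed `interval`")
  ratio <- interval / marker_spacing
  if (abs(ratio - round(ratio)) > 1e-8)
    stop("`interval` (", interval, " cM) is not a multiple of ",
         "`marker_spacing` (", marker_spacing, " cM); choose an exact ",
         "multiple rather than relying on silent rounding")
  structure(list(chr_len = chr_len, marker_spacing = marker_spacing,
                 interval = interval),
            class = "genome_map")
}

#' @export
print.genome_map <- function(x, ...) {
  cat(sprintf(
    "Genome map: %d chromosome(s) of %s cM; markers every %g cM; %g cM RH interval\n",
    length(x$chr_len), paste(x$chr_len, collapse = "/"), x$marker_spacing,
    x$interval))
  invisible(x)
}

new_individual <- function(hap, map, id = NA_character_) {
  structure(list(hap = hap, map = map, id = id), class = "magic_individual")
}

#' Founder individual
#'
#' A fully inbred founder: homozygous for its own label on every chromosome.
#'
#' @param map A [genome_map()].
#' @param founder Founder label (positive integer).
#' @return A `magic_individual` (two segment haplotypes per chromosome).
#' @export
founder_individual <- function(map, founder) {
  founder <- as.integer(founder)
  hap <- lapply(map$chr_len, function(L) {
    h <- list(ends = L, founder = founder)
    list(h1 = h, h2 = h)
  })
  new_individual(hap, map, paste0("F", founder))
}

#' Meiosis: one recombined gamete
#'
#' Draws one meiotic product from a diploid individual under the Haldane
#' model (Poisson crossovers, no interference).  Uses the current RNG
#' stream; wrap in `set.seed()` for reproducibility.
#'
#' @param ind A `magic_individual`.
#' @param map Genome map; defaults to the individual's own.
#' @return A segment haplotype: per chromosome a list with `ends`
#'   (segment right endpoints in cM, last equals the chromosome length) and
#'   `founder` (founder label per segment), in merged canonical form.
#' @export
meiosis <- function(ind, map = ind$map) {
  stopifnot(inherits(ind, "magic_individual"))
  lapply(seq_along(map$chr_len), function(c)
    gamete_cpp(ind$hap[[c]]$h1, ind$hap[[c]]$h2, map$chr_len[c]))
}

#' Cross two individuals (or self one)
#'
#' The offspring receives one independent meiotic gamete from each parent;
#' selfing draws two independent gametes from the same parent.
#'
#' @param p1,p2 `magic_individual` parents sharing the same genome map.
#' @param id Optional offspring id.
#' @return A `magic_individual`.
#' @export
cross_individuals <- function(p1, p2, id = NA_character_) {
  if (!identical(p1$map, p2$map))
    stop("cannot cross individuals with different genome maps")
  g1 <- meiosis(p1)
  g2 <- meiosis(p2)
  hap <- lapply(seq_along(p1$map$chr_len), function(c)
    list(h1 = g1[[c]], h2 = g2[[c]]))
  new_individual(hap, p1$map, id)
}

#' @rdname cross_individuals
#' @param p A `magic_individual` to self.
#' @export
self_individual <- function(p, id = NA_character_) {
  cross_individuals(p, p, id)
}

#' Simulate a population through a pedigree
#'
#' Executes the pedigree rows in order: founders are assigned fixed
#' homozygous labels 1..n in order of appearance (all founders are unique),
#' every cross/self row receives one independent gamete per parent.
#' Deterministic given the seed.
#'
#' @param ped A validated `magic_pedigree` (see [build_scheme()]).
#' @param map A [genome_map()].
#' @param seed Optional integer seed.
#' @return A `magic_population` holding the terminal individuals (the final
#'   RILs) as founder-labelled segment haplotypes.
#' @examples
#' ped <- build_scheme(basic_design(4, replicates = c(1, 1), selfing = c(0, 2)))
#' pop <- simulate_population(ped, genome_map(100), seed = 1)
#' founder_proportions(pop)$mean
#' @export
simulate_population <- function(ped, map, seed = NULL) {
  stopifnot(inherits(map, "genome_map"))
  if (!inherits(ped, "magic_pedigree")) ped <- validate_pedigree(ped)
  p1 <- match(ped$parent1, ped$id)
  p2 <- match(ped$parent2, ped$id)
  is_founder <- is.na(ped$parent1)
  if (any(is.na(p1) & !is_founder))
    stop("pedigree references an unsimulated parent")
  p1[is_founder] <- 0L
  p2[is_founder] <- 0L
  founder <- integer(nrow(ped))
  founder[is_founder] <- seq_len(sum(is_founder))
  terminal <- which(!(ped$id %in% c(ped$parent1, ped$parent2)))
  geno <- with_seed(seed, sim_pedigree_cpp(p1, p2, founder,
                                           map$chr_len, terminal))
  structure(list(map = map,
                 n_founders = sum(is_founder),
                 ids = ped$id[terminal],
                 n_ind = length(terminal),
                 geno = geno),
            class = "magic_population")
}

#' Assemble a population from explicit segment haplotypes
#'
#' Mainly for testing and for importing externally derived founder mosaics:
#' builds the compact population container from a list of individuals.
#'
#' @param individuals List of `magic_individual` objects sharing `map`.
#' @param map A [genome_map()].
#' @param n_founders Number of founders the labels refer to.
#' @return A `magic_population`.
#' @export
population_from_individuals <- function(individuals, map, n_founders) {
  stopifnot(length(individuals) >= 1L)
  geno <- lapply(seq_along(map$chr_len), function(c) {
    lapply(c(h1 = "h1", h2 = "h2"), function(h) {
      haps <- lapply(individuals, function(ind) ind$hap[[c]][[h]])
      list(ends = unlist(lapply(haps, `[[`, "ends")),
           founder = as.integer(unlist(lapply(haps, `[[`, "founder"))),
           offsets = c(0L, cumsum(vapply(haps, function(x)
             length(x$ends), integer(1)))))
    })
  })
  ids <- vapply(individuals, function(i)
    if (is.null(i$id)) NA_character_ else i$id, character(1))
  structure(list(map = map, n_founders = as.integer(n_founders),
                 ids = ids, n_ind = length(individuals), geno = geno),
            class = "magic_population")
}

#' Extract one individual from a population
#'
#' @param pop A `magic_population`.
#' @param i Individual index.
#' @return A `magic_individual`.
#' @export
get_individual <- function(pop, i) {
  stopifnot(i >= 1L, i <= pop$n_ind)
  hap <- lapply(pop$geno, function(chr) {
    lapply(chr, function(h) {
      idx <- (h$offsets[i] + 1L):h$offsets[i + 1L]
      list(ends = h$ends[idx], founder = h$founder[idx])
    })
  })
  hap <- lapply(hap, function(chr) list(h1 = chr[[1]], h2 = chr[[2]]))
  new_individual(hap, pop$map, pop$ids[i])
}

#' @export
print.magic_population <- function(x, ...) {
  cat(sprintf("MAGIC population: %d RILs, %d founders, %d chromosome(s)\n",
              x$n_ind, x$n_founders, length(x$map$chr_len)))
  invisible(x)
}

marker_positions <- function(map, spacing = map$marker_spacing) {
  lapply(map$chr_len, function(L) seq(0, L, by = spacing))
}

#' Founder labels on the marker grid
#'
#' Labels each evenly spaced marker with the founder of the segment
#' containing it (half-open convention: a marker at a breakpoint takes the
#' right-hand segment).
#'
#' @param x A `magic_population` or `magic_individual`.
#' @param map Genome map (defaults to the object's own).
#' @param spacing Marker spacing in cM, default `map$marker_spacing`.
#' @return For a population: per chromosome, a list of two
#'   individuals-by-markers integer matrices (one per homolog).  For an
#'   individual: per chromosome, a 2 x markers matrix.
#' @export
to_marker_labels <- function(x, map = x$map, spacing = map$marker_spacing) {
  pos <- marker_positions(map, spacing)
  if (inherits(x, "magic_population")) {
    lapply(seq_along(pos), function(c)
      stats::setNames(lapply(x$geno[[c]], function(h)
        marker_labels_cpp(h$ends, h$founder, h$offsets, pos[[c]])),
        c("h1", "h2")))
  } else if (inherits(x, "magic_individual")) {
    lapply(seq_along(pos), function(c) {
      rbind(
        marker_labels_cpp(x$hap[[c]]$h1$ends, x$hap[[c]]$h1$founder,
                          c(0L, length(x$hap[[c]]$h1$ends)), pos[[c]]),
        marker_labels_cpp(x$hap[[c]]$h2$ends, x$hap[[c]]$h2$founder,
                          c(0L, length(x$hap[[c]]$h2$ends)), pos[[c]]))
    })
  } else stop("`x` must be a magic_population or magic_individual")
}

#' Export a population's marker labels as CSV
#'
#' One row per RIL and homolog, one column per marker (`chr:pos`), plus a
#' JSON manifest (map, founder count, ids) alongside.
#'
#' @param pop A `magic_population`.
#' @param file Output CSV path.
#' @export
write_population <- function(pop, file) {
  lab <- to_marker_labels(pop)
  pos <- marker_positions(pop$map)
  mat <- do.call(cbind, lapply(seq_along(lab), function(c) {
    out <- matrix(0L, 2L * pop$n_ind, ncol(lab[[c]]$h1))
    out[seq(1L, 2L * pop$n_ind, 2L), ] <- lab[[c]]$h1
    out[seq(2L, 2L * pop$n_ind, 2L), ] <- lab[[c]]$h2
    out
  }))
  rows <- paste0(rep(pop$ids, each = 2L), "_h", rep(1:2, pop$n_ind))
  cols <- unlist(lapply(seq_along(pos), function(c)
    paste0("chr", c, ":", pos[[c]])))
  dimnames(mat) <- list(rows, cols)
  utils::write.csv(mat, file)
  manifest <- sub("\\.csv$", ".json", file)
  jsonlite::write_json(list(n_founders = pop$n_founders,
                            n_ind = pop$n_ind,
                            chr_len = pop$map$chr_len,
                            marker_spacing = pop$map$marker_spacing),
                       manifest, auto_unbox = TRUE, digits = NA)
  invisible(file)
}
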