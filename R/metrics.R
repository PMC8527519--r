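# Design-quality metrics: recombinant haplotypes and founder-genome summaries.

ordered_pair_names <- function(n) {
  p <- expand.grid(to = seq_len(n), from = seq_len(n))
  p <- p[p$from != p$to, c("from", "to")]
  paste(p$from, p$to, sep = "_")
}

#' Score recombinant haplotypes in a population
#'
#' Evaluates founder labels at consecutive grid markers spaced `interval`
#' cM apart on both homologs of every RIL.  Where the two flanking labels
#' differ, the ordered founder pair (left label, right label) is recorded as
#' a recombinant haplotype; with n founders there are n^2 - n possible
#' ordered pairs (56 for eight founders).
#'
#' @param pop A `magic_population`.
#' @param interval Interval size in cM (default: the genome map's);
#'   must be at least, and an exact multiple of, the marker spacing.
#' @return A `magic_rh` list:
#'   * `prop_total`: fraction of evaluated intervals containing a founder
#'     switch, averaged over homologs and RILs;
#'   * `unique_per_interval`: mean (over intervals) number of distinct
#'     ordered pairs observed in an interval across the population -- the
#'     design-comparison "unique recombinant haplotypes" statistic;
#'   * `pairs_observed`: distinct ordered pairs seen anywhere;
#'   * `per_pair`: mean count per RIL of each ordered pair (homolog
#'     average);
#'   * `events`: data frame of all events (chrom, pos of the interval
#'     start, ril, homolog, from, to);
#'   * `n_intervals`: evaluated intervals genome-wide.
#' @export
recombinant_haplotypes <- function(pop, interval = pop$map$interval) {
  stopifnot(inherits(pop, "magic_population"))
  map <- pop$map
  if (interval < map$marker_spacing)
    stop("`interval` must be at least the marker spacing")
  ratio <- interval / map$marker_spacing
  if (abs(ratio - round(ratio)) > 1e-8)
    stop("`interval` (", interval, ") is not a multiple of the marker ",
         "spacing (", map$marker_spacing, "); refusing to round silently")
  n <- pop$n_founders
  nind <- pop$n_ind
  ev_chrom <- ev_pos <- ev_ril <- ev_hom <- ev_from <- ev_to <- list()
  n_int <- 0L
  n_sw <- c(h1 = 0, h2 = 0)
  uniq_sum <- 0L
  for (c in seq_along(map$chr_len)) {
    pos <- seq(0, map$chr_len[c], by = interval)
    m <- length(pos)
    if (m < 2L) next
    lab <- lapply(pop$geno[[c]], function(h)
      marker_labels_cpp(h$ends, h$founder, h$offsets, pos))
    n_int <- n_int + (m - 1L)
    pair_sets <- vector("list", m - 1L)
    for (h in 1:2) {
      L <- lab[[h]]
      sw <- L[, -m, drop = FALSE] != L[, -1L, drop = FALSE]
      n_sw[h] <- n_sw[h] + sum(sw)
      idx <- which(sw, arr.ind = TRUE)
      if (nrow(idx)) {
        from <- L[cbind(idx[, 1L], idx[, 2L])]
        to <- L[cbind(idx[, 1L], idx[, 2L] + 1L)]
        k <- length(ev_chrom) + 1L
        ev_chrom[[k]] <- rep.int(c, nrow(idx))
        ev_pos[[k]] <- pos[idx[, 2L]]
        ev_ril[[k]] <- idx[, 1L]
        ev_hom[[k]] <- rep.int(h, nrow(idx))
        ev_from[[k]] <- from
        ev_to[[k]] <- to
        code <- (from - 1L) * n + to
        sp <- split(code, idx[, 2L])
        for (j in names(sp)) {
          ji <- as.integer(j)
          pair_sets[[ji]] <- c(pair_sets[[ji]], unique(sp[[j]]))
        }
      }
    }
    uniq_sum <- uniq_sum + sum(vapply(pair_sets, function(s)
      length(unique(s)), integer(1)))
  }
  events <- data.frame(chrom = unlist(ev_chrom), pos = unlist(ev_pos),
                       ril = unlist(ev_ril), homolog = unlist(ev_hom),
                       from = unlist(ev_from), to = unlist(ev_to))
  if (nrow(events)) events <- events[order(events$chrom, events$pos), ]
  pair_lab <- ordered_pair_names(n)
  counts <- table(factor(paste(events$from, events$to, sep = "_"),
                         levels = pair_lab))
  per_pair <- as.numeric(counts) / (2 * nind)
  names(per_pair) <- pair_lab
  structure(list(
    n_founders = n, n_ind = nind, interval = interval,
    n_intervals = n_int,
    prop_total = mean(n_sw / (n_int * nind)),
    unique_per_interval = uniq_sum / n_int,
    pairs_observed = length(unique(paste(events$from, events$to))),
    per_pair = per_pair,
    events = events), class = "magic_rh")
}

#' @export
print.magic_rh <- function(x, ...) {
  cat(sprintf(paste0(
    "Recombinant haplotypes (%g cM intervals): proportion %.4f, ",
    "%.2f unique pairs per interval, %d/%d pairs observed\n"),
    x$interval, x$prop_total, x$unique_per_interval, x$pairs_observed,
    x$n_founders^2 - x$n_founders))
  invisible(x)
}

#' Unique recombinant haplotype statistic
#'
#' The number of distinct ordered founder pairs observed per evaluation
#' interval across the population, averaged over intervals.  Bounded by
#' n^2 - n; it measures how evenly a design spreads recombination over
#' founder pairs at every genomic position, rather than merely whether each
#' pair occurs somewhere.
#'
#' @param x A `magic_rh` result or a `magic_population`.
#' @param ... Passed to [recombinant_haplotypes()] when `x` is a population.
#' @return A single number.
#' @export
unique_rh_count <- function(x, ...) {
  if (inherits(x, "magic_population")) x <- recombinant_haplotypes(x, ...)
  stopifnot(inherits(x, "magic_rh"))
  x$unique_per_interval
}

segment_widths <- function(h) {
  ends <- h$ends
  prev <- c(0, ends[-length(ends)])
  starts <- h$offsets[-length(h$offsets)] + 1L
  prev[starts] <- 0
  ends - prev
}

#' Founder-genome proportions
#'
#' Genome-length-weighted fraction of each founder's genome in every RIL
#' (averaged over the two homologs), with the population mean per founder.
#' The mean over founders is exactly 1/n because the segments tile the
#' genome.
#'
#' @param pop A `magic_population`.
#' @return List with `per_ril` (RILs x founders matrix), `mean` (per
#'   founder) and `founder_mean` (mean over founders, 1/n).
#' @export
founder_proportions <- function(pop) {
  n <- pop$n_founders
  nind <- pop$n_ind
  acc <- matrix(0, nind, n)
  for (c in seq_along(pop$map$chr_len)) {
    for (h in pop$geno[[c]]) {
      w <- segment_widths(h)
      ind <- rep.int(seq_len(nind), diff(h$offsets))
      code <- ind + (h$founder - 1L) * nind
      s <- rowsum(w, group = code)
      acc[as.integer(rownames(s))] <- acc[as.integer(rownames(s))] + s
    }
  }
  per_ril <- acc / (2 * sum(pop$map$chr_len))
  rownames(per_ril) <- pop$ids
  colnames(per_ril) <- paste0("founder", seq_len(n))
  m <- colMeans(per_ril)
  list(per_ril = per_ril, mean = m, founder_mean = mean(m))
}

#' Founder tracts per chromosome
#'
#' For every RIL and chromosome, the number of distinct founder genomes
#' present (union over the two homologs), and the population distribution
#' over 1..n distinct founders.
#'
#' @param pop A `magic_population`.
#' @return List with `per_ril` (RILs x chromosomes matrix of distinct
#'   founder counts) and `distribution` (chromosomes x n matrix of
#'   proportions of RILs, rows summing to 1).
#' @export
founder_tracts <- function(pop) {
  n <- pop$n_founders
  nind <- pop$n_ind
  nc <- length(pop$map$chr_len)
  per_ril <- matrix(0L, nind, nc)
  distr <- matrix(0, nc, n, dimnames = list(paste0("chr", seq_len(nc)),
                                            paste0("k", seq_len(n))))
  for (c in seq_len(nc)) {
    ind <- unlist(lapply(pop$geno[[c]], function(h)
      rep.int(seq_len(nind), diff(h$offsets))))
    fdr <- unlist(lapply(pop$geno[[c]], `[[`, "founder"))
    seen <- !duplicated(cbind(ind, fdr))
    k <- tabulate(ind[seen], nind)
    per_ril[, c] <- k
    distr[c, ] <- tabulate(k, n) / nind
  }
  list(per_ril = per_ril, distribution = distr)
}

#' Mean nonrecombinant segment length per chromosome
#'
#' Mean length in cM of maximal single-founder segments per RIL chromosome
#' (merged form), averaged over homologs and RILs.
#'
#' @param pop A `magic_population`.
#' @return Numeric vector, one mean per chromosome.
#' @export
segment_lengths <- function(pop) {
  vapply(seq_along(pop$map$chr_len), function(c) {
    L <- pop$map$chr_len[c]
    mean(unlist(lapply(pop$geno[[c]], function(h) L / diff(h$offsets))))
  }, numeric(1))
}

#' Unique vs identical recombinant haplotypes in positional bins
#'
#' Recombinant haplotypes of the same ordered founder pair are considered
#' identical when they fall in the same nonoverlapping positional bin
#' (anchored at position 0 of each chromosome), otherwise unique.
#' Identical haplotypes arise from replicated cross progeny.
#'
#' @param events Data frame with columns `chrom`, `pos`, `from`, `to`
#'   (e.g. the `events` element of [recombinant_haplotypes()]).
#' @param bin_width Bin width in cM (typically 1 or 10).
#' @return List with `multiplicity` (table: how many (chromosome, bin,
#'   pair) keys occur 1x, 2x, ...), `prop_unique` (fraction of events that
#'   are unique), `n_events` and `n_distinct`.
#' @export
unique_identical_bins <- function(events, bin_width) {
  stopifnot(bin_width > 0,
            all(c("chrom", "pos", "from", "to") %in% names(events)))
  if (nrow(events) == 0L)
    return(list(multiplicity = table(integer(0)), prop_unique = NaN,
                n_events = 0L, n_distinct = 0L))
  key <- paste(events$chrom, floor(events$pos / bin_width),
               events$from, events$to)
  mult <- table(key)
  list(multiplicity = table(as.integer(mult)),
       prop_unique = sum(mult == 1L) / nrow(events),
       n_events = nrow(events),
       n_distinct = length(mult))
}

#' Proportion of recombinant haplotypes recovered (PRHR)
#'
#' The number of recombinant haplotypes observed in a dataset divided by
#' the number present in the corresponding simulated (true) dataset.
#'
#' @param observed_count Observed recombinant haplotype count.
#' @param true_count True (simulated) count; must be positive.
#' @return `observed_count / true_count`.
#' @examples
#' prhr(30, 100)  # 0.3
#' @export
prhr <- function(observed_count, true_count) {
  if (any(true_count <= 0))
    stop("undefined ratio: `true_count` must be positive")
  observed_count / true_count
}

#' Exact founder junctions of a population
#'
#' All segment boundaries (true breakpoints, independent of any marker
#' grid) with their flanking ordered founder pairs.
#'
#' @param pop A `magic_population`.
#' @return Data frame with columns `chrom`, `pos`, `ril`, `homolog`,
#'   `from`, `to`.
#' @export
breakpoints <- function(pop) {
  out <- list()
  for (c in seq_along(pop$map$chr_len)) {
    for (h in 1:2) {
      g <- pop$geno[[c]][[h]]
      nseg <- diff(g$offsets)
      last <- cumsum(nseg)
      keep <- rep.int(TRUE, length(g$ends))
      keep[last] <- FALSE  # the final segment end is the chromosome end
      if (!any(keep)) next
      out[[length(out) + 1L]] <- data.frame(
        chrom = c, pos = g$ends[keep],
        ril = rep.int(seq_len(pop$n_ind), nseg - 1L),
        homolog = h, from = g$founder[keep],
        to = g$founder[which(keep) + 1L])
    }
  }
  if (length(out) == 0L)
    return(data.frame(chrom = integer(0), pos = numeric(0),
                      ril = integer(0), homolog = integer(0),
                      from = integer(0), to = integer(0)))
  do.call(rbind, out)
}

#' Import and score a founder-call matrix
#'
#' Reads founder genotype calls for a RIL population: a CSV with columns
#' `chr`, `pos_cM`, then one column per RIL holding founder labels
#' (integers; `NA` for missing calls).  `calls_to_events()` extracts the
#' recombinant haplotypes: for every RIL, consecutive non-missing markers
#' on a chromosome whose labels differ yield an event at the left marker's
#' position.
#'
#' @param file Path to the CSV file.
#' @return `read_founder_calls`: list with `chr`, `pos` and `calls`
#'   (markers x RILs integer matrix).
#' @export
read_founder_calls <- function(file) {
  df <- utils::read.csv(file, check.names = FALSE)
  if (!all(c("chr", "pos_cM") %in% names(df)))
    stop("founder-call CSV needs `chr` and `pos_cM` columns")
  ord <- order(df$chr, df$pos_cM)
  df <- df[ord, ]
  calls <- as.matrix(df[, setdiff(names(df), c("chr", "pos_cM")),
                        drop = FALSE])
  storage.mode(calls) <- "integer"
  list(chr = df$chr, pos = df$pos_cM, calls = calls)
}

#' @rdname read_founder_calls
#' @param calls A list as returned by `read_founder_calls`.
#' @return `calls_to_events`: data frame with columns `chrom`, `pos`,
#'   `ril`, `from`, `to`, usable with [unique_identical_bins()].
#' @export
calls_to_events <- function(calls) {
  out <- list()
  for (ch in unique(calls$chr)) {
    sel <- which(calls$chr == ch)
    pos <- calls$pos[sel]
    m <- calls$calls[sel, , drop = FALSE]
    for (r in seq_len(ncol(m))) {
      obs <- which(!is.na(m[, r]))
      if (length(obs) < 2L) next
      lab <- m[obs, r]
      sw <- which(lab[-1L] != lab[-length(lab)])
      if (length(sw))
        out[[length(out) + 1L]] <- data.frame(
          chrom = ch, pos = pos[obs[sw]], ril = r,
          from = lab[sw], to = lab[sw + 1L])
    }
  }
  if (length(out) == 0L)
    return(data.frame(chrom = integer(0), pos = numeric(0), ril = integer(0),
                      from = integer(0), to = integer(0)))
  do.call(rbind, out)
}

#' Per-iteration metrics summary
#'
#' Computes all design-quality statistics for one simulated population.
#'
#' @param pop A `magic_population`.
#' @param interval Recombinant-haplotype interval in cM (default: map's).
#' @return A `magic_metrics` list: `total_rh_proportion`,
#'   `unique_rh_count`, `per_pair_mean_count`, `founder_proportions`,
#'   `tract_distribution`, `mean_segment_length`.
#' @export
metrics_summary <- function(pop, interval = pop$map$interval) {
  rh <- recombinant_haplotypes(pop, interval)
  fp <- founder_proportions(pop)
  tr <- founder_tracts(pop)
  structure(list(
    total_rh_proportion = rh$prop_total,
    unique_rh_count = rh$unique_per_interval,
    pairs_observed = rh$pairs_observed,
    per_pair_mean_count = rh$per_pair,
    founder_proportions = fp$mean,
    tract_distribution = tr$distribution,
    mean_segment_length = segment_lengths(pop)), class = "magic_metrics")
}
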