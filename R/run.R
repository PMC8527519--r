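# Configuration-driven orchestration: run and compare designs.

#' Build a run configuration
#'
#' @param designs Named list of designs: [magic_design()] objects,
#'   `magic_pedigree` tables, or paths to pedigree files.
#' @param map A [genome_map()] shared by all designs in the run.
#' @param iterations Number of simulation iterations per design.
#' @param seed Master seed; per-iteration substreams are derived from it so
#'   results do not depend on execution order.
#' @param outdir Optional output directory for per-iteration CSV and
#'   aggregated JSON results.
#' @return A `magic_config`.
#' @export
magic_config <- function(designs, map, iterations = 100, seed = NULL,
                         outdir = NULL) {
  if (inherits(designs, "magic_design")) designs <- list(designs)
  if (is.null(names(designs)) || any(names(designs) == ""))
    names(designs) <- paste0("design", seq_along(designs))
  structure(list(designs = designs, map = map,
                 iterations = as.integer(iterations), seed = seed,
                 outdir = outdir),
            class = "magic_config")
}

#' Read a run configuration from YAML
#'
#' Schema (version 1): top-level `version`, `seed`, `iterations`,
#' optional `output`, a `map` block (`chr_len`, `marker_spacing`,
#' `interval`) and a `designs` list whose entries either describe a design
#' (`name`, `type`, `n_founders`, `replicates`, `selfing`, and type-specific
#' fields `n_funnels` / `n_funnel_sets` / `funnels` / `additional_cross` /
#' `n_ril`) or point to a pedigree file (`name`, `pedigree`).
#'
#' @param file Path to a YAML file.
#' @return A `magic_config`.
#' @export
read_config <- function(file) {
  y <- yaml::read_yaml(file)
  if (is.null(y$version) || y$version != 1)
    stop("config must declare `version: 1`")
  if (is.null(y$map)) stop("config must have a `map` block")
  map <- genome_map(unlist(y$map$chr_len),
                    marker_spacing = y$map$marker_spacing %||% 1,
                    interval = y$map$interval %||% 5)
  if (is.null(y$designs) || length(y$designs) == 0L)
    stop("config must list at least one design")
  designs <- lapply(y$designs, function(d) {
    if (!is.null(d$pedigree)) return(d$pedigree)
    magic_design(n_founders = d$n_founders,
                 type = d$type %||% "basic",
                 n_funnels = d$n_funnels,
                 n_funnel_sets = d$n_funnel_sets,
                 funnels = if (!is.null(d$funnels))
                   do.call(rbind, lapply(d$funnels, parse_funnel)),
                 replicates = unlist(d$replicates),
                 selfing = unlist(d$selfing),
                 additional_cross = isTRUE(d$additional_cross),
                 n_ril = d$n_ril,
                 seed = y$seed)
  })
  names(designs) <- vapply(seq_along(y$designs), function(i)
    y$designs[[i]]$name %||% paste0("design", i), character(1))
  magic_config(designs, map, iterations = y$iterations %||% 100,
               seed = y$seed, outdir = y$output)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Validate a run configuration
#'
#' Collects every problem (schema errors, invalid designs, unreadable
#' pedigrees) instead of stopping at the first; an empty result means the
#' configuration is runnable.
#'
#' @param config A `magic_config`.
#' @return Character vector of diagnostics (zero-length when valid).
#' @export
validate_config <- function(config) {
  diag <- character(0)
  note <- function(...) diag <<- c(diag, paste0(...))
  if (!inherits(config, "magic_config")) {
    return("not a magic_config object")
  }
  if (!inherits(config$map, "genome_map")) note("`map` is not a genome_map")
  if (is.na(config$iterations) || config$iterations < 1L)
    note("`iterations` must be at least 1")
  if (length(config$designs) == 0L) note("no designs configured")
  for (i in seq_along(config$designs)) {
    d <- config$designs[[i]]
    nm <- names(config$designs)[i]
    res <- tryCatch({
      resolve_pedigree(d, seed = config$seed)
      NULL
    }, error = function(e) conditionMessage(e))
    if (!is.null(res)) note("design '", nm, "' (index ", i, "): ", res)
  }
  diag
}

resolve_pedigree <- function(d, seed = NULL) {
  if (inherits(d, "magic_pedigree")) return(d)
  if (inherits(d, "magic_design")) return(build_scheme(d, seed = seed))
  if (is.character(d) && length(d) == 1L) {
    if (!file.exists(d)) stop("pedigree file not found: ", d)
    return(read_pedigree(d))
  }
  stop("a design must be a magic_design, a magic_pedigree, or a file path")
}

#' Run and compare designs
#'
#' For every design and iteration: simulate a population through the
#' expanded pedigree and score it; then aggregate means and variances per
#' design.  Fully deterministic given the configuration seed.  All designs
#' are validated before any simulation starts.
#'
#' @param config A `magic_config`.
#' @return A `magic_report`: `per_iteration` (data frame: one row per
#'   design x iteration with the scalar metrics, founder proportions and
#'   per-chromosome mean segment lengths), `aggregate` (mean and variance
#'   of every metric per design), `per_pair` (designs x ordered-pairs
#'   matrix of mean per-RIL counts), `tracts` (per design, chromosomes x k
#'   mean tract distribution), and `cross_counts` per design.  When the
#'   config has an output directory, writes `metrics_per_iteration.csv`,
#'   `metrics_aggregate.json` and one pedigree TSV per design there.
#' @export
run_comparison <- function(config) {
  stopifnot(inherits(config, "magic_config"))
  diag <- validate_config(config)
  if (length(diag))
    stop("invalid configuration:\n", paste("-", diag, collapse = "\n"))
  nd <- length(config$designs)
  ni <- config$iterations
  seeds <- matrix(iteration_seeds(config$seed, nd * (ni + 1L)), nrow = nd)
  rows <- list()
  per_pair <- NULL
  tracts <- list()
  ccs <- list()
  peds <- list()
  for (i in seq_len(nd)) {
    nm <- names(config$designs)[i]
    ped <- resolve_pedigree(config$designs[[i]], seed = seeds[i, 1L])
    peds[[nm]] <- ped
    ccs[[nm]] <- cross_counts(ped)
    tr_acc <- NULL
    pp_acc <- NULL
    for (it in seq_len(ni)) {
      pop <- simulate_population(ped, config$map, seed = seeds[i, it + 1L])
      ms <- metrics_summary(pop)
      rows[[length(rows) + 1L]] <- data.frame(
        design = nm, iteration = it,
        total_rh_prop = ms$total_rh_proportion,
        unique_rh = ms$unique_rh_count,
        pairs_observed = ms$pairs_observed,
        t(stats::setNames(ms$founder_proportions,
                          paste0("fp_", seq_along(ms$founder_proportions)))),
        t(stats::setNames(ms$mean_segment_length,
                          paste0("seglen_chr", seq_along(ms$mean_segment_length)))),
        check.names = FALSE)
      tr_acc <- if (is.null(tr_acc)) ms$tract_distribution
                else tr_acc + ms$tract_distribution
      pp_acc <- if (is.null(pp_acc)) ms$per_pair_mean_count
                else pp_acc + ms$per_pair_mean_count
    }
    tracts[[nm]] <- tr_acc / ni
    per_pair <- rbind(per_pair, pp_acc / ni)
  }
  rownames(per_pair) <- names(config$designs)
  per_iteration <- do.call(rbind, rows)
  metric_cols <- setdiff(names(per_iteration), c("design", "iteration"))
  agg <- do.call(rbind, lapply(split(per_iteration, per_iteration$design),
                               function(df) {
    data.frame(design = df$design[1L], metric = metric_cols,
               mean = vapply(metric_cols, function(cn) mean(df[[cn]]), numeric(1)),
               var = vapply(metric_cols, function(cn) stats::var(df[[cn]]), numeric(1)),
               row.names = NULL)
  }))
  agg <- agg[order(match(agg$design, names(config$designs))), ]
  rownames(agg) <- NULL
  report <- structure(list(per_iteration = per_iteration, aggregate = agg,
                           per_pair = per_pair, tracts = tracts,
                           cross_counts = ccs, pedigrees = peds,
                           config = config),
                      class = "magic_report")
  if (!is.null(config$outdir)) write_report(report, config$outdir)
  report
}

write_report <- function(report, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$per_iteration,
                   file.path(outdir, "metrics_per_iteration.csv"),
                   row.names = FALSE)
  agg <- split(report$aggregate[, c("metric", "mean", "var")],
               report$aggregate$design)
  jsonlite::write_json(
    lapply(agg, function(df)
      stats::setNames(lapply(seq_len(nrow(df)), function(r)
        list(mean = df$mean[r], var = df$var[r])), df$metric)),
    file.path(outdir, "metrics_aggregate.json"),
    auto_unbox = TRUE, digits = NA)
  for (nm in names(report$pedigrees))
    write_pedigree(report$pedigrees[[nm]],
                   file.path(outdir, paste0("pedigree_", nm, ".tsv")))
  invisible(outdir)
}

#' @export
print.magic_report <- function(x, ...) {
  cat(sprintf("MAGIC design comparison: %d design(s), %d iteration(s)\n",
              length(x$config$designs), x$config$iterations))
  key <- x$aggregate[x$aggregate$metric %in% c("total_rh_prop", "unique_rh"), ]
  print(key, row.names = FALSE)
  invisible(x)
}
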