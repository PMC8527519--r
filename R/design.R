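# Design specifications: founders + funnels + replicate/selfing schedule.

#' Create a MAGIC design specification
#'
#' Bundles the inputs that define a MAGIC crossing design: the number of
#' founders, the funnel set (constructed according to the design type), and
#' the replicate/selfing schedule per crossing generation.
#'
#' @param n_founders Number of founders, an integer between 3 and 128.
#' @param type Design type: `"full"` (all distinct funnels),
#'   `"partial_balanced"` (`n_funnel_sets` minimal balanced funnel sets),
#'   `"partial_unbalanced"` (`n_funnels` funnels drawn at random),
#'   `"basic"` (the single funnel in founder order), or `"custom"`
#'   (funnels supplied in `funnels`).
#' @param n_funnels Number of funnels for a partial unbalanced design.
#' @param n_funnel_sets Number of minimal balanced sets for a partial
#'   balanced design.
#' @param funnels Funnel matrix (one funnel per row) for a custom design.
#' @param replicates Positive integer vector, one entry per crossing
#'   generation (plus one for the additional crossing generation when
#'   enabled): how many seeds from each cross are retained.  Default: one
#'   seed everywhere.
#' @param selfing Non-negative integer vector of the same length: how many
#'   generations of selfing (single-seed descent) follow each crossing
#'   generation.  Default: no selfing except four generations after the
#'   final cross, the usual route to near-inbred RILs.
#' @param additional_cross If `TRUE`, one extra generation of random
#'   intercrosses among the progeny of the final funnel crosses is appended
#'   (its replicate/selfing entries are the last elements of `replicates`
#'   and `selfing`).
#' @param n_ril Target number of final RILs; required when
#'   `additional_cross = TRUE`, where it determines the number of extra
#'   crosses (`round(n_ril / last replicate)`).
#' @param seed Optional integer seed used when funnels are drawn at random
#'   (balanced-set sampling, unbalanced sampling).
#' @return An object of class `magic_design`.
#' @examples
#' magic_design(8, "basic", replicates = c(1, 1, 3))
#' @export
magic_design <- function(n_founders,
                         type = c("full", "partial_balanced",
                                  "partial_unbalanced", "basic", "custom"),
                         n_funnels = NULL, n_funnel_sets = NULL,
                         funnels = NULL, replicates = NULL, selfing = NULL,
                         additional_cross = FALSE, n_ril = NULL, seed = NULL) {
  type <- match.arg(type)
  n <- as.integer(n_founders)
  if (length(n) != 1L || is.na(n) || n < 3L || n > 128L)
    stop("`n_founders` must be an integer between 3 and 128")
  ngen <- as.integer(ceiling(log2(n))) + as.integer(additional_cross)
  if (is.null(replicates)) replicates <- rep(1L, ngen)
  if (is.null(selfing)) selfing <- c(rep(0L, ngen - 1L), 4L)
  replicates <- as.integer(replicates)
  selfing <- as.integer(selfing)
  if (length(replicates) != ngen || length(selfing) != ngen)
    stop("`replicates` and `selfing` must have one entry per crossing ",
         "generation: ", ngen, " for ", n, " founders",
         if (additional_cross) " (including the additional crossing generation)")
  if (anyNA(replicates) || any(replicates < 1L))
    stop("`replicates` must be positive integers")
  if (anyNA(selfing) || any(selfing < 0L))
    stop("`selfing` must be non-negative integers")
  if (additional_cross) {
    if (is.null(n_ril))
      stop("`n_ril` (target RIL count) is required when additional_cross = TRUE")
    n_ril <- as.integer(n_ril)
    if (n_ril < 1L) stop("`n_ril` must be positive")
  }

  funnels <- switch(type,
    full = {
      if (n > 10L)
        stop("a full design is only enumerable for n <= 10; got n = ", n)
      enumerate_full_funnels(n)
    },
    partial_balanced = {
      if (is.null(n_funnel_sets)) n_funnel_sets <- 1L
      find_balanced_sets(n, n_funnel_sets, seed = seed)
    },
    partial_unbalanced = {
      if (is.null(n_funnels))
        stop("`n_funnels` is required for a partial unbalanced design")
      sample_unbalanced(n, n_funnels, seed = seed)
    },
    basic = matrix(seq_len(n), 1L),
    custom = {
      if (is.null(funnels))
        stop("`funnels` is required for a custom design")
      m <- as_funnel_matrix(funnels)
      if (ncol(m) != n)
        stop("custom funnels have ", ncol(m), " founders, expected ", n)
      canonicalize_rows(m)
    })
  if (anyDuplicated(funnels))
    stop("funnels in a design must be distinct")

  structure(list(n_founders = n,
                 design_type = type,
                 funnels = funnels,
                 replicates = replicates,
                 selfing = selfing,
                 additional_cross = isTRUE(additional_cross),
                 n_ril = if (additional_cross) n_ril else NA_integer_,
                 n_funnel_sets = if (type == "partial_balanced")
                   as.integer(n_funnel_sets) else NA_integer_),
            class = "magic_design")
}

#' Basic design: a single funnel in founder order
#'
#' @param n Number of founders (at least 3).
#' @param ... Passed on to [magic_design()] (replicates, selfing, ...).
#' @return A `magic_design` with one funnel `1 2 ... n`.
#' @examples
#' basic_design(8)
#' @export
basic_design <- function(n, ...) {
  magic_design(n, type = "basic", ...)
}

#' @export
print.magic_design <- function(x, ...) {
  cat(sprintf("MAGIC design: %d founders, %s type, %d funnel%s\n",
              x$n_founders, x$design_type, nrow(x$funnels),
              if (nrow(x$funnels) == 1L) "" else "s"))
  cat("  replicates:", paste(x$replicates, collapse = ", "), "\n")
  cat("  selfing:   ", paste(x$selfing, collapse = ", "), "\n")
  if (x$additional_cross)
    cat("  additional crossing generation, target RILs:", x$n_ril, "\n")
  if (nrow(x$funnels) <= 8L)
    cat("  funnels:", paste(apply(x$funnels, 1L, format_funnel),
                            collapse = " "), "\n")
  invisible(x)
}
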