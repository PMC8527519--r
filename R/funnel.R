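# Funnel combinatorics: canonical crossing trees, enumeration, balance.

# Crossing-tree shape shared by all funnels with n founders: founders occupy
# leaf positions 1..n; at each generation consecutive lineages are crossed
# pairwise and, when the lineage count is odd, the last lineage advances
# unchanged.  Two leaf orders describe the same crossing scheme iff one can be
# turned into the other by swapping the two children of nodes whose subtrees
# have the same shape, so every equivalence class has exactly 2^s members,
# where s is the number of shape-symmetric internal nodes.
funnel_shape <- function(n) {
  n <- as.integer(n)
  stopifnot(n >= 2)
  # lineages: start position, length, shape signature
  lin <- data.frame(start = seq_len(n), len = 1L, sig = "x",
                    stringsAsFactors = FALSE)
  nodes <- list()
  gen <- 0L
  while (nrow(lin) > 1L) {
    gen <- gen + 1L
    m <- nrow(lin)
    keep <- NULL
    if (m %% 2L == 1L) {
      keep <- lin[m, , drop = FALSE]
      lin <- lin[-m, , drop = FALSE]
      m <- m - 1L
    }
    nxt <- vector("list", m / 2L)
    for (k in seq_len(m / 2L)) {
      a <- lin[2L * k - 1L, ]
      b <- lin[2L * k, ]
      nodes[[length(nodes) + 1L]] <- list(
        gen = gen,
        ls = a$start, ll = a$len, rs = b$start, rl = b$len,
        sym = identical(a$sig, b$sig))
      nxt[[k]] <- data.frame(start = a$start, len = a$len + b$len,
                             sig = paste0("(", a$sig, b$sig, ")"),
                             stringsAsFactors = FALSE)
    }
    lin <- do.call(rbind, c(nxt, if (!is.null(keep)) list(keep)))
  }
  list(n = n,
       n_generations = gen,
       nodes = nodes,
       n_symmetric = sum(vapply(nodes, `[[`, logical(1), "sym")))
}

#' Number of distinct funnels in a full design
#'
#' A funnel is a complete crossing tree over `n` founders; leaf orders that
#' differ only by swapping the two parents of any cross describe the same
#' funnel.  For a power-of-two number of founders every class has
#' `2^(n-1)` members, giving `n!/2^(n-1)` distinct funnels; for other `n`
#' the class size is `2^s` with `s` the number of shape-symmetric nodes of
#' the crossing tree (an unpaired lineage advances unchanged), giving
#' `n!/2^s`.
#'
#' @param n Number of founders (an integer, at least 2).
#' @return Number of distinct funnels (equivalence classes of crossing
#'   schemes).  Exact for `n <= 18`; beyond that the value exceeds the range
#'   of exact double-precision integers.
#' @examples
#' count_full_funnels(4)  # 3
#' count_full_funnels(8)  # 315
#' @export
count_full_funnels <- function(n) {
  n <- as.integer(n)
  if (length(n) != 1L || is.na(n) || n < 2L)
    stop("`n` must be a single integer >= 2")
  sh <- funnel_shape(n)
  factorial(n) / 2^sh$n_symmetric
}

is_perm <- function(x, n) {
  length(x) == n && !anyNA(x) && all(sort(as.integer(x)) == seq_len(n))
}

# Canonicalize many leaf orders at once (rows of a matrix): bottom-up over the
# shape's symmetric nodes, put the child block with the smaller minimum
# founder first.
canonicalize_rows <- function(m, shape = funnel_shape(ncol(m))) {
  storage.mode(m) <- "integer"
  for (nd in shape$nodes) {
    if (!nd$sym) next
    li <- nd$ls:(nd$ls + nd$ll - 1L)
    ri <- nd$rs:(nd$rs + nd$rl - 1L)
    lmin <- do.call(pmin, lapply(li, function(j) m[, j]))
    rmin <- do.call(pmin, lapply(ri, function(j) m[, j]))
    swap <- lmin > rmin
    if (any(swap)) m[swap, c(li, ri)] <- m[swap, c(ri, li), drop = FALSE]
  }
  m
}

#' Canonical representative of a funnel
#'
#' Maps a founder permutation to the canonical leaf order of its equivalence
#' class: at every crossing-tree node whose two subtrees have the same shape,
#' the subtree containing the smaller founder index comes first.  All
#' equivalent leaf orders map to the same output, e.g. `2143 -> 1234` for
#' four founders.
#'
#' @param perm Integer vector: a permutation of `1..n` giving the leaf order
#'   of the crossing tree (for eight founders, positions 1-2, 3-4, 5-6, 7-8
#'   are the two-way crosses, and so on).
#' @return Integer vector of the same length, the canonical leaf order.
#' @examples
#' canonical_funnel(c(2, 1, 4, 3))  # 1 2 3 4
#' @export
canonical_funnel <- function(perm) {
  n <- length(perm)
  if (!is_perm(perm, n))
    stop("`perm` must be a permutation of 1..n (repeated or missing founders)")
  drop(canonicalize_rows(matrix(as.integer(perm), 1L)))
}

all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  out <- vector("list", n)
  for (k in seq_len(n)) {
    m <- sub
    m[m >= k] <- m[m >= k] + 1L
    out[[k]] <- cbind(rep.int(k, nrow(m)), m, deparse.level = 0)
  }
  do.call(rbind, out)
}

#' Enumerate all distinct funnels of a full design
#'
#' @param n Number of founders; explicit enumeration is supported for
#'   `n <= 10` (a full 16-founder design has about 6.4e8 funnels and is
#'   impractical by the paper's own account; use [sample_unbalanced()] to
#'   draw funnels for large `n`).
#' @return Integer matrix with one canonical funnel per row, in
#'   lexicographic order; `nrow` equals [count_full_funnels()].
#' @examples
#' enumerate_full_funnels(4)
#' @export
enumerate_full_funnels <- function(n) {
  n <- as.integer(n)
  if (n < 2L || n > 10L)
    stop("explicit funnel enumeration is supported for 2 <= n <= 10; ",
         "got n = ", n)
  key <- as.character(n)
  cached <- .magicpop_cache$full[[key]]
  if (!is.null(cached)) return(cached)
  m <- unique(canonicalize_rows(all_permutations(n)))
  m <- m[do.call(order, lapply(seq_len(ncol(m)), function(j) m[, j])), ,
         drop = FALSE]
  dimnames(m) <- NULL
  .magicpop_cache$full[[key]] <- m
  m
}

.magicpop_cache <- new.env(parent = emptyenv())
.magicpop_cache$full <- list()

as_funnel_matrix <- function(funnels) {
  if (is.matrix(funnels)) {
    m <- funnels
  } else if (is.list(funnels)) {
    len <- lengths(funnels)
    if (length(unique(len)) != 1L)
      stop("mixed founder counts across funnels")
    m <- do.call(rbind, funnels)
  } else if (is.numeric(funnels)) {
    m <- matrix(as.integer(funnels), 1L)
  } else stop("`funnels` must be a matrix, list of vectors, or single vector")
  storage.mode(m) <- "integer"
  n <- ncol(m)
  ok <- apply(m, 1L, is_perm, n = n)
  if (!all(ok))
    stop("funnel(s) ", paste(which(!ok), collapse = ", "),
         " are not permutations of 1..", n)
  m
}

#' Founder-pair co-occurrence profile of a funnel set
#'
#' For each crossing generation, counts how often every unordered founder
#' pair is brought together: pairs within a two-way cross at generation 1
#' and, at later generations, all founder pairs spanning the two merged
#' subtrees.
#'
#' @param funnels A funnel set: integer matrix with one funnel per row (or a
#'   list of funnel vectors), all over the same founders.
#' @return A matrix with one row per founder pair (named `"i:j"`) and one
#'   column per crossing generation, containing co-occurrence counts, with
#'   attribute `founder_counts` (appearances of each founder across
#'   funnels).
#' @examples
#' balance_profile(rbind(c(1,2,3,4), c(1,3,2,4), c(1,4,2,3)))
#' @export
balance_profile <- function(funnels) {
  m <- as_funnel_matrix(funnels)
  n <- ncol(m)
  sh <- funnel_shape(n)
  ngen <- sh$n_generations
  pairs <- t(utils::combn(n, 2L))
  pid <- matrix(0L, n, n)
  pid[pairs] <- seq_len(nrow(pairs))
  pid <- pid + t(pid)
  counts <- matrix(0L, nrow(pairs), ngen,
                   dimnames = list(paste(pairs[, 1L], pairs[, 2L], sep = ":"),
                                   paste0("gen", seq_len(ngen))))
  for (nd in sh$nodes) {
    li <- nd$ls:(nd$ls + nd$ll - 1L)
    ri <- nd$rs:(nd$rs + nd$rl - 1L)
    for (r in seq_len(nrow(m))) {
      ids <- pid[cbind(rep(m[r, li], each = length(ri)),
                       rep(m[r, ri], times = length(li)))]
      tab <- tabulate(ids, nrow(pairs))
      counts[, nd$gen] <- counts[, nd$gen] + tab
    }
  }
  structure(counts,
            founder_counts = tabulate(m, n),
            class = c("balance_profile", class(counts)))
}

#' @export
print.balance_profile <- function(x, ...) {
  cat("Founder-pair co-occurrence counts by crossing generation\n")
  print(unclass(structure(x, founder_counts = NULL)), ...)
  invisible(x)
}

#' Is a funnel set balanced?
#'
#' A balanced design has an equal number of appearances of every founder
#' across the funnels and an equal co-occurrence frequency of every founder
#' pair at each crossing generation.
#'
#' @inheritParams balance_profile
#' @return `TRUE` or `FALSE`.
#' @examples
#' is_balanced(rbind(c(1,2,3,4), c(1,3,2,4), c(1,4,2,3)))  # TRUE
#' is_balanced(matrix(1:4, 1))                              # FALSE
#' @export
is_balanced <- function(funnels) {
  bp <- balance_profile(funnels)
  fc <- attr(bp, "founder_counts")
  length(unique(fc)) == 1L &&
    all(apply(unclass(bp), 2L, function(col) length(unique(col)) == 1L))
}

balance_imbalance <- function(funnels) {
  bp <- unclass(balance_profile(funnels))
  sum(apply(bp, 2L, function(col) sum((col - mean(col))^2)))
}

#' Enumerate all minimal balanced funnel sets for eight founders
#'
#' Exhaustive constrained backtracking over unordered sets of seven canonical
#' eight-founder funnels: the seven two-way levels must form a
#' 1-factorization of the complete graph on the eight founders (every pair
#' exactly once) and every pair must occur exactly twice at the four-way
#' level; each pair then occurs four times at the eight-way level
#' automatically, since every founder pair meets exactly once per funnel.
#'
#' @param n Number of founders; only `n = 8` admits this exhaustive search.
#' @return A list of funnel sets, each a 7 x 8 integer matrix of canonical
#'   funnels (rows sorted lexicographically); 720 sets for eight founders.
#' @export
enumerate_balanced_sets <- function(n = 8) {
  if (n != 8L)
    stop("exhaustive balanced-set enumeration is implemented for n = 8 only; ",
         "use find_balanced_sets() for other founder numbers")
  if (!is.null(.magicpop_cache$balanced8)) return(.magicpop_cache$balanced8)
  funnels <- enumerate_full_funnels(8L)
  idx <- balanced_sets8_cpp(funnels)
  sets <- lapply(seq_len(nrow(idx)), function(s) {
    m <- funnels[sort(idx[s, ]), , drop = FALSE]
    dimnames(m) <- NULL
    m
  })
  .magicpop_cache$balanced8 <- sets
  sets
}

#' Minimal balanced funnel-set size
#'
#' The smallest number of funnels that can carry an exactly balanced design:
#' at every crossing generation the pairs contributed per funnel times the
#' number of funnels must be divisible by the number of founder pairs.
#'
#' @param n Number of founders.
#' @return Integer, the minimal funnel count per balanced set.
#' @export
balanced_set_size <- function(n) {
  n <- as.integer(n)
  sh <- funnel_shape(n)
  npair <- n * (n - 1L) / 2L
  per_gen <- integer(sh$n_generations)
  for (nd in sh$nodes)
    per_gen[nd$gen] <- per_gen[nd$gen] + nd$ll * nd$rl
  f <- vapply(per_gen, function(p) npair / gcd_int(p, npair), numeric(1))
  as.integer(Reduce(lcm_int, f))
}

gcd_int <- function(a, b) if (b == 0) a else gcd_int(b, a %% b)
lcm_int <- function(a, b) a / gcd_int(a, b) * b

#' Construct a balanced funnel set
#'
#' For eight founders, samples from the 720 exhaustively enumerated minimal
#' balanced sets; multiple sets are combined from funnel-disjoint minimal
#' sets.  For four founders the unique balanced set is the full design.  For
#' other founder numbers a seeded simulated-annealing search over funnel
#' replacements and within-funnel founder swaps minimizes the sum of squared
#' deviations of the pair-count profile; only an exactly balanced result is
#' accepted.
#'
#' @param n Number of founders (4 to 16).
#' @param n_sets Number of minimal balanced sets to combine.
#' @param seed Optional integer seed making the construction reproducible.
#' @param max_iter Annealing iterations for founder numbers without an
#'   exhaustive enumeration.
#' @return Integer matrix of `n_sets * balanced_set_size(n)` funnels (one
#'   per row) forming a balanced design.
#' @export
find_balanced_sets <- function(n, n_sets = 1, seed = NULL, max_iter = 40000) {
  n <- as.integer(n)
  n_sets <- as.integer(n_sets)
  if (n < 4L || n > 16L)
    stop("balanced designs are supported for 4 to 16 founders")
  if (n_sets < 1L) stop("`n_sets` must be at least 1")
  size <- balanced_set_size(n)
  total <- n_sets * size
  nfull <- count_full_funnels(n)
  if (total > nfull)
    stop("infeasible: ", n_sets, " balanced set(s) of ", size,
         " funnels exceed the ", nfull, " distinct funnels for ", n,
         " founders (funnels in a design must be distinct)")
  with_seed(seed, {
    if (n == 8L) {
      sets <- enumerate_balanced_sets(8L)
      keys <- lapply(sets, function(m) apply(m, 1L, paste, collapse = "."))
      chosen <- sample.int(length(sets), 1L)
      used <- keys[[chosen]]
      out <- sets[[chosen]]
      while (nrow(out) < total) {
        free <- which(vapply(keys, function(k) !any(k %in% used), logical(1)))
        if (length(free) == 0L)
          stop("could not combine ", n_sets,
               " funnel-disjoint balanced sets for 8 founders")
        nxt <- free[sample.int(length(free), 1L)]
        out <- rbind(out, sets[[nxt]])
        used <- c(used, keys[[nxt]])
      }
      return(out)
    }
    if (n == 4L) {
      out <- enumerate_full_funnels(4L)  # the unique minimal balanced set
      if (n_sets > 1L)
        stop("infeasible: only one balanced set (the full design) exists ",
             "for 4 founders")
      return(out)
    }
    anneal_balanced(n, total, max_iter)
  })
}

# Seeded simulated annealing toward an exactly balanced funnel set.
anneal_balanced <- function(n, total, max_iter) {
  sh <- funnel_shape(n)
  rand_funnel <- function() drop(canonicalize_rows(matrix(sample.int(n), 1L), sh))
  cur <- matrix(0L, total, n)
  repeat {
    for (i in seq_len(total)) cur[i, ] <- rand_funnel()
    if (!anyDuplicated(cur)) break
  }
  cost <- balance_imbalance(cur)
  temp <- max(cost, 1)
  cool <- exp(log(0.01 / temp) / max_iter)
  for (it in seq_len(max_iter)) {
    if (cost == 0) break
    cand <- cur
    i <- sample.int(total, 1L)
    if (stats::runif(1) < 0.5) {
      cand[i, ] <- rand_funnel()
    } else {
      pos <- sample.int(n, 2L)
      cand[i, pos] <- cand[i, rev(pos)]
      cand[i, ] <- drop(canonicalize_rows(cand[i, , drop = FALSE], sh))
    }
    if (anyDuplicated(cand)) next
    newcost <- balance_imbalance(cand)
    if (newcost <= cost || stats::runif(1) < exp((cost - newcost) / temp)) {
      cur <- cand
      cost <- newcost
    }
    temp <- temp * cool
  }
  if (cost != 0)
    stop("balanced-set search did not reach exact balance for n = ", n,
         " with ", total, " funnels (residual imbalance ", cost,
         "); no exactly balanced set may exist for this request, or more ",
         "iterations are needed")
  cur
}

#' Sample distinct funnels uniformly at random
#'
#' Draws `n_funnels` distinct canonical funnels uniformly from all
#' equivalence classes (a partial unbalanced design; one funnel is a basic
#' design).  Uniformity holds for every `n` because all classes have equal
#' size.
#'
#' @param n Number of founders.
#' @param n_funnels Number of distinct funnels to draw.
#' @param seed Optional integer seed.
#' @return Integer matrix of `n_funnels` canonical funnels (one per row).
#' @export
sample_unbalanced <- function(n, n_funnels, seed = NULL) {
  n <- as.integer(n)
  n_funnels <- as.integer(n_funnels)
  nfull <- count_full_funnels(n)
  if (n_funnels < 1L || n_funnels > nfull)
    stop("`n_funnels` must be between 1 and ", nfull, " for ", n, " founders")
  with_seed(seed, {
    if (n <= 10L) {
      all <- enumerate_full_funnels(n)
      all[sort(sample.int(nrow(all), n_funnels)), , drop = FALSE]
    } else {
      sh <- funnel_shape(n)
      seen <- character(0)
      out <- matrix(0L, n_funnels, n)
      k <- 0L
      while (k < n_funnels) {
        f <- drop(canonicalize_rows(matrix(sample.int(n), 1L), sh))
        key <- paste(f, collapse = ".")
        if (key %in% seen) next
        k <- k + 1L
        seen <- c(seen, key)
        out[k, ] <- f
      }
      out
    }
  })
}

#' Read and write funnel notation
#'
#' Funnels are written as founder indices separated by whitespace or
#' hyphens; for at most nine founders a compact digit string such as
#' `"1234"` (meaning `((1x2)x(3x4))`) is also accepted.
#'
#' @param x A character string (`parse_funnel`) or funnel vector
#'   (`format_funnel`).
#' @return `parse_funnel`: an integer leaf-order vector; `format_funnel`: a
#'   string that `parse_funnel` round-trips.
#' @export
parse_funnel <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  x <- gsub("[()x×]", " ", x)
  if (grepl("[-[:space:]]", trimws(x))) {
    out <- as.integer(strsplit(trimws(x), "[-[:space:]]+")[[1]])
  } else {
    out <- as.integer(strsplit(trimws(x), "")[[1]])
  }
  if (!is_perm(out, length(out)))
    stop("not a valid funnel string: ", x)
  out
}

#' @rdname parse_funnel
#' @export
format_funnel <- function(x) {
  if (length(x) <= 9L) paste(x, collapse = "") else paste(x, collapse = "-")
}
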