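# Pedigree expansion and validation: from a design to explicit cross/self rows.

generation_labels <- function(n, ngen) {
  if (is_power_of_two(n)) paste0(2^seq_len(ngen), "way")
  else paste0("cross", seq_len(ngen))
}

#' Expand a design into an explicit crossing scheme
#'
#' Produces the full pedigree from founders to final RILs.  Crosses are
#' deduplicated within each generation (funnels sharing a two-way cross
#' reuse it); `r` replicates at a generation mean `r` seeds retained per
#' cross, each an independent meiosis; `s` selfing generations append `s`
#' chained single-seed-descent rows per seed; the additional crossing
#' generation randomly pairs the progeny of the final funnel crosses
#' (avoiding, where possible, pairs from the same cross), making
#' `round(n_ril / last replicate)` extra crosses.
#'
#' @param design A [magic_design()] object.
#' @param seed Optional integer seed; only the random pairing of the
#'   additional crossing generation draws random numbers.
#' @return A `magic_pedigree`: a data frame with columns `id`, `parent1`,
#'   `parent2`, `generation`, `type` (founder/cross/self), topologically
#'   ordered.
#' @examples
#' ped <- build_scheme(basic_design(4, replicates = c(1, 1), selfing = c(0, 0)))
#' cross_counts(ped)
#' @export
build_scheme <- function(design, seed = NULL) {
  stopifnot(inherits(design, "magic_design"))
  n <- design$n_founders
  funnels <- design$funnels
  sh <- funnel_shape(n)
  ngen_funnel <- sh$n_generations
  ngen_total <- ngen_funnel + as.integer(design$additional_cross)
  if (length(design$replicates) != ngen_total ||
      length(design$selfing) != ngen_total)
    stop("replicate/selfing schedule length mismatch: expected ", ngen_total,
         " entries for ", n, " founders",
         if (design$additional_cross) " (including the additional cross)")
  glab <- generation_labels(n, ngen_funnel)

  id <- parent1 <- parent2 <- generation <- type <- character(0)
  add_row <- function(i, p1, p2, g, t) {
    id[[length(id) + 1L]] <<- i
    parent1[[length(parent1) + 1L]] <<- p1
    parent2[[length(parent2) + 1L]] <<- p2
    generation[[length(generation) + 1L]] <<- g
    type[[length(type) + 1L]] <<- t
  }
  founder_ids <- paste0("F", seq_len(n))
  for (f in seq_len(n)) add_row(founder_ids[f], NA_character_, NA_character_,
                                "founder", "founder")

  avail <- new.env(parent = emptyenv())
  for (f in seq_len(n)) assign(as.character(f), founder_ids[f], envir = avail)

  with_seed(seed, {
    final_pool <- character(0)
    for (g in seq_len(ngen_funnel)) {
      r_g <- design$replicates[g]
      s_g <- design$selfing[g]
      nodes_g <- Filter(function(nd) nd$gen == g, sh$nodes)
      # unique cross shapes at this generation, identified by the canonical
      # leaf string of the merged subtree
      shape_tab <- list()
      for (nd in nodes_g) {
        li <- nd$ls:(nd$ls + nd$ll - 1L)
        ri <- nd$rs:(nd$rs + nd$rl - 1L)
        for (r in seq_len(nrow(funnels))) {
          v <- funnels[r, ]
          key <- paste(v[c(li, ri)], collapse = ".")
          if (is.null(shape_tab[[key]]))
            shape_tab[[key]] <- list(kL = paste(v[li], collapse = "."),
                                     kR = paste(v[ri], collapse = "."),
                                     leaves = v[c(li, ri)])
        }
      }
      ord <- order(vapply(shape_tab, function(s)
        paste(sprintf("%03d", s$leaves), collapse = ""), character(1)))
      shape_tab <- shape_tab[ord]
      keys <- names(shape_tab)
      for (si in seq_along(shape_tab)) {
        s <- shape_tab[[si]]
        pl <- get(s$kL, envir = avail)
        pr <- get(s$kR, envir = avail)
        ncross <- max(length(pl), length(pr))
        terminals <- character(0)
        for (i in seq_len(ncross)) {
          pa <- pl[1L + (i - 1L) %% length(pl)]
          pb <- pr[1L + (i - 1L) %% length(pr)]
          base <- sprintf("%s_%03d_%02d", glab[g], si, i)
          for (j in seq_len(r_g)) {
            pid <- paste0(base, "_p", j)
            add_row(pid, pa, pb, glab[g], "cross")
            cur <- pid
            for (k in seq_len(s_g)) {
              sid <- paste0(pid, "_s", k)
              add_row(sid, cur, cur, paste0(glab[g], ".self", k), "self")
              cur <- sid
            }
            terminals <- c(terminals, cur)
          }
        }
        assign(keys[si], terminals, envir = avail)
        if (g == ngen_funnel) final_pool <- c(final_pool, terminals)
      }
    }

    if (design$additional_cross) {
      r_ax <- design$replicates[ngen_funnel + 1L]
      s_ax <- design$selfing[ngen_funnel + 1L]
      n_extra <- max(1L, as.integer(round(design$n_ril / r_ax)))
      pool <- final_pool
      if (length(pool) < 2L)
        stop("additional crossing needs at least two final-funnel individuals")
      parent_key <- paste(parent1, parent2)[match(pool, id)]
      np <- length(pool)
      # distinct parent pairs, excluding pairs of seeds from the same cross
      # (unless nothing else is available)
      cmb <- utils::combn(np, 2L)
      allowed <- cmb[, parent_key[cmb[1L, ]] != parent_key[cmb[2L, ]],
                     drop = FALSE]
      if (ncol(allowed) == 0L) allowed <- cmb
      if (n_extra > ncol(allowed))
        stop("additional crossing: ", n_extra, " crosses requested but only ",
             ncol(allowed), " distinct parent pairs are available")
      pair_index <- matrix(0L, np, np)
      pair_index[t(allowed)] <- seq_len(ncol(allowed))
      used <- rep(FALSE, ncol(allowed))
      sel <- integer(0)
      stall <- 0L
      # shuffled pairing rounds keep per-individual usage balanced
      while (length(sel) < n_extra && stall < 50L) {
        p <- sample.int(np)
        a <- p[seq(1L, np - 1L, by = 2L)]
        b <- p[seq(2L, np, by = 2L)]
        ids <- pair_index[cbind(pmin(a, b), pmax(a, b))]
        ids <- ids[ids > 0L]
        ids <- ids[!used[ids]]
        if (length(ids)) {
          used[ids] <- TRUE
          sel <- c(sel, ids)
          stall <- 0L
        } else stall <- stall + 1L
      }
      if (length(sel) < n_extra) {
        rem <- which(!used)
        sel <- c(sel, rem[sample.int(length(rem), n_extra - length(sel))])
      }
      sel <- sel[seq_len(n_extra)]
      pairs_a <- pool[allowed[1L, sel]]
      pairs_b <- pool[allowed[2L, sel]]
      for (i in seq_len(n_extra)) {
        base <- sprintf("addx_%03d", i)
        for (j in seq_len(r_ax)) {
          pid <- paste0(base, "_p", j)
          add_row(pid, pairs_a[i], pairs_b[i], "addx", "cross")
          cur <- pid
          for (k in seq_len(s_ax)) {
            sid <- paste0(pid, "_s", k)
            add_row(sid, cur, cur, paste0("addx.self", k), "self")
            cur <- sid
          }
        }
      }
    }
  })

  ped <- data.frame(id = id, parent1 = parent1, parent2 = parent2,
                    generation = generation, type = type,
                    stringsAsFactors = FALSE)
  class(ped) <- c("magic_pedigree", "data.frame")
  attr(ped, "n_founders") <- n
  ped
}

#' Cross counts per generation
#'
#' Counts distinct crosses (unique parent pairs among cross-type rows) by
#' generation; selfing rows are excluded.
#'
#' @param ped A `magic_pedigree` (see [build_scheme()] or
#'   [read_pedigree()]).
#' @return List with `per_generation` (named integer vector in pedigree
#'   order) and `total`.
#' @export
cross_counts <- function(ped) {
  cr <- ped[ped$type == "cross", , drop = FALSE]
  if (nrow(cr) == 0L)
    return(list(per_generation = integer(0), total = 0L))
  key <- paste(pmin(cr$parent1, cr$parent2), pmax(cr$parent1, cr$parent2))
  gen <- factor(cr$generation, levels = unique(cr$generation))
  per <- vapply(split(key, gen), function(k) length(unique(k)), integer(1))
  list(per_generation = per, total = sum(per))
}

#' Number of final RILs in a pedigree
#'
#' Terminal individuals (rows that are nobody's parent) after all selfing.
#'
#' @inheritParams cross_counts
#' @return Integer count.
#' @export
count_rils <- function(ped) {
  sum(!(ped$id %in% c(ped$parent1, ped$parent2)))
}

#' Validate a pedigree table
#'
#' Checks that ids are unique, every parent is defined on an earlier row
#' (so the table is topologically ordered and acyclic), founders have no
#' parents, and no row is its own parent.  Missing `generation`/`type`
#' columns are inferred (`self` when both parents coincide).
#'
#' @param ped Data frame with columns `id`, `parent1`, `parent2` and
#'   optionally `generation`, `type`.  Blank, `"0"` or `NA` parents denote
#'   founders.
#' @return The normalized `magic_pedigree`, invisibly usable downstream.
#' @export
validate_pedigree <- function(ped) {
  ped <- as.data.frame(ped, stringsAsFactors = FALSE)
  need <- c("id", "parent1", "parent2")
  if (!all(need %in% names(ped)))
    stop("pedigree must have columns id, parent1, parent2")
  for (cn in c("id", "parent1", "parent2"))
    ped[[cn]] <- as.character(ped[[cn]])
  blank <- function(x) is.na(x) | x == "" | x == "0" | x == "NA"
  ped$parent1[blank(ped$parent1)] <- NA_character_
  ped$parent2[blank(ped$parent2)] <- NA_character_
  dup <- which(duplicated(ped$id))
  if (length(dup))
    stop("duplicated id at row(s) ", paste(dup, collapse = ", "))
  half <- which(is.na(ped$parent1) != is.na(ped$parent2))
  if (length(half))
    stop("exactly one parent missing at row(s) ", paste(half, collapse = ", "))
  self_parent <- which(ped$id == ped$parent1 | ped$id == ped$parent2)
  if (length(self_parent))
    stop("cycle: row(s) ", paste(self_parent, collapse = ", "),
         " list themselves as parent")
  seen <- character(0)
  for (r in seq_len(nrow(ped))) {
    for (p in c(ped$parent1[r], ped$parent2[r])) {
      if (!is.na(p) && !(p %in% seen))
        stop("row ", r, ": parent '", p,
             "' is not defined on an earlier row (unknown parent or ",
             "child listed before parent)")
    }
    seen <- c(seen, ped$id[r])
  }
  if (is.null(ped$type))
    ped$type <- ifelse(is.na(ped$parent1), "founder",
                       ifelse(ped$parent1 == ped$parent2, "self", "cross"))
  if (is.null(ped$generation))
    ped$generation <- ifelse(ped$type == "founder", "founder", "unknown")
  ped <- ped[, c("id", "parent1", "parent2", "generation", "type")]
  class(ped) <- c("magic_pedigree", "data.frame")
  attr(ped, "n_founders") <- sum(ped$type == "founder")
  ped
}

#' Read / write a pedigree file
#'
#' TSV or CSV (by file extension) with header columns
#' `id,parent1,parent2[,generation][,type]`; blank, `"NA"` or `"0"` parents
#' denote founders.  Writing then reading a pedigree returns an identical
#' table.
#'
#' @param file Path to a `.csv` or tab-separated file.
#' @param ped A `magic_pedigree`.
#' @return `read_pedigree`: a validated `magic_pedigree`.
#' @export
read_pedigree <- function(file) {
  sep <- if (grepl("\\.csv$", file, ignore.case = TRUE)) "," else "\t"
  ped <- utils::read.table(file, header = TRUE, sep = sep,
                           colClasses = "character", na.strings = c("NA", ""),
                           stringsAsFactors = FALSE)
  validate_pedigree(ped)
}

#' @rdname read_pedigree
#' @export
write_pedigree <- function(ped, file) {
  sep <- if (grepl("\\.csv$", file, ignore.case = TRUE)) "," else "\t"
  utils::write.table(as.data.frame(ped), file, sep = sep, quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(file)
}

#' @export
print.magic_pedigree <- function(x, ...) {
  cc <- cross_counts(x)
  cat(sprintf(
    "MAGIC pedigree: %d rows, %d founders, %d RILs; crosses %s (total %d)\n",
    nrow(x), sum(x$type == "founder"), count_rils(x),
    paste(cc$per_generation, collapse = ", "), cc$total))
  invisible(x)
}
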