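# Pair-separation structure: which conditions distinguish which GTT pairs.
# A condition separates a pair iff the two tables differ there in at least
# one readout with both predictions resolved (unresolved never separates).
separation_matrix <- function(gtts) {
  stopifnot(length(gtts) >= 2)
  n <- length(gtts)
  pairs <- utils::combn(n, 2)
  nc <- nrow(gtts[[1]]$table)
  S <- matrix(FALSE, nc, ncol(pairs))
  ndiff <- matrix(0L, nc, ncol(pairs))
  for (p in seq_len(ncol(pairs))) {
    ta <- gtts[[pairs[1, p]]]$table
    tb <- gtts[[pairs[2, p]]]$table
    d <- !is.na(ta) & !is.na(tb) & ta != tb
    ndiff[, p] <- rowSums(d)
    S[, p] <- ndiff[, p] > 0
  }
  list(pairs = pairs, S = S, ndiff = ndiff,
       assignments = gtts[[1]]$assignments)
}

greedy_cover <- function(S, cover_pairs) {
  chosen <- integer()
  uncovered <- cover_pairs
  while (length(uncovered)) {
    gain <- rowSums(S[, uncovered, drop = FALSE])
    best <- which.max(gain)
    if (gain[best] == 0) break
    chosen <- c(chosen, best)
    uncovered <- uncovered[!S[best, uncovered]]
  }
  chosen
}

exact_cover <- function(S, cover_pairs, ub_size, max_conditions = 5000) {
  # dominance pruning: drop conditions whose covered pair set is a subset of
  # another's (keeping the canonically first among equals)
  active <- which(rowSums(S[, cover_pairs, drop = FALSE]) > 0)
  keep <- rep(TRUE, length(active))
  for (i in seq_along(active)) {
    if (!keep[i]) next
    si <- S[active[i], cover_pairs]
    for (j in seq_along(active)) {
      if (i == j || !keep[j]) next
      sj <- S[active[j], cover_pairs]
      if (all(sj <= si) && (any(si & !sj) || j > i)) keep[j] <- FALSE
    }
  }
  active <- active[keep]
  if (length(active) > max_conditions) return(NULL)
  Ssub <- S[active, cover_pairs, drop = FALSE]
  best <- seq_len(ub_size)         # placeholder; replaced on first solution
  best_n <- ub_size
  found <- FALSE
  npairs <- length(cover_pairs)
  rec <- function(chosen, covered) {
    if (all(covered)) {
      if (length(chosen) < best_n || !found) {
        best <<- chosen; best_n <<- length(chosen); found <<- TRUE
      }
      return()
    }
    if (length(chosen) + 1 > best_n) return()
    # branch on the uncovered pair with fewest remaining covers
    cand_per_pair <- colSums(Ssub[, !covered, drop = FALSE])
    u <- which(!covered)
    pick <- u[which.min(cand_per_pair)]
    for (cond in which(Ssub[, pick])) {
      if (cond %in% chosen) next
      rec(c(chosen, cond), covered | Ssub[cond, ])
    }
  }
  rec(integer(), rep(FALSE, npairs))
  if (!found) return(integer())
  active[best]
}

#' Minimal set of discriminating experiments
#'
#' Finds conditions whose predicted readouts differ for every separable pair
#' of behaviors — a set cover over GTT pairs. `mode = "greedy"` picks
#' conditions by maximal newly separated pairs; `mode = "exact"` proves a
#' minimum cover by branch-and-bound seeded with the greedy solution (never
#' larger than greedy). Pairs no condition separates are reported and
#' excluded from the cover.
#'
#' @param gtts list of at least two `gtt` objects on the same grid.
#' @param mode `"exact"` (default) or `"greedy"`.
#' @param max_conditions exact mode is attempted only when at most this many
#'   candidate conditions remain after dominance pruning; beyond it the
#'   greedy cover and the lower bound are returned with `exact = FALSE`.
#' @return list with `conditions` (row indices into the condition grid),
#'   `experiments` (their input assignments), `n_pairs`, `inseparable`
#'   (matrix of unseparable pair indices, 0 columns if none), `exact`
#'   (logical: is the cover provably minimum) and `lower_bound`.
#' @export
minimal_discriminating_set <- function(gtts, mode = c("exact", "greedy"),
                                       max_conditions = 5000) {
  mode <- match.arg(mode)
  sep <- separation_matrix(gtts)
  coverable <- colSums(sep$S) > 0
  inseparable <- sep$pairs[, !coverable, drop = FALSE]
  cover_pairs <- which(coverable)
  if (!length(cover_pairs))
    return(list(conditions = integer(),
                experiments = sep$assignments[integer(), , drop = FALSE],
                n_pairs = ncol(sep$pairs), inseparable = inseparable,
                exact = TRUE, lower_bound = 0L))
  greedy <- greedy_cover(sep$S, cover_pairs)
  # lower bound: pairs needing pairwise-disjoint condition sets
  lb <- {
    covers <- lapply(cover_pairs, function(p) which(sep$S[, p]))
    chosen_pairs <- integer(); used <- integer()
    for (p in order(lengths(covers))) {
      if (!length(intersect(covers[[p]], used))) {
        chosen_pairs <- c(chosen_pairs, p)
        used <- c(used, covers[[p]])
      }
    }
    length(chosen_pairs)
  }
  conditions <- greedy
  exact <- FALSE
  if (mode == "exact") {
    res <- exact_cover(sep$S, cover_pairs, length(greedy), max_conditions)
    if (!is.null(res)) {
      conditions <- if (length(res)) res else greedy
      exact <- TRUE
    }
  }
  conditions <- sort(conditions)
  # verification pass: the returned set must separate every coverable pair
  stopifnot(all(colSums(sep$S[conditions, cover_pairs, drop = FALSE]) > 0))
  list(conditions = conditions,
       experiments = sep$assignments[conditions, , drop = FALSE],
       n_pairs = ncol(sep$pairs), inseparable = inseparable,
       exact = exact, lower_bound = max(lb, 1L))
}

#' Rank single experiments by discriminating power
#'
#' Ranks every condition lexicographically by (number of separated GTT pairs,
#' descending; number of active stimuli, ascending; number of active
#' inhibitors, ascending) and returns all conditions achieving the top of
#' that order, with each GTT's predicted readouts — the shortlist of
#' simplest, most informative next experiments.
#'
#' @param gtts list of at least two `gtt` objects.
#' @return list with `ranking` (data frame over all conditions: `condition`,
#'   `n_pairs_separated`, `n_stimuli`, `n_inhibitors`) and `top` (data frame
#'   of the top conditions: assignments plus per-GTT readout predictions).
#' @export
best_single_experiments <- function(gtts) {
  sep <- separation_matrix(gtts)
  n_sep <- rowSums(sep$S)
  ns <- length(gtts[[1]]$stimuli)
  a <- sep$assignments
  n_stim <- rowSums(a[, seq_len(ns), drop = FALSE])
  n_inhib <- rowSums(a[, -seq_len(ns), drop = FALSE])
  if (!ncol(a) - ns) n_inhib <- rep(0L, nrow(a))
  ord <- order(-n_sep, n_stim, n_inhib)
  ranking <- data.frame(condition = seq_len(nrow(a)),
                        n_pairs_separated = n_sep,
                        n_stimuli = n_stim, n_inhibitors = n_inhib)[ord, ]
  top_key <- c(n_sep[ord[1]], n_stim[ord[1]], n_inhib[ord[1]])
  is_top <- n_sep == top_key[1] & n_stim == top_key[2] & n_inhib == top_key[3]
  top_idx <- which(is_top)
  preds <- do.call(cbind, lapply(seq_along(gtts), function(i) {
    p <- as.data.frame(gtts[[i]]$table[top_idx, , drop = FALSE])
    names(p) <- paste0("gtt", i, ".", names(p))
    p
  }))
  list(ranking = ranking,
       top = cbind(data.frame(condition = top_idx),
                   as.data.frame(a[top_idx, , drop = FALSE]), preds))
}

#' Write proposed experiments as CSV
#'
#' @param design output of [best_single_experiments()] or
#'   [minimal_discriminating_set()].
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_experiments <- function(design, path) {
  df <- if (!is.null(design$top)) design$top
        else cbind(data.frame(condition = design$conditions),
                   as.data.frame(design$experiments))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
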