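# All 2^k input assignments over stimuli then inhibitables, in canonical
# binary order (first input = most significant bit).
input_assignments <- function(hg, cap = 20) {
  inputs <- c(hg$stimuli, hg$inhibitables)
  k <- length(inputs)
  if (k == 0) stop("no input nodes (stimuli or inhibitables) designated")
  if (k > cap)
    stop("GTT over ", k, " inputs exceeds the cap of ", cap,
         " (2^", k, " conditions); raise `cap` deliberately if intended")
  r <- 0:(2^k - 1)
  a <- vapply(seq_len(k), function(j) as.integer((r %/% 2^(k - j)) %% 2),
              integer(2^k))
  a <- matrix(as.integer(a), ncol = k)
  colnames(a) <- c(hg$stimuli, if (length(hg$inhibitables))
    paste0(hg$inhibitables, "i"))
  a
}

gtt_clamps <- function(hg, assignments) {
  ns <- length(hg$stimuli)
  stim <- assignments[, seq_len(ns), drop = FALSE]
  colnames(stim) <- hg$stimuli
  inhib <- assignments[, ns + seq_along(hg$inhibitables), drop = FALSE]
  colnames(inhib) <- hg$inhibitables
  build_clamps(hg, stim, inhib)
}

gtt_key <- function(table) {
  paste(ifelse(is.na(table), "u", as.character(table)), collapse = "")
}

new_gtt <- function(hg, assignments, table, members = integer()) {
  structure(list(stimuli = hg$stimuli, inhibitables = hg$inhibitables,
                 readouts = hg$readouts, assignments = assignments,
                 table = table, members = members),
            class = "gtt")
}

#' @export
print.gtt <- function(x, ...) {
  cat(sprintf("GTT: %d conditions (%d inputs) x %d readouts; %d member model(s)\n",
              nrow(x$table), ncol(x$assignments), ncol(x$table),
              length(x$members)))
  invisible(x)
}

#' Compute a model's Global Truth Table
#'
#' The Global Truth Table (GTT) is the model's complete input-output map: its
#' steady-state prediction for every readout under every one of the `2^k`
#' assignments of the `k` input nodes (all stimuli and all inhibitables,
#' toggled independently). Two models with the same GTT are experimentally
#' indistinguishable no matter which condition is applied.
#'
#' @param x a `logic_model`.
#' @param cap refuse more than `2^cap` conditions (default 20).
#' @param max_steps simulation step cap.
#' @return A `gtt` object: input `assignments` (rows in canonical binary
#'   order) and the prediction `table` (conditions x readouts; `NA` =
#'   unresolved).
#' @export
compute_gtt <- function(x, cap = 20, max_steps = NULL) {
  stopifnot(inherits(x, "logic_model"))
  hg <- x$hypergraph
  if (!length(hg$readouts)) stop("no readout nodes designated")
  a <- input_assignments(hg, cap)
  states <- predict_states(hg, x$selected, gtt_clamps(hg, a), max_steps)
  new_gtt(hg, a, states[, hg$readouts, drop = FALSE])
}

#' Group a model family by input-output behavior
#'
#' Partitions the family into its distinct GTTs. Groups are ordered by the
#' minimum member MSE, then by member count (descending), so the first group
#' always contains fit-optimal models.
#'
#' @param x a `model_family`.
#' @param cap,max_steps passed to the GTT computation.
#' @return List of `gtt` objects whose `members` index rows of `x$models`;
#'   together they partition the family.
#' @export
group_by_gtt <- function(x, cap = 20, max_steps = NULL) {
  stopifnot(inherits(x, "model_family"))
  if (!nrow(x$models)) stop("empty family")
  hg <- x$hypergraph
  a <- input_assignments(hg, cap)
  cl <- gtt_clamps(hg, a)
  keys <- character(nrow(x$models))
  tables <- list()
  for (i in seq_len(nrow(x$models))) {
    tab <- predict_states(hg, x$models[i, ], cl, max_steps)[, hg$readouts,
                                                           drop = FALSE]
    keys[i] <- gtt_key(tab)
    if (is.null(tables[[keys[i]]])) tables[[keys[i]]] <- tab
  }
  split_members <- split(seq_len(nrow(x$models)), keys)
  gtts <- lapply(names(split_members), function(kk)
    new_gtt(hg, a, tables[[kk]], members = split_members[[kk]]))
  mse_min <- vapply(gtts, function(g) min(x$mse[g$members]), 0)
  counts <- vapply(gtts, function(g) length(g$members), 0L)
  gtts[order(mse_min, -counts)]
}

#' Core predictions shared by all behaviors
#'
#' Conditions on which every GTT in the list predicts identically for every
#' readout (unresolved counting as its own symbol). These predictions are
#' invariant over the whole family: they hold no matter which member model is
#' the true one.
#'
#' @param gtts list of `gtt` objects over the same inputs/readouts.
#' @return list with `core_index` (condition row indices), `n_core`,
#'   `n_conditions`, and `core` (data frame of the agreeing input
#'   assignments and predicted readout values).
#' @export
core_predictions <- function(gtts) {
  stopifnot(length(gtts) >= 1)
  ref <- gtts[[1]]
  agree <- rep(TRUE, nrow(ref$table))
  enc <- function(tab) ifelse(is.na(tab), -9L, tab)
  ref_t <- enc(ref$table)
  for (g in gtts[-1]) {
    if (!identical(dim(g$table), dim(ref$table)))
      stop("GTTs are not over the same condition/readout grid")
    agree <- agree & rowSums(enc(g$table) != ref_t) == 0
  }
  idx <- which(agree)
  core <- cbind(as.data.frame(ref$assignments),
                as.data.frame(ref$table)[, , drop = FALSE])[idx, , drop = FALSE]
  list(core_index = idx, n_core = length(idx),
       n_conditions = nrow(ref$table), core = core)
}

#' Hierarchically cluster behaviors
#'
#' Agglomerative (average-linkage) clustering of GTTs under the Hamming
#' distance between their concatenated prediction vectors (unresolved is a
#' third symbol). Identical tables merge at height 0; for two tables the
#' first merge height equals their Hamming distance.
#'
#' @param gtts list of at least two `gtt` objects.
#' @return list with `hclust` (the merge tree), `dist` (Hamming distance
#'   matrix) and `newick` (the dendrogram as a Newick string).
#' @export
cluster_gtts <- function(gtts) {
  stopifnot(length(gtts) >= 2)
  vecs <- vapply(gtts, function(g) as.vector(ifelse(is.na(g$table), -9L,
                                                    g$table)),
                 integer(length(gtts[[1]]$table)))
  n <- length(gtts)
  D <- matrix(0, n, n)
  for (i in seq_len(n - 1))
    for (j in (i + 1):n)
      D[i, j] <- D[j, i] <- sum(vecs[, i] != vecs[, j])
  labels <- paste0("gtt", seq_len(n))
  dimnames(D) <- list(labels, labels)
  hc <- stats::hclust(stats::as.dist(D), method = "average")
  phy <- ape::as.phylo(hc)
  list(hclust = hc, dist = D,
       newick = ape::write.tree(phy))
}

#' Write GTT tables as CSV
#'
#' One wide file: group id, input assignment columns, readout prediction
#' columns (empty cell = unresolved), one row per (group, condition).
#'
#' @param gtts list of `gtt` objects.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_gtts <- function(gtts, path) {
  rows <- lapply(seq_along(gtts), function(i) {
    g <- gtts[[i]]
    cbind(data.frame(gtt = i, n_members = length(g$members)),
          as.data.frame(g$assignments), as.data.frame(g$table))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
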