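#' Hyperedge presence frequencies across a family
#'
#' For each candidate gate, the fraction of family members containing it.
#' Gates present in every member (`always`) are expected to be functional;
#' gates in no member (`never`) are not; the rest (`variable`) are not
#' identifiable from the data at the given tolerance.
#'
#' @param x a `model_family`.
#' @return data frame with one row per hyperedge: `id`, `target`, `sources`,
#'   presence `count`, `frequency` (`count / n_models`, exact) and `class`
#'   in `{"always", "never", "variable"}`.
#' @export
hyperedge_frequencies <- function(x) {
  stopifnot(inherits(x, "model_family"))
  n <- nrow(x$models)
  if (!n) stop("empty family")
  count <- colSums(x$models)
  data.frame(id = x$hypergraph$edges$id,
             target = x$hypergraph$edges$target,
             sources = x$hypergraph$edges$sources,
             count = as.integer(count),
             frequency = count / n,
             class = ifelse(count == n, "always",
                            ifelse(count == 0, "never", "variable")),
             row.names = NULL)
}

#' Mutually inclusive gate groups
#'
#' Maximal sets of hyperedges with identical presence patterns across the
#' family — gates that are always either all present or all absent together.
#' These act as single interchangeable modules in the family's
#' combinatorics. Groups are equivalence classes of the presence columns;
#' all-absent gates form their own (inactive) class.
#'
#' @param x a `model_family`.
#' @return data frame with one row per hyperedge: `id`, `group` (integer
#'   label shared by identical columns) and the group's `frequency`.
#' @export
mutually_inclusive_groups <- function(x) {
  stopifnot(inherits(x, "model_family"))
  n <- nrow(x$models)
  if (!n) stop("empty family")
  cols <- apply(x$models, 2L, paste, collapse = "")
  group <- match(cols, unique(cols))
  data.frame(id = x$hypergraph$edges$id, group = group,
             frequency = colSums(x$models)[seq_along(group)] / n,
             row.names = NULL)
}

#' Mutually exclusive module pairs
#'
#' First forms the mutually inclusive groups (identical presence columns),
#' then reports every unordered pair of groups such that in every family
#' member exactly one of the two groups is (fully) present — the
#' interchangeable alternatives whose free combination inflates the family.
#' Only pairs where both sides occur (frequency in `(0, 1)`, frequencies
#' summing to 1) are reported.
#'
#' @param x a `model_family`.
#' @return data frame with one row per pair: hyperedge ids of each side
#'   (`a_ids`, `b_ids`, semicolon-joined), readable gate labels and each
#'   side's frequency. Zero rows when no exclusive pair exists.
#' @export
mutually_exclusive_pairs <- function(x) {
  stopifnot(inherits(x, "model_family"))
  n <- nrow(x$models)
  if (!n) stop("empty family")
  cols <- apply(x$models, 2L, paste, collapse = "")
  groups <- split(seq_len(ncol(x$models)), match(cols, unique(cols)))
  pres <- lapply(groups, function(idx) x$models[, idx[1]])
  freq <- vapply(pres, mean, 0)
  variable <- which(freq > 0 & freq < 1)
  out <- list()
  if (length(variable) >= 2) {
    pairs <- utils::combn(variable, 2)
    for (p in seq_len(ncol(pairs))) {
      ga <- pairs[1, p]; gb <- pairs[2, p]
      if (all(pres[[ga]] + pres[[gb]] == 1L)) {
        ia <- groups[[ga]]; ib <- groups[[gb]]
        lab <- function(idx) paste(paste0(x$hypergraph$edges$sources[idx], "->",
                                          x$hypergraph$edges$target[idx]),
                                   collapse = " & ")
        out[[length(out) + 1L]] <- data.frame(
          a_ids = paste(x$hypergraph$edges$id[ia], collapse = ";"),
          b_ids = paste(x$hypergraph$edges$id[ib], collapse = ";"),
          a_gates = lab(ia), b_gates = lab(ib),
          a_frequency = freq[[ga]], b_frequency = freq[[gb]])
      }
    }
  }
  if (!length(out))
    return(data.frame(a_ids = character(), b_ids = character(),
                      a_gates = character(), b_gates = character(),
                      a_frequency = numeric(), b_frequency = numeric()))
  do.call(rbind, out)
}

#' Effect of swapping one exclusive module for its alternative
#'
#' For every family member containing side A of a mutually exclusive pair,
#' replaces A by B, rescores the swapped model and compares its predictions
#' over the experimental conditions. Score-equivalent pairs give MSE deltas
#' of zero; otherwise the deltas quantify how interchangeable the modules
#' really are.
#'
#' @param x a `model_family`.
#' @param pair one row of [mutually_exclusive_pairs()] output.
#' @param dataset the `midas_dataset` the family was trained on.
#' @param max_steps simulation step cap.
#' @return data frame with one row per swapped member: `model` (row index),
#'   `mse_before`, `mse_after`, `mse_delta` and `changed_fraction` (fraction
#'   of experimental conditions with at least one changed readout
#'   prediction).
#' @export
swap_effect <- function(x, pair, dataset, max_steps = NULL) {
  stopifnot(inherits(x, "model_family"), inherits(dataset, "midas_dataset"))
  a_ids <- as.integer(strsplit(as.character(pair$a_ids), ";")[[1]])
  b_ids <- as.integer(strsplit(as.character(pair$b_ids), ";")[[1]])
  E <- ncol(x$models)
  if (any(c(a_ids, b_ids) < 0) || any(c(a_ids, b_ids) >= E))
    stop("internal error: pair references hyperedges outside the hypergraph")
  hg <- x$hypergraph
  prec <- x$config$precision
  has_a <- which(rowSums(x$models[, a_ids + 1L, drop = FALSE]) == length(a_ids))
  if (!length(has_a)) return(data.frame())
  swapped <- x$models[has_a, , drop = FALSE]
  swapped[, a_ids + 1L] <- 0L
  swapped[, b_ids + 1L] <- 1L
  before <- score_models(hg, x$models[has_a, , drop = FALSE], dataset, prec,
                         max_steps)
  after <- score_models(hg, swapped, dataset, prec, max_steps)
  cl <- build_clamps(hg, dataset$stim, dataset$inhib)
  changed <- vapply(seq_along(has_a), function(r) {
    p0 <- predict_states(hg, x$models[has_a[r], ], cl,
                         max_steps)[, dataset$readouts, drop = FALSE]
    p1 <- predict_states(hg, swapped[r, ], cl,
                         max_steps)[, dataset$readouts, drop = FALSE]
    enc <- function(m) ifelse(is.na(m), -9L, m)
    mean(rowSums(enc(p0) != enc(p1)) > 0)
  }, 0)
  data.frame(model = has_a,
             mse_before = before$mse, mse_after = after$mse,
             mse_delta = after$mse - before$mse,
             changed_fraction = changed)
}
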