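# Low-level gate encoding handed to the C++ engine.
gate_encoding <- function(hg) {
  stopifnot(inherits(hg, "hypergraph"))
  nodes <- hg$nodes
  nsrc <- vapply(hg$gates, function(g) length(g$sources), 0L)
  list(N = length(nodes),
       nodes = nodes,
       gate_target = match(vapply(hg$gates, `[[`, "", "target"), nodes) - 1L,
       gate_ptr = as.integer(c(0L, cumsum(nsrc))),
       gate_src = as.integer(match(unlist(lapply(hg$gates, `[[`, "sources"),
                                          use.names = FALSE), nodes) - 1L),
       gate_sign = as.integer(unlist(lapply(hg$gates, `[[`, "signs"),
                                     use.names = FALSE)))
}

# Clamp codes per (condition, node): -1 free, 0/1 clamped. Stimuli are always
# clamped (on = 1, off = 0); an active inhibitor clamps its node to 0 and
# overrides everything, including a stimulus clamp.
build_clamps <- function(hg, stim, inhib) {
  nodes <- hg$nodes
  n <- max(nrow(stim), nrow(inhib), 1L)
  cl <- matrix(-1L, n, length(nodes))
  if (!is.null(stim) && ncol(stim)) {
    j <- match(colnames(stim), nodes)
    ok <- !is.na(j)
    cl[, j[ok]] <- as.integer(stim[, ok, drop = FALSE])
  }
  if (!is.null(inhib) && ncol(inhib)) {
    j <- match(colnames(inhib), nodes)
    for (k in which(!is.na(j))) {
      on <- inhib[, k] != 0
      cl[on, j[k]] <- 0L
    }
  }
  cl
}

condition_clamps <- function(hg, condition) {
  stim <- matrix(0L, 1, length(hg$stimuli), dimnames = list(NULL, hg$stimuli))
  inhib <- matrix(0L, 1, length(hg$inhibitables),
                  dimnames = list(NULL, hg$inhibitables))
  bad <- setdiff(condition$stimulus_on, hg$stimuli)
  if (length(bad)) stop("not a stimulus: ", paste(bad, collapse = ", "))
  bad <- setdiff(condition$inhibitor_on, hg$inhibitables)
  if (length(bad)) stop("not inhibitable: ", paste(bad, collapse = ", "))
  stim[, match(condition$stimulus_on, hg$stimuli)] <- 1L
  inhib[, match(condition$inhibitor_on, hg$inhibitables)] <- 1L
  build_clamps(hg, stim, inhib)
}

#' Construct a logic model as a gate subset
#'
#' A model selects a subset of the candidate hyperedges; each target's update
#' rule is the OR over its selected AND gates (sum-of-products). A target
#' with no selected gate, not clamped by the condition, is constitutively 0.
#'
#' @param hg a `hypergraph` from [expand_pkn()].
#' @param selected 0/1 (or logical) vector over the canonical hyperedge ids,
#'   or an integer vector of selected ids when `ids = TRUE`.
#' @param ids interpret `selected` as 0-based hyperedge ids.
#' @return An object of class `logic_model`.
#' @export
logic_model <- function(hg, selected, ids = FALSE) {
  stopifnot(inherits(hg, "hypergraph"))
  E <- nrow(hg$edges)
  if (ids) {
    sel <- integer(E)
    stopifnot(all(selected >= 0 & selected < E))
    sel[selected + 1L] <- 1L
  } else {
    if (length(selected) != E)
      stop("selected must have one entry per hyperedge (", E, ")")
    sel <- as.integer(as.logical(selected))
  }
  structure(list(hypergraph = hg, selected = sel), class = "logic_model")
}

#' @export
print.logic_model <- function(x, ...) {
  on <- which(x$selected == 1L)
  cat(sprintf("Logic model: %d/%d gates, size %d\n", length(on),
              length(x$selected), model_size(x)))
  if (length(on)) {
    e <- x$hypergraph$edges[on, , drop = FALSE]
    cat(paste0("  ", e$sources, " -> ", e$target, collapse = "\n"), "\n")
  }
  invisible(x)
}

#' Size of a logic model
#'
#' The parsimony objective: the sum over selected gates of the number of
#' gate inputs.
#'
#' @param x a `logic_model`.
#' @return Integer size.
#' @export
model_size <- function(x) {
  stopifnot(inherits(x, "logic_model"))
  sum(vapply(x$hypergraph$gates[x$selected == 1L],
             function(g) length(g$sources), 0L))
}

#' Simulate a model to quasi steady state under one condition
#'
#' Stimulated stimuli are clamped to 1 and unstimulated stimuli to 0;
#' inhibited nodes are clamped to 0, overriding their rule. All remaining
#' nodes start at 0 and are updated synchronously by their sum-of-products
#' rules until a fixpoint or `max_steps`. At a fixpoint every unclamped node
#' satisfies its own rule. With feedback loops the trajectory may never
#' settle; nodes still oscillating at `max_steps` are reported as `NA`
#' (unresolved) rather than an error.
#'
#' @param x a `logic_model`.
#' @param condition list with character elements `stimulus_on` and
#'   `inhibitor_on` (subsets of the designated roles).
#' @param max_steps maximum synchronous updates; default `3 * n_nodes`.
#' @return Named integer vector of node states (0/1, `NA` = unresolved).
#' @export
simulate_model <- function(x, condition = list(stimulus_on = character(),
                                               inhibitor_on = character()),
                           max_steps = NULL) {
  stopifnot(inherits(x, "logic_model"))
  hg <- x$hypergraph
  enc <- gate_encoding(hg)
  if (is.null(max_steps)) max_steps <- 3L * enc$N
  cl <- condition_clamps(hg, condition)
  out <- simulate_cpp(enc$N, enc$gate_target, enc$gate_ptr, enc$gate_src,
                      enc$gate_sign, x$selected, cl, as.integer(max_steps))
  stats::setNames(out[1, ], hg$nodes)
}

# Observation matrix on the scaled integer grid (NA kept).
scale_obs <- function(dataset, precision) {
  v <- discretize_values(dataset$values, precision)
  m <- round(v * 10^precision)
  storage.mode(m) <- "integer"
  m
}

#' Score models against a dataset (exact integer arithmetic)
#'
#' For each condition and readout with a non-missing measurement, the
#' residual is the Boolean prediction minus the measurement discretized to
#' the `10^-precision` grid. Unresolved predictions contribute the maximum
#' squared residual of 1. The sum of squared residuals is accumulated as an
#' exact integer scaled by `10^(2 * precision)`, so ties and tolerance
#' thresholds in the enumeration are exact.
#'
#' @param hg a `hypergraph`.
#' @param models matrix of 0/1 rows over canonical hyperedge ids (one row
#'   per model), or a single `logic_model`.
#' @param dataset a `midas_dataset` with values in `[0, 1]`.
#' @param precision discretization digits (default 2).
#' @param max_steps simulation step cap; default `3 * n_nodes`.
#' @return data frame with one row per model: `sse_scaled`, `n_compared`,
#'   `size`, `mse`.
#' @export
score_models <- function(hg, models, dataset, precision = 2, max_steps = NULL) {
  if (inherits(models, "logic_model")) {
    hg <- models$hypergraph
    models <- matrix(models$selected, nrow = 1)
  }
  stopifnot(inherits(hg, "hypergraph"), inherits(dataset, "midas_dataset"))
  if (!all(dataset$readouts %in% hg$nodes))
    stop("dataset readouts not all present in hypergraph nodes")
  obs <- scale_obs(dataset, precision)
  if (all(is.na(obs))) stop("dataset has no non-missing measurements")
  enc <- gate_encoding(hg)
  if (is.null(max_steps)) max_steps <- 3L * enc$N
  cl <- build_clamps(hg, dataset$stim, dataset$inhib)
  storage.mode(models) <- "integer"
  res <- score_models_cpp(enc$N, enc$gate_target, enc$gate_ptr, enc$gate_src,
                          enc$gate_sign, models, cl, obs,
                          match(dataset$readouts, hg$nodes) - 1L,
                          10^precision, as.integer(max_steps))
  data.frame(sse_scaled = res$sse, n_compared = res$n_compared,
             size = res$size,
             mse = res$sse / (res$n_compared * 10^(2 * precision)))
}

#' Score a single logic model
#'
#' @inheritParams score_models
#' @param x a `logic_model`.
#' @return list with `sse_scaled`, `n_compared`, `size` and `mse`
#'   (`MSE = sse_scaled / (n_compared * 10^(2 * precision))`).
#' @export
score_model <- function(x, dataset, precision = 2, max_steps = NULL) {
  df <- score_models(NULL, x, dataset, precision, max_steps)
  as.list(df[1, ])
}

# Prediction matrix (conditions x nodes) for one model over a clamp matrix.
predict_states <- function(hg, selected, clamps, max_steps = NULL) {
  enc <- gate_encoding(hg)
  if (is.null(max_steps)) max_steps <- 3L * enc$N
  out <- simulate_cpp(enc$N, enc$gate_target, enc$gate_ptr, enc$gate_src,
                      enc$gate_sign, as.integer(selected), clamps,
                      as.integer(max_steps))
  colnames(out) <- hg$nodes
  out
}
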