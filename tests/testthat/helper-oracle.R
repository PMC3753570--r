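# Independent pure-R oracle: simulator, scorer and exhaustive family search.
# Deliberately written from the definitions (synchronous updates, OR of AND
# gates, clamp semantics, integer-grid residuals), sharing no code with the
# package's C++ engine.

r_simulate <- function(hg, selected, stimulus_on = character(),
                       inhibitor_on = character(), max_steps = NULL) {
  nodes <- hg$nodes
  if (is.null(max_steps)) max_steps <- 3L * length(nodes)
  clamp <- stats::setNames(rep(NA_integer_, length(nodes)), nodes)
  clamp[hg$stimuli] <- 0L
  clamp[intersect(stimulus_on, nodes)] <- 1L
  clamp[intersect(inhibitor_on, nodes)] <- 0L
  gates <- hg$gates[selected == 1]
  step <- function(state) {
    nxt <- state
    for (v in nodes) {
      if (!is.na(clamp[[v]])) { nxt[[v]] <- clamp[[v]]; next }
      val <- 0L
      for (g in gates) {
        if (g$target != v) next
        lit <- ifelse(g$signs > 0, 1L, 0L)
        if (all(state[g$sources] == lit)) { val <- 1L; break }
      }
      nxt[[v]] <- val
    }
    nxt
  }
  state <- ifelse(is.na(clamp), 0L, clamp)
  names(state) <- nodes
  converged <- FALSE
  for (i in seq_len(max_steps)) {
    nxt <- step(state)
    if (identical(unname(nxt), unname(state))) { converged <- TRUE; break }
    state <- nxt
  }
  if (!converged) {
    unstable <- rep(FALSE, length(nodes))
    cur <- state
    for (i in seq_len(length(nodes) + 1L)) {
      nxt <- step(cur)
      unstable <- unstable | (unname(nxt) != unname(cur))
      cur <- nxt
    }
    state[unstable] <- NA_integer_
  }
  state
}

r_score <- function(hg, selected, dataset, precision = 2) {
  s <- 10^precision
  sse <- 0
  n <- 0
  for (i in seq_len(nrow(dataset$values))) {
    stim_on <- dataset$stimuli[dataset$stim[i, ] == 1]
    inhib_on <- dataset$inhibitables[dataset$inhib[i, ] == 1]
    state <- r_simulate(hg, selected, stim_on, inhib_on)
    for (j in seq_along(dataset$readouts)) {
      x <- dataset$values[i, j]
      if (is.na(x)) next
      n <- n + 1
      d <- floor(x * s + 0.5 + 1e-9)  # discretized, scaled
      p <- state[[dataset$readouts[j]]]
      sse <- sse + if (is.na(p)) s^2 else (p * s - d)^2
    }
  }
  size <- sum(vapply(hg$gates[selected == 1], function(g) length(g$sources), 0L))
  list(sse_scaled = unname(sse), n_compared = n, size = size)
}

# Exhaustive family: scores every one of the 2^E subsets. `scorer = "r"`
# uses the pure-R scorer above (tiny instances); `scorer = "cpp"` scores all
# subsets in bulk through score_models() so only the *search* is independent
# (the scorer itself is validated against the R oracle elsewhere).
brute_family <- function(hg, dataset, precision = 2, eps = 0,
                         size_bound = "optimal", scorer = c("cpp", "r")) {
  scorer <- match.arg(scorer)
  E <- nrow(hg$edges)
  subsets <- all_subsets(E)
  if (scorer == "r") {
    scores <- lapply(seq_len(nrow(subsets)),
                     function(r) r_score(hg, subsets[r, ], dataset, precision))
    sse <- vapply(scores, `[[`, 0, "sse_scaled")
    size <- vapply(scores, `[[`, 0, "size")
  } else {
    df <- score_models(hg, subsets, dataset, precision)
    sse <- df$sse_scaled
    size <- df$size
  }
  sse_opt <- min(sse)
  size_opt <- min(size[sse == sse_opt])
  sb <- if (identical(size_bound, "optimal")) size_opt else size_bound
  keep <- sse <= (1 + eps) * sse_opt + 1e-9 & size <= sb
  models <- subsets[keep, , drop = FALSE]
  ord <- do.call(order, as.data.frame(models))
  list(models = models[ord, , drop = FALSE],
       sse = sse[keep][ord], size = size[keep][ord],
       sse_opt = sse_opt, size_opt = size_opt)
}

# Check that a converged state satisfies every node's rule (fixpoint
# property), evaluated directly from the hypergraph definition.
r_is_fixpoint <- function(hg, selected, state, stimulus_on, inhibitor_on) {
  clamp <- stats::setNames(rep(NA_integer_, length(hg$nodes)), hg$nodes)
  clamp[hg$stimuli] <- 0L
  clamp[intersect(stimulus_on, hg$nodes)] <- 1L
  clamp[intersect(inhibitor_on, hg$nodes)] <- 0L
  gates <- hg$gates[selected == 1]
  for (v in hg$nodes) {
    expected <- if (!is.na(clamp[[v]])) clamp[[v]] else {
      val <- 0L
      for (g in gates) {
        if (g$target != v) next
        lit <- ifelse(g$signs > 0, 1L, 0L)
        if (all(state[g$sources] == lit)) { val <- 1L; break }
      }
      val
    }
    if (state[[v]] != expected) return(FALSE)
  }
  TRUE
}
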