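#' Compress a PKN before gate expansion
#'
#' Removes structure that cannot influence the fit: undesignated nodes with
#' no directed path to any readout, undesignated nodes unreachable from every
#' stimulus or inhibitable, and pass-through undesignated nodes (indegree 1
#' or outdegree 1), which are collapsed by replacing each path `u -> x -> w`
#' with a direct edge carrying the sign product. Collapses that would create
#' a self-loop are skipped so the fixpoint semantics of any feedback loop is
#' preserved. Role-designated nodes (stimuli, inhibitables, readouts) are
#' never removed. Parallel edges with equal sign are merged; opposite-sign
#' parallels are both kept (they generate distinct gate literals).
#'
#' @param x a `pkn` with roles assigned.
#' @return The compressed `pkn`. A readout left without regulators is kept
#'   and reported as a warning.
#' @export
compress_pkn <- function(x) {
  stopifnot(inherits(x, "pkn"))
  designated <- unique(c(x$stimuli, x$inhibitables, x$readouts))
  if (!length(designated)) stop("compress_pkn requires assigned roles")
  edges <- x$edges
  nodes <- x$nodes
  repeat {
    changed <- FALSE
    key <- paste(edges$source, edges$sign, edges$target)
    edges <- edges[!duplicated(key), , drop = FALSE]
    # (a)/(b) reachability pruning of undesignated nodes
    g <- igraph::graph_from_data_frame(
      edges[c("source", "target")], directed = TRUE,
      vertices = data.frame(name = nodes))
    reach <- function(from, mode) {
      hit <- character()
      for (v in intersect(from, nodes))
        hit <- union(hit, names(igraph::subcomponent(g, v, mode = mode)))
      hit
    }
    to_readout <- reach(x$readouts, "in")
    from_input <- reach(c(x$stimuli, x$inhibitables), "out")
    keep <- nodes %in% designated | (nodes %in% to_readout & nodes %in% from_input)
    if (!all(keep)) {
      drop <- nodes[!keep]
      nodes <- nodes[keep]
      edges <- edges[!(edges$source %in% drop) & !(edges$target %in% drop), ,
                     drop = FALSE]
      changed <- TRUE
    }
    # (c) collapse one pass-through undesignated node per sweep
    for (v in setdiff(nodes, designated)) {
      inc <- edges[edges$target == v & edges$source != v, , drop = FALSE]
      out <- edges[edges$source == v & edges$target != v, , drop = FALSE]
      if (any(edges$source == v & edges$target == v)) next  # self-loop: keep
      if (nrow(inc) == 0 || nrow(out) == 0) next            # handled by (a)/(b)
      if (nrow(inc) > 1 && nrow(out) > 1) next              # would multiply edges
      pairs <- merge(inc, out, by = NULL)
      if (any(pairs$source.x == pairs$target.y)) next       # would create self-loop
      new_edges <- data.frame(source = pairs$source.x,
                              sign = pairs$sign.x * pairs$sign.y,
                              target = pairs$target.y)
      edges <- rbind(edges[edges$source != v & edges$target != v, , drop = FALSE],
                     new_edges)
      nodes <- setdiff(nodes, v)
      changed <- TRUE
      break
    }
    if (!changed) break
  }
  key <- paste(edges$source, edges$sign, edges$target)
  edges <- edges[!duplicated(key), , drop = FALSE]
  out <- pkn(edges, nodes = nodes, stimuli = intersect(x$stimuli, nodes),
             inhibitables = intersect(x$inhibitables, nodes),
             readouts = intersect(x$readouts, nodes))
  orphans <- setdiff(out$readouts, out$edges$target)
  if (length(orphans))
    warning("readout(s) without remaining regulators: ",
            paste(orphans, collapse = ", "))
  out
}

signed_token <- function(node, sign) paste0(ifelse(sign > 0, "+", "-"), node)

#' Expand a compressed PKN into the candidate gate hypergraph
#'
#' For each node `t` with signed regulators `R(t)` in the compressed PKN,
#' one AND-gate hyperedge is generated per non-empty, sign-consistent subset
#' of `R(t)` with at most `max_gate_size` inputs (a gate containing both `p`
#' and `NOT p` is always false and is excluded). With `r` sign-consistent
#' regulators and no cap this yields `2^r - 1` candidate gates for `t`. A
#' logic model is then any subset of these gates, read as an OR over the
#' selected gates per target (sum-of-products form).
#'
#' @param x a compressed `pkn`.
#' @param max_gate_size maximum number of inputs per gate; `Inf` for
#'   unbounded. Default 4.
#' @return An object of class `hypergraph`: node set, roles and the
#'   canonical hyperedge table (`$edges`: 0-based `id`, `target`, `sources`
#'   as semicolon-joined signed tokens such as `"+a;-b"`), plus the gate
#'   structure used by the simulator.
#' @export
expand_pkn <- function(x, max_gate_size = 4) {
  stopifnot(inherits(x, "pkn"))
  if (!is.numeric(max_gate_size) || max_gate_size < 1)
    stop("max_gate_size must be >= 1")
  out <- list()
  for (t in sort(unique(x$edges$target), method = "radix")) {
    reg <- x$edges[x$edges$target == t, , drop = FALSE]
    reg <- reg[order(reg$source, reg$sign, method = "radix"), , drop = FALSE]
    r <- nrow(reg)
    for (k in seq_len(min(r, max_gate_size))) {
      for (idx in utils::combn(r, k, simplify = FALSE)) {
        sub <- reg[idx, , drop = FALSE]
        if (anyDuplicated(sub$source)) next  # p AND NOT p: always false
        o <- order(signed_token(sub$source, sub$sign), method = "radix")
        out[[length(out) + 1L]] <- list(target = t,
                                        sources = sub$source[o],
                                        signs = sub$sign[o],
                                        key = paste(signed_token(sub$source, sub$sign)[o],
                                                    collapse = ";"))
      }
    }
  }
  if (length(out)) {
    ord <- order(vapply(out, `[[`, "", "target"),
                 vapply(out, `[[`, "", "key"), method = "radix")
    out <- out[ord]
  }
  edges <- data.frame(id = seq_along(out) - 1L,
                      target = vapply(out, `[[`, "", "target"),
                      sources = vapply(out, `[[`, "", "key"),
                      stringsAsFactors = FALSE)
  structure(list(nodes = x$nodes,
                 stimuli = x$stimuli, inhibitables = x$inhibitables,
                 readouts = x$readouts,
                 edges = edges,
                 gates = lapply(out, function(g)
                   list(target = g$target, sources = g$sources, signs = g$signs))),
            class = "hypergraph")
}

#' @export
print.hypergraph <- function(x, ...) {
  cat(sprintf("Expanded hypergraph: %d nodes, %d candidate gates (model space %s)\n",
              length(x$nodes), nrow(x$edges), search_space_size(x)))
  invisible(x)
}

#' Number of hyperedges in a hypergraph
#' @param x a `hypergraph`.
#' @return Integer count of candidate gates.
#' @export
n_hyperedges <- function(x) nrow(x$edges)

#' Size of the model search space
#'
#' The number of candidate logic models is `2^E` for `E` hyperedges; this is
#' returned as an exact decimal string (arbitrary precision), since `E` can
#' exceed what a double represents exactly.
#'
#' @param x a `hypergraph`, or an integer hyperedge count.
#' @return Character scalar holding the exact decimal value of `2^E`.
#' @examples
#' search_space_size(6L)   # "64"
#' @export
search_space_size <- function(x) {
  e <- if (inherits(x, "hypergraph")) nrow(x$edges) else as.integer(x)
  stopifnot(e >= 0)
  digits <- c(1L)  # little-endian decimal digits
  for (i in seq_len(e)) {
    digits <- digits * 2L
    carry <- 0L
    for (j in seq_along(digits)) {
      digits[j] <- digits[j] + carry
      carry <- digits[j] %/% 10L
      digits[j] <- digits[j] %% 10L
    }
    while (carry > 0L) {
      digits <- c(digits, carry %% 10L)
      carry <- carry %/% 10L
    }
  }
  paste(rev(digits), collapse = "")
}

#' Write / read the hyperedge table as CSV
#'
#' Columns: `id` (canonical 0-based), `target`, `sources` (semicolon-joined
#' signed tokens).
#'
#' @param x a `hypergraph`.
#' @param path CSV path.
#' @return `path` (write) invisibly.
#' @export
write_hypergraph <- function(x, path) {
  stopifnot(inherits(x, "hypergraph"))
  utils::write.csv(x$edges, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}
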