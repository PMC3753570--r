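#' Construct a prior knowledge network (PKN)
#'
#' A PKN is a signed directed graph of known causal interactions among
#' signaling species, with three experimental roles designated on its nodes:
#' stimuli (ligands that can be set active), inhibitables (species that can be
#' clamped inactive by a small-molecule inhibitor) and readouts (species whose
#' activity is measured).
#'
#' @param edges data frame with columns `source` (character), `sign`
#'   (integer, `+1` activation or `-1` inhibition) and `target` (character).
#' @param nodes optional character vector of node names; defaults to the nodes
#'   appearing in `edges`. Extra isolated nodes may be listed.
#' @param stimuli,inhibitables,readouts character vectors of role-designated
#'   node names; each must be a subset of `nodes`.
#' @return An object of class `pkn`: a list with elements `nodes`, `edges`,
#'   `stimuli`, `inhibitables`, `readouts`.
#' @examples
#' pkn(data.frame(source = c("a", "b"), sign = c(1L, -1L), target = c("c", "c")),
#'     stimuli = c("a", "b"), readouts = "c")
#' @export
pkn <- function(edges, nodes = NULL, stimuli = character(),
                inhibitables = character(), readouts = character()) {
  stopifnot(is.data.frame(edges),
            all(c("source", "sign", "target") %in% names(edges)))
  edges$source <- as.character(edges$source)
  edges$target <- as.character(edges$target)
  edges$sign <- as.integer(edges$sign)
  if (nrow(edges) && !all(edges$sign %in% c(-1L, 1L)))
    stop("edge signs must be +1 or -1")
  key <- paste(edges$source, edges$sign, edges$target)
  if (anyDuplicated(key))
    edges <- edges[!duplicated(key), , drop = FALSE]
  all_nodes <- sort(unique(c(edges$source, edges$target, nodes,
                             stimuli, inhibitables, readouts)),
                    method = "radix")
  for (role in list(stimuli, inhibitables, readouts))
    if (!all(role %in% all_nodes)) stop("role-designated node not in node set")
  rownames(edges) <- NULL
  structure(list(nodes = all_nodes,
                 edges = edges[c("source", "sign", "target")],
                 stimuli = sort(unique(as.character(stimuli)), method = "radix"),
                 inhibitables = sort(unique(as.character(inhibitables)), method = "radix"),
                 readouts = sort(unique(as.character(readouts)), method = "radix")),
            class = "pkn")
}

#' @export
print.pkn <- function(x, ...) {
  cat(sprintf("PKN: %d nodes, %d signed edges\n", length(x$nodes), nrow(x$edges)))
  cat(sprintf("  stimuli:      %s\n", paste(x$stimuli, collapse = ", ")))
  cat(sprintf("  inhibitables: %s\n", paste(x$inhibitables, collapse = ", ")))
  cat(sprintf("  readouts:     %s\n", paste(x$readouts, collapse = ", ")))
  invisible(x)
}

#' Assign experimental roles to a PKN
#'
#' Roles usually come from the MIDAS header (see [read_midas()]); this helper
#' attaches them to a network read from SIF, which carries no role information.
#'
#' @param x a `pkn`.
#' @param stimuli,inhibitables,readouts character vectors of node names, or a
#'   `midas_roles` object in place of `stimuli`.
#' @return The `pkn` with roles set.
#' @export
set_roles <- function(x, stimuli = character(), inhibitables = character(),
                      readouts = character()) {
  stopifnot(inherits(x, "pkn"))
  if (inherits(stimuli, "midas_roles")) {
    r <- stimuli
    stimuli <- r$stimuli; inhibitables <- r$inhibitables; readouts <- r$readouts
  }
  missing_nodes <- setdiff(c(stimuli, inhibitables, readouts), x$nodes)
  if (length(missing_nodes))
    stop("role nodes absent from network: ", paste(missing_nodes, collapse = ", "))
  pkn(x$edges, nodes = x$nodes, stimuli = stimuli,
      inhibitables = inhibitables, readouts = readouts)
}
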