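#' Configuration for synthetic instance generation
#'
#' The generator emulates the structure of perturbation phospho-proteomics
#' studies: a signed (by default acyclic) prior network whose sources are
#' ligand stimuli, a few drug-inhibitable intermediates, measured readouts,
#' and bounded noisy measurements over factorial stimulus/inhibitor
#' conditions.
#'
#' @param n_nodes,n_stimuli,n_inhibitables,n_readouts node counts;
#'   `n_stimuli + n_readouts <= n_nodes`.
#' @param edge_prob probability of each forward edge.
#' @param neg_sign_prob probability an edge is inhibitory.
#' @param allow_cycles also sample feedback edges (default `FALSE`).
#' @param max_gate_size gate-size cap used when expanding.
#' @param noise_sd standard deviation of additive Gaussian measurement noise,
#'   truncated so observations stay in `[0, 1]`; 0 = noise-free.
#' @param n_conditions `"all"` for the full factorial over inputs, or a count
#'   of distinct sampled conditions.
#' @param seed integer RNG seed; every output is reproducible from it.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_nodes = 10, n_stimuli = 2, n_inhibitables = 1,
                         n_readouts = 3, edge_prob = 0.3, neg_sign_prob = 0.25,
                         allow_cycles = FALSE, max_gate_size = 3,
                         noise_sd = 0, n_conditions = "all", seed = 1) {
  stopifnot(n_stimuli >= 1, n_readouts >= 1, n_inhibitables >= 0,
            n_stimuli + n_readouts <= n_nodes,
            edge_prob >= 0, edge_prob <= 1,
            neg_sign_prob >= 0, neg_sign_prob <= 1,
            noise_sd >= 0, max_gate_size >= 1)
  structure(list(n_nodes = n_nodes, n_stimuli = n_stimuli,
                 n_inhibitables = n_inhibitables, n_readouts = n_readouts,
                 edge_prob = edge_prob, neg_sign_prob = neg_sign_prob,
                 allow_cycles = allow_cycles, max_gate_size = max_gate_size,
                 noise_sd = noise_sd, n_conditions = n_conditions,
                 seed = as.integer(seed)), class = "synth_config")
}

#' Generate a random prior knowledge network
#'
#' Nodes are laid out in a fixed topological order: the first `n_stimuli`
#' nodes are stimuli (no incoming edges), the last `n_readouts` are
#' readouts; inhibitables are sampled among the non-stimulus nodes. Forward
#' edges `i -> j` (`i < j`, `j` not a stimulus) appear independently with
#' `edge_prob`; with `allow_cycles`, feedback edges are sampled at half that
#' rate. Generation fails if no readout is reachable from any stimulus.
#'
#' @param config a [synth_config()].
#' @return A `pkn` with roles assigned.
#' @export
generate_pkn <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  withr::with_seed(config$seed, {
    n <- config$n_nodes
    nodes <- sprintf("v%02d", seq_len(n))
    stimuli <- nodes[seq_len(config$n_stimuli)]
    readouts <- nodes[(n - config$n_readouts + 1):n]
    non_stim <- setdiff(nodes, stimuli)
    pool <- setdiff(non_stim, readouts)
    if (length(pool) < config$n_inhibitables) pool <- non_stim
    inhibitables <- sort(sample(pool, min(config$n_inhibitables, length(pool))))
    src <- character(); sgn <- integer(); tgt <- character()
    for (j in seq_len(n)) {
      if (nodes[j] %in% stimuli) next
      for (i in seq_len(n)) {
        if (i == j) next
        forward <- i < j
        p <- if (forward) config$edge_prob
             else if (config$allow_cycles) config$edge_prob / 2 else 0
        if (stats::runif(1) < p) {
          src <- c(src, nodes[i]); tgt <- c(tgt, nodes[j])
          sgn <- c(sgn, if (stats::runif(1) < config$neg_sign_prob) -1L else 1L)
        }
      }
    }
    net <- pkn(data.frame(source = src, sign = sgn, target = tgt),
               nodes = nodes, stimuli = stimuli,
               inhibitables = inhibitables, readouts = readouts)
    g <- igraph::graph_from_data_frame(net$edges[c("source", "target")],
                                       directed = TRUE,
                                       vertices = data.frame(name = net$nodes))
    reached <- unique(unlist(lapply(stimuli, function(s)
      names(igraph::subcomponent(g, s, mode = "out")))))
    if (!any(readouts %in% reached))
      stop("generated network has no path from any stimulus to any readout; ",
           "increase edge_prob or change the seed")
    if (!config$allow_cycles &&
        !igraph::is_acyclic(igraph::graph_from_data_frame(
          net$edges[c("source", "target")])))
      stop("internal error: acyclic generation produced a cycle")
    net
  })
}

#' Sample a ground-truth model and simulate a noisy dataset from it
#'
#' The PKN is compressed and expanded; a ground-truth gate subset is sampled
#' with a bias toward small gates (every target on a path to a readout gets
#' at least one gate where possible, so the parsimony objective stays
#' informative). The truth is simulated under the experimental conditions
#' and observations are its Boolean states plus truncated Gaussian noise.
#'
#' @param net a `pkn` with roles (typically from [generate_pkn()]).
#' @param config the [synth_config()] (uses `max_gate_size`, `noise_sd`,
#'   `n_conditions` and `seed`).
#' @return list with `hypergraph`, `truth` (a `logic_model`), and `dataset`
#'   (a `midas_dataset` ready for scoring or [write_midas()]).
#' @export
generate_truth_and_data <- function(net, config) {
  stopifnot(inherits(net, "pkn"), inherits(config, "synth_config"))
  hg <- expand_pkn(suppressWarnings(compress_pkn(net)), config$max_gate_size)
  if (!nrow(hg$edges)) stop("expanded hypergraph is empty")
  withr::with_seed(config$seed + 1000003L, {
    # feeds-readout targets must stay active so the truth is observable
    g <- igraph::graph_from_data_frame(
      data.frame(source = unlist(lapply(hg$gates, `[[`, "sources")),
                 target = rep(vapply(hg$gates, `[[`, "", "target"),
                              vapply(hg$gates, function(x) length(x$sources), 0L))),
      directed = TRUE,
      vertices = data.frame(name = hg$nodes))
    feeds_readout <- unique(unlist(lapply(intersect(hg$readouts, hg$nodes),
      function(r) names(igraph::subcomponent(g, r, mode = "in")))))
    sel <- integer(nrow(hg$edges))
    for (t in unique(hg$edges$target)) {
      gates_t <- which(hg$edges$target == t)
      must <- t %in% feeds_readout
      if (!must && stats::runif(1) < 0.5) next
      k <- min(1L + stats::rgeom(1, 0.7), length(gates_t))
      w <- 0.5^vapply(hg$gates[gates_t], function(x) length(x$sources), 0L)
      pick <- gates_t[sample.int(length(gates_t), k, prob = w)]
      sel[pick] <- 1L
    }
    truth <- logic_model(hg, sel)
    a <- input_assignments(hg, cap = 20)
    if (!identical(config$n_conditions, "all")) {
      nc <- min(config$n_conditions, nrow(a))
      a <- a[sort(sample(nrow(a), nc)), , drop = FALSE]
    }
    cl <- gtt_clamps(hg, a)
    states <- predict_states(hg, truth$selected, cl)
    pred <- states[, hg$readouts, drop = FALSE]
    values <- matrix(as.numeric(pred), nrow(pred), ncol(pred),
                     dimnames = list(NULL, hg$readouts))
    if (config$noise_sd > 0)
      values <- pmin(pmax(values +
        stats::rnorm(length(values), 0, config$noise_sd), 0), 1)
    ns <- length(hg$stimuli)
    stim <- a[, seq_len(ns), drop = FALSE]
    colnames(stim) <- hg$stimuli
    inhib <- a[, ns + seq_along(hg$inhibitables), drop = FALSE]
    colnames(inhib) <- hg$inhibitables
    dataset <- structure(list(stimuli = hg$stimuli,
                              inhibitables = hg$inhibitables,
                              readouts = hg$readouts,
                              stim = stim, inhib = inhib,
                              values = values, time = 10),
                         class = "midas_dataset")
    list(hypergraph = hg, truth = truth, dataset = dataset)
  })
}
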