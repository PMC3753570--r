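# Shared fixtures, built in code.

# Minimal dataset constructor used throughout the tests.
make_dataset <- function(stim, inhib, values, time = 10) {
  if (is.null(inhib)) inhib <- matrix(0L, nrow(stim), 0)
  structure(list(stimuli = colnames(stim),
                 inhibitables = if (ncol(inhib)) colnames(inhib) else character(),
                 readouts = colnames(values),
                 stim = stim, inhib = inhib, values = values, time = time),
            class = "midas_dataset")
}

# Two-stimulus cascade: c has regulators {a+, b+}, d has {b-, c+};
# expansion gives 3 + 3 = 6 candidate gates. Ground truth: c = a,
# d = c AND NOT b; data are the noise-free truth states over all four
# stimulus combinations. Unique optimum: MSE 0, size 3.
toy1_pkn <- function(inhibit_c = FALSE) {
  pkn(data.frame(source = c("a", "b", "c", "b"),
                 sign = c(1L, 1L, 1L, -1L),
                 target = c("c", "c", "d", "d")),
      stimuli = c("a", "b"),
      inhibitables = if (inhibit_c) "c" else character(),
      readouts = c("c", "d"))
}

toy1_hypergraph <- function(inhibit_c = FALSE)
  expand_pkn(compress_pkn(toy1_pkn(inhibit_c)), Inf)

toy1_dataset <- function() {
  stim <- cbind(a = c(0L, 0L, 1L, 1L), b = c(0L, 1L, 0L, 1L))
  values <- cbind(c = as.numeric(stim[, "a"]),
                  d = as.numeric(stim[, "a"] == 1 & stim[, "b"] == 0))
  make_dataset(stim, NULL, values)
}

toy1_truth_selected <- function(hg) {
  as.integer(hg$edges$sources == "+a" & hg$edges$target == "c" |
             hg$edges$sources == "+c;-b" & hg$edges$target == "d")
}

# All 2^E gate subsets as a 0/1 matrix (rows in increasing binary order).
all_subsets <- function(E) {
  r <- 0:(2^E - 1)
  m <- vapply(seq_len(E) - 1L,
              function(b) as.integer(bitwAnd(r, bitwShiftL(1L, b)) > 0),
              integer(length(r)))
  matrix(m, ncol = E)
}

model_key <- function(models) apply(models, 1L, paste, collapse = "")

# Deterministic battery of small synthetic instances for oracle comparisons.
# Filters seeds so the expanded hypergraph stays within max_edges gates.
synth_battery <- function(n, max_edges = 18, noise_sd = 0, seed0 = 100,
                          allow_cyclic_every = 0) {
  out <- list()
  seed <- seed0
  shapes <- list(
    list(n_nodes = 7, n_stimuli = 2, n_inhibitables = 1, n_readouts = 2,
         edge_prob = 0.35, max_gate_size = 2),
    list(n_nodes = 8, n_stimuli = 3, n_inhibitables = 0, n_readouts = 3,
         edge_prob = 0.3, max_gate_size = 2),
    list(n_nodes = 8, n_stimuli = 2, n_inhibitables = 1, n_readouts = 3,
         edge_prob = 0.35, max_gate_size = 3),
    list(n_nodes = 6, n_stimuli = 2, n_inhibitables = 1, n_readouts = 2,
         edge_prob = 0.45, max_gate_size = 3))
  while (length(out) < n) {
    seed <- seed + 1
    shape <- shapes[[1 + (seed %% length(shapes))]]
    cyclic <- allow_cyclic_every > 0 &&
      (length(out) + 1) %% allow_cyclic_every == 0
    cfg <- do.call(synth_config, c(shape,
                                   list(noise_sd = noise_sd, seed = seed,
                                        allow_cycles = cyclic)))
    inst <- tryCatch({
      net <- generate_pkn(cfg)
      generate_truth_and_data(net, cfg)
    }, error = function(e) NULL)
    if (is.null(inst)) next
    E <- nrow(inst$hypergraph$edges)
    if (E < 4 || E > max_edges) next
    if (all(is.na(inst$dataset$values))) next
    inst$config <- cfg
    out[[length(out) + 1]] <- inst
  }
  out
}
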