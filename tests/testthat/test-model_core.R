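test_that("simulation propagates the cascade and honors NOT literals", {
  hg <- toy1_hypergraph()
  truth <- logic_model(hg, toy1_truth_selected(hg))
  s <- simulate_model(truth, list(stimulus_on = "a", inhibitor_on = character()))
  expect_equal(s[["c"]], 1L)
  expect_equal(s[["d"]], 1L)
  s <- simulate_model(truth, list(stimulus_on = c("a", "b"),
                                  inhibitor_on = character()))
  expect_equal(s[["c"]], 1L)
  expect_equal(s[["d"]], 0L)  # NOT b blocks d
  s <- simulate_model(truth, list(stimulus_on = character(),
                                  inhibitor_on = character()))
  expect_equal(unname(s[c("c", "d")]), c(0L, 0L))
})

test_that("an inhibitor clamp overrides the node's rule", {
  hg <- toy1_hypergraph(inhibit_c = TRUE)
  truth <- logic_model(hg, toy1_truth_selected(hg))
  s <- simulate_model(truth, list(stimulus_on = "a", inhibitor_on = "c"))
  expect_equal(s[["c"]], 0L)
  expect_equal(s[["d"]], 0L)  # downstream consequence
  expect_error(simulate_model(truth, list(stimulus_on = "a",
                                          inhibitor_on = "zz")),
               "not inhibitable")
})

test_that("simulation agrees with the independent R simulator", {
  withr::local_seed(21)
  for (inst in synth_battery(4, max_edges = 14, seed0 = 400,
                             allow_cyclic_every = 2)) {
    hg <- inst$hypergraph
    for (rep in 1:5) {
      sel <- rbinom(nrow(hg$edges), 1, 0.5)
      stim_on <- hg$stimuli[rbinom(length(hg$stimuli), 1, 0.5) == 1]
      inhib_on <- hg$inhibitables[rbinom(length(hg$inhibitables), 1, 0.5) == 1]
      got <- simulate_model(logic_model(hg, sel),
                            list(stimulus_on = stim_on, inhibitor_on = inhib_on))
      want <- r_simulate(hg, sel, stim_on, inhib_on)
      expect_identical(unname(got), unname(want))
    }
  }
})

test_that("unresolved oscillating nodes are NA and penalized in the score", {
  # b negates itself: with the gate {-b} -> b selected, b oscillates
  net <- pkn(data.frame(source = c("a", "b"), sign = c(1L, -1L),
                        target = c("c", "b")),
             stimuli = "a", readouts = c("b", "c"))
  hg <- expand_pkn(net, Inf)
  sel <- as.integer(hg$edges$target %in% c("b", "c"))
  s <- simulate_model(logic_model(hg, sel), list(stimulus_on = "a",
                                                 inhibitor_on = character()))
  expect_true(is.na(s[["b"]]))
  expect_equal(s[["c"]], 1L)
  ds <- make_dataset(cbind(a = 1L), NULL, cbind(b = 0.5, c = 1))
  sc <- score_model(logic_model(hg, sel), ds)
  # unresolved b contributes the maximum residual 1; c fits exactly
  expect_equal(sc$sse_scaled, 10^4)
  expect_equal(sc$mse, 0.5)
})

test_that("scoring arithmetic is exact on the discretization grid", {
  net <- pkn(data.frame(source = "a", sign = 1L, target = "c"),
             stimuli = "a", readouts = "c")
  hg <- expand_pkn(net, Inf)
  model <- logic_model(hg, 1L)
  ds <- make_dataset(cbind(a = c(1L, 0L)), NULL, cbind(c = c(0.91, 0.10)))
  sc <- score_model(model, ds, precision = 2)
  expect_equal(sc$sse_scaled, 81 + 100)
  expect_equal(sc$mse, 0.00905)  # (0.0081 + 0.01) / 2
  expect_equal(sc$size, 1L)
  # perfect fit and empty model conventions
  ds0 <- make_dataset(cbind(a = c(1L, 0L)), NULL, cbind(c = c(1, 0)))
  expect_equal(score_model(model, ds0)$mse, 0)
  empty <- logic_model(hg, 0L)
  dsz <- make_dataset(cbind(a = c(1L, 0L)), NULL, cbind(c = c(0, 0)))
  sc0 <- score_model(empty, dsz)
  expect_equal(sc0$mse, 0)
  expect_equal(sc0$size, 0L)
  allna <- make_dataset(cbind(a = 1L), NULL, cbind(c = NA_real_))
  expect_error(score_model(model, allna), "no non-missing")
})

test_that("score matches the independent R scorer on random instances", {
  withr::local_seed(33)
  for (inst in synth_battery(3, max_edges = 12, seed0 = 500)) {
    hg <- inst$hypergraph
    ds <- inst$dataset
    ds$values[1, 1] <- NA  # exercise missing handling
    for (rep in 1:4) {
      sel <- rbinom(nrow(hg$edges), 1, 0.4)
      got <- score_model(logic_model(hg, sel), ds)
      want <- r_score(hg, sel, ds)
      expect_equal(got$sse_scaled, want$sse_scaled)
      expect_equal(got$size, want$size)
      expect_equal(got$n_compared, want$n_compared)
    }
  }
})

test_that("score is invariant under row and column permutations", {
  withr::local_seed(5)
  inst <- synth_battery(1, max_edges = 14, seed0 = 600)[[1]]
  ds <- inst$dataset
  sel <- rbinom(nrow(inst$hypergraph$edges), 1, 0.5)
  base <- score_model(logic_model(inst$hypergraph, sel), ds)
  rp <- sample(nrow(ds$values))
  cp <- sample(ncol(ds$values))
  ds2 <- ds
  ds2$stim <- ds$stim[rp, , drop = FALSE]
  ds2$inhib <- ds$inhib[rp, , drop = FALSE]
  ds2$values <- ds$values[rp, cp, drop = FALSE]
  ds2$readouts <- ds$readouts[cp]
  perm <- score_model(logic_model(inst$hypergraph, sel), ds2)
  expect_equal(perm$sse_scaled, base$sse_scaled)
  expect_equal(perm$n_compared, base$n_compared)
})

test_that("model size sums gate input counts and is monotone", {
  hg <- toy1_hypergraph()
  expect_equal(model_size(logic_model(hg, rep(0L, 6))), 0L)
  two_for_c <- as.integer(hg$edges$target == "c" &
                          hg$edges$sources %in% c("+a", "+a;+b"))
  expect_equal(model_size(logic_model(hg, two_for_c)), 3L)  # 1 + 2
  withr::local_seed(9)
  for (rep in 1:10) {
    sel <- rbinom(6, 1, 0.5)
    grown <- sel
    off <- which(grown == 0)
    if (length(off)) grown[off[1]] <- 1L
    expect_gte(model_size(logic_model(hg, grown)),
               model_size(logic_model(hg, sel)))
  }
})
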