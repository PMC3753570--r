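# Hand-built families over the toy hypergraph: rows = models, columns = gates.
fam_from_models <- function(hg, models, dataset = toy1_dataset()) {
  sc <- score_models(hg, models, dataset)
  structure(list(hypergraph = hg, models = models,
                 sse_scaled = sc$sse_scaled, size = sc$size, mse = sc$mse,
                 n_compared = sc$n_compared[1],
                 mse_opt = min(sc$mse), sse_opt = min(sc$sse_scaled),
                 size_opt = min(sc$size[sc$sse_scaled == min(sc$sse_scaled)]),
                 config = enumeration_config()),
            class = "model_family")
}

test_that("hyperedge frequencies count presence exactly", {
  hg <- toy1_hypergraph()
  one <- fam_from_models(hg, matrix(toy1_truth_selected(hg), nrow = 1))
  fr <- hyperedge_frequencies(one)
  expect_equal(fr$frequency, as.numeric(toy1_truth_selected(hg)))
  expect_setequal(fr$class[fr$frequency == 1], "always")
  expect_setequal(fr$class[fr$frequency == 0], "never")
  # family {{e1,e3},{e2,e3}} -> e3: 1, e1: 0.5, e2: 0.5
  models <- rbind(c(1L, 0L, 1L, 0L, 0L, 0L),
                  c(0L, 1L, 1L, 0L, 0L, 0L))
  fr2 <- hyperedge_frequencies(fam_from_models(hg, models))
  expect_equal(fr2$frequency, c(0.5, 0.5, 1, 0, 0, 0))
  expect_equal(fr2$class, c("variable", "variable", "always",
                            "never", "never", "never"))
  # bookkeeping identity: sum of frequencies = mean model gate count
  expect_equal(sum(fr2$frequency), mean(rowSums(models)))
})

test_that("mutually inclusive groups are equivalence classes of presence columns", {
  hg <- toy1_hypergraph()
  models <- rbind(c(1L, 1L, 0L, 0L, 1L, 0L),
                  c(1L, 1L, 0L, 1L, 0L, 0L),
                  c(0L, 0L, 1L, 1L, 0L, 0L))
  gr <- mutually_inclusive_groups(fam_from_models(hg, models))
  expect_equal(gr$group[1], gr$group[2])   # identical columns share a group
  expect_true(gr$group[3] != gr$group[1])
  # reflexive/symmetric/transitive comes free from match(); check coverage
  expect_equal(sort(unique(gr$group)), seq_len(max(gr$group)))
})

test_that("mutually exclusive pairs require exactly-one-side presence", {
  hg <- toy1_hypergraph()
  # {{e1,e3},{e2,e3}}: e1/e2 exclusive, e3 in no pair
  models <- rbind(c(1L, 0L, 1L, 0L, 0L, 0L),
                  c(0L, 1L, 1L, 0L, 0L, 0L))
  pr <- mutually_exclusive_pairs(fam_from_models(hg, models))
  expect_equal(nrow(pr), 1L)
  expect_setequal(c(pr$a_ids, pr$b_ids), c("0", "1"))
  expect_equal(pr$a_frequency + pr$b_frequency, 1)
  # {{e1},{e1,e2}}: e1 always present -> no exclusive pair
  models2 <- rbind(c(1L, 0L, 0L, 0L, 0L, 0L),
                   c(1L, 1L, 0L, 0L, 0L, 0L))
  expect_equal(nrow(mutually_exclusive_pairs(fam_from_models(hg, models2))), 0L)
  # post-hoc verification on an enumerated family with interchangeable gates
  inst <- synth_battery(1, max_edges = 14, noise_sd = 0.1, seed0 = 1500)[[1]]
  fam <- enumerate_models(inst$hypergraph, inst$dataset,
                          enumeration_config(fit_tolerance = 0.1))
  pairs <- mutually_exclusive_pairs(fam)
  if (nrow(pairs)) {
    for (p in seq_len(nrow(pairs))) {
      a <- as.integer(strsplit(pairs$a_ids[p], ";")[[1]]) + 1L
      b <- as.integer(strsplit(pairs$b_ids[p], ";")[[1]]) + 1L
      a_in <- rowSums(fam$models[, a, drop = FALSE]) == length(a)
      b_in <- rowSums(fam$models[, b, drop = FALSE]) == length(b)
      expect_true(all(xor(a_in, b_in)))
    }
  }
  # co-occurrence oracle: every exclusive pair shows zero co-occurrence
  co <- crossprod(fam$models)
  if (nrow(pairs)) {
    for (p in seq_len(nrow(pairs))) {
      a <- as.integer(strsplit(pairs$a_ids[p], ";")[[1]]) + 1L
      b <- as.integer(strsplit(pairs$b_ids[p], ";")[[1]]) + 1L
      expect_equal(max(co[a, b]), 0)
    }
  }
})

test_that("swapping an exclusive module matches independent rescoring", {
  hg <- toy1_hypergraph()
  # both members set c = a; d alternates between gate {+c} and {+c;-b},
  # which only disagree at (a=1, b=1) -- where the d measurement is missing,
  # so the two modules are score-equivalent but not prediction-equivalent
  ds <- toy1_dataset()
  ds$values[4, "d"] <- NA
  c_gate <- as.integer(hg$edges$sources == "+a")
  mA <- c_gate | as.integer(hg$edges$sources == "+c")
  mB <- c_gate | as.integer(hg$edges$sources == "+c;-b")
  models <- rbind(as.integer(mA), as.integer(mB))
  fam <- fam_from_models(hg, models, ds)
  pairs <- mutually_exclusive_pairs(fam)
  expect_equal(nrow(pairs), 1L)
  sw <- swap_effect(fam, pairs[1, ], ds)
  expect_equal(nrow(sw), 1L)  # one member fully contains side A
  # the swap turns member A into member B: delta from direct rescoring
  direct <- score_models(hg, models, ds)
  expect_equal(sw$mse_delta, direct$mse[2] - direct$mse[1])
  expect_equal(sw$mse_delta, 0)            # score-equivalent by construction
  expect_equal(sw$changed_fraction, 0.25)  # predictions differ at 1 of 4
})

test_that("swap reports the fraction of conditions with changed readouts", {
  hg <- toy1_hypergraph()
  ds <- toy1_dataset()
  # family alternating d's gate between {+c} and {-b}: predictions differ
  base <- as.integer(hg$edges$sources == "+a")
  mA <- base | as.integer(hg$edges$sources == "+c")
  mB <- base | as.integer(hg$edges$sources == "-b" & hg$edges$target == "d")
  fam <- fam_from_models(hg, rbind(as.integer(mA), as.integer(mB)), ds)
  pairs <- mutually_exclusive_pairs(fam)
  expect_equal(nrow(pairs), 1L)
  sw <- swap_effect(fam, pairs[1, ], ds)
  # d = c(=a) vs d = NOT b: differ at (0,0) and (1,1): half the conditions
  expect_equal(sw$changed_fraction, 0.5)
  direct <- score_models(hg, rbind(as.integer(mA), as.integer(mB)), ds)
  expect_equal(sw$mse_delta, direct$mse[2] - direct$mse[1])
})
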