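test_that("the toy cascade has the unique lexicographic optimum (0, 3)", {
  hg <- toy1_hypergraph()
  ds <- toy1_dataset()
  opt <- find_optimum(hg, ds)
  expect_equal(opt$mse_opt, 0)
  expect_equal(opt$size_opt, 3L)
  expect_equal(opt$witness$selected, toy1_truth_selected(hg))
  fam <- enumerate_models(hg, ds, enumeration_config(fit_tolerance = 0))
  oracle <- brute_family(hg, ds, eps = 0, scorer = "r")
  expect_equal(unname(fam$models), unname(oracle$models))
})

test_that("all-zero observations admit the empty model as optimum", {
  hg <- toy1_hypergraph()
  stim <- cbind(a = c(0L, 1L), b = c(0L, 1L))
  ds <- make_dataset(stim, NULL, cbind(c = c(0, 0), d = c(0, 0)))
  opt <- find_optimum(hg, ds)
  expect_equal(opt$mse_opt, 0)
  expect_equal(opt$size_opt, 0L)
  expect_equal(sum(opt$witness$selected), 0L)
  fam <- enumerate_models(hg, ds,
                          enumeration_config(fit_tolerance = 0, size_bound = 0))
  expect_equal(nrow(fam$models), 1L)
  expect_equal(sum(fam$models), 0L)
})

test_that("enumeration equals the pure-R brute force on tiny instances", {
  for (inst in synth_battery(3, max_edges = 9, seed0 = 700)) {
    hg <- inst$hypergraph
    ds <- inst$dataset
    for (eps in c(0, 0.1)) {
      fam <- enumerate_models(hg, ds, enumeration_config(fit_tolerance = eps))
      oracle <- brute_family(hg, ds, eps = eps, scorer = "r")
      expect_equal(unname(fam$models), unname(oracle$models))
      expect_equal(fam$sse_scaled, oracle$sse)
      expect_equal(fam$size, oracle$size)
    }
  }
})

test_that("a perturbed observation keeps oracle equality and tolerance nesting", {
  hg <- toy1_hypergraph()
  ds <- toy1_dataset()
  ds$values[1, "c"] <- ds$values[1, "c"] + 0.1
  fam0 <- enumerate_models(hg, ds, enumeration_config(fit_tolerance = 0))
  fam10 <- enumerate_models(hg, ds, enumeration_config(fit_tolerance = 0.10))
  oracle <- brute_family(hg, ds, eps = 0.10, scorer = "r")
  expect_equal(unname(fam10$models), unname(oracle$models))
  expect_true(all(model_key(fam0$models) %in% model_key(fam10$models)))
  expect_true(all(fam10$sse_scaled <= 1.1 * fam10$sse_opt + 1e-9))
})

test_that("families are nested in the fit tolerance", {
  for (inst in synth_battery(3, max_edges = 14, noise_sd = 0.1, seed0 = 800)) {
    fams <- lapply(c(0, 0.02, 0.1), function(eps)
      enumerate_models(inst$hypergraph, inst$dataset,
                       enumeration_config(fit_tolerance = eps)))
    keys <- lapply(fams, function(f) model_key(f$models))
    expect_true(all(keys[[1]] %in% keys[[2]]))
    expect_true(all(keys[[2]] %in% keys[[3]]))
  }
})

test_that("every enumerated model re-scores within the stated bounds", {
  inst <- synth_battery(1, max_edges = 14, noise_sd = 0.1, seed0 = 900)[[1]]
  fam <- enumerate_models(inst$hypergraph, inst$dataset,
                          enumeration_config(fit_tolerance = 0.1))
  rescored <- score_models(inst$hypergraph, fam$models, inst$dataset)
  expect_equal(rescored$sse_scaled, fam$sse_scaled)
  expect_true(all(rescored$sse_scaled <= 1.1 * fam$sse_opt + 1e-9))
  expect_true(all(rescored$size <= fam$size_opt))
  expect_false(anyDuplicated(model_key(fam$models)) > 0)
})

test_that("enumeration output is deterministic and canonically ordered", {
  inst <- synth_battery(1, max_edges = 14, noise_sd = 0.05, seed0 = 1000)[[1]]
  cfg <- enumeration_config(fit_tolerance = 0.1)
  f1 <- enumerate_models(inst$hypergraph, inst$dataset, cfg)
  f2 <- enumerate_models(inst$hypergraph, inst$dataset, cfg)
  expect_identical(f1$models, f2$models)
  expect_identical(f1$sse_scaled, f2$sse_scaled)
  k <- model_key(f1$models)
  expect_identical(k, k[order(k)])
  p1 <- withr::local_tempfile(fileext = ".csv")
  write_family(f1, p1)
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_family(f2, p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("the family safety cap and the external backend error cleanly", {
  hg <- toy1_hypergraph()
  stim <- cbind(a = c(0L, 1L), b = c(0L, 1L))
  ds <- make_dataset(stim, NULL, cbind(c = c(0, 0), d = c(0, 0)))
  # huge tolerance + large size bound admits very many models; cap must trip
  expect_error(enumerate_models(hg, ds,
                 enumeration_config(fit_tolerance = 1e6, size_bound = 99,
                                    max_models = 3)),
               "cap")
  expect_error(enumerate_models(hg, ds,
                 enumeration_config(backend = "external")),
               "external")
})

test_that("the MSE spectrum matches a brute-force recount", {
  inst <- synth_battery(1, max_edges = 12, noise_sd = 0.1, seed0 = 1100)[[1]]
  fam <- enumerate_models(inst$hypergraph, inst$dataset,
                          enumeration_config(fit_tolerance = 0.1))
  spec <- family_mse_spectrum(fam)
  expect_equal(sum(spec$count), nrow(fam$models))
  expect_false(is.unsorted(spec$mse, strictly = TRUE))
  oracle <- brute_family(inst$hypergraph, inst$dataset, eps = 0.1, scorer = "r")
  otab <- table(oracle$sse)
  expect_equal(spec$sse_scaled, as.numeric(names(otab)))
  expect_equal(spec$count, as.integer(otab))
  single <- enumerate_models(toy1_hypergraph(), toy1_dataset(),
                             enumeration_config())
  sp1 <- family_mse_spectrum(single)
  expect_equal(nrow(sp1), 1L)
  expect_equal(sp1$count, 1L)
})
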