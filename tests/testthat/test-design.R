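# Build bare GTT fixtures directly: k inputs (first ns are stimuli),
# random or hand-set prediction tables on the full factorial grid.
make_gtt <- function(table, ns = 1) {
  k <- round(log2(nrow(table)))
  stopifnot(2^k == nrow(table))
  r <- 0:(2^k - 1)
  a <- vapply(seq_len(k), function(j) as.integer((r %/% 2^(k - j)) %% 2),
              integer(2^k))
  a <- matrix(as.integer(a), ncol = k)
  stimuli <- paste0("s", seq_len(ns))
  inhibitables <- if (k > ns) paste0("x", seq_len(k - ns)) else character()
  colnames(a) <- c(stimuli, if (length(inhibitables))
    paste0(inhibitables, "i"))
  structure(list(stimuli = stimuli, inhibitables = inhibitables,
                 readouts = colnames(table), assignments = a, table = table,
                 members = integer()), class = "gtt")
}

# Exhaustive minimum-cover oracle: smallest condition subset separating all
# separable pairs, found by breadth-first search over subset sizes.
exhaustive_min_cover <- function(gtts) {
  sep <- boolfam:::separation_matrix(gtts)
  cover_pairs <- which(colSums(sep$S) > 0)
  if (!length(cover_pairs)) return(0L)
  useful <- which(rowSums(sep$S[, cover_pairs, drop = FALSE]) > 0)
  for (size in seq_len(length(useful))) {
    for (comb in utils::combn(useful, size, simplify = FALSE)) {
      if (all(colSums(sep$S[comb, cover_pairs, drop = FALSE]) > 0))
        return(size)
    }
  }
  stop("unreachable")
}

test_that("two behaviors differing at one condition need exactly that condition", {
  tab <- matrix(0L, 4, 2, dimnames = list(NULL, c("r1", "r2")))
  g1 <- make_gtt(tab, ns = 2)
  g2 <- g1
  g2$table[3, 2] <- 1L
  res <- minimal_discriminating_set(list(g1, g2))
  expect_equal(res$conditions, 3L)
  expect_true(res$exact)
  expect_equal(ncol(res$inseparable), 0L)
})

test_that("private pairwise differences force covers of matching size", {
  # unit-vector behaviors over one readout: A=000, B=100, C=010, D=001 on
  # conditions 1..3; pairs with A are private to one condition each, so any
  # cover must contain conditions 1, 2 and 3
  base <- matrix(0L, 8, 1, dimnames = list(NULL, "r"))
  mk <- function(on) { g <- make_gtt(base, ns = 3); g$table[on, 1] <- 1L; g }
  gA <- make_gtt(base, ns = 3)
  gtts <- list(gA, mk(1), mk(2), mk(3))
  res <- minimal_discriminating_set(gtts)
  expect_true(res$exact)
  expect_equal(sort(res$conditions), c(1L, 2L, 3L))
  expect_equal(exhaustive_min_cover(gtts), 3L)
  # for three behaviors the pair differences can never be fully private
  # (B != C forces a difference from A at the same condition): min cover 2
  tri <- list(mk(1), mk(2), mk(3))
  res3 <- minimal_discriminating_set(tri)
  expect_true(res3$exact)
  expect_equal(length(res3$conditions), exhaustive_min_cover(tri))
  expect_equal(length(res3$conditions), 2L)
})

test_that("exact covers equal exhaustive minima; greedy is never smaller", {
  withr::local_seed(91)
  for (rep in 1:12) {
    n_gtt <- sample(3:6, 1)
    k <- sample(2:3, 1)
    m <- sample(2:3, 1)
    gtts <- lapply(seq_len(n_gtt), function(i) {
      tab <- matrix(rbinom(2^k * m, 1, 0.5), 2^k, m,
                    dimnames = list(NULL, paste0("r", seq_len(m))))
      make_gtt(tab, ns = 1)
    })
    exact <- minimal_discriminating_set(gtts, mode = "exact")
    greedy <- minimal_discriminating_set(gtts, mode = "greedy")
    expect_true(exact$exact)
    expect_equal(length(exact$conditions), exhaustive_min_cover(gtts))
    expect_gte(length(greedy$conditions), length(exact$conditions))
    expect_gte(length(exact$conditions), exact$lower_bound)
    # verification: every separable pair is separated by the returned set
    sep <- boolfam:::separation_matrix(gtts)
    coverable <- which(colSums(sep$S) > 0)
    expect_true(all(colSums(sep$S[exact$conditions, coverable,
                                  drop = FALSE]) > 0))
  }
})

test_that("inseparable pairs are reported and excluded", {
  tab <- matrix(0L, 4, 1, dimnames = list(NULL, "r"))
  g1 <- make_gtt(tab, ns = 2)
  g2 <- g1                       # identical to g1: inseparable pair
  g3 <- make_gtt(tab, ns = 2)
  g3$table[2, 1] <- 1L
  res <- minimal_discriminating_set(list(g1, g2, g3))
  expect_equal(ncol(res$inseparable), 1L)
  expect_equal(sort(res$inseparable[, 1]), c(1L, 2L))
  expect_equal(res$conditions, 2L)
})

test_that("unresolved predictions never separate a pair", {
  tab1 <- matrix(0L, 4, 1, dimnames = list(NULL, "r"))
  tab2 <- tab1
  tab1[2, 1] <- NA_integer_   # unresolved vs 0: not a separation
  g1 <- make_gtt(tab1, ns = 2)
  g2 <- make_gtt(tab2, ns = 2)
  res <- minimal_discriminating_set(list(g1, g2))
  expect_equal(ncol(res$inseparable), 1L)
  expect_equal(length(res$conditions), 0L)
})

test_that("single-experiment ranking is lexicographic and complete", {
  tab <- matrix(0L, 8, 2, dimnames = list(NULL, c("r1", "r2")))
  g1 <- make_gtt(tab, ns = 2)
  g2 <- g1; g2$table[2, 1] <- 1L; g2$table[8, 1] <- 1L
  g3 <- g1; g3$table[8, 2] <- 1L
  # condition 8 (all inputs on) separates all 3 pairs; condition 2 only one
  res <- best_single_experiments(list(g1, g2, g3))
  expect_equal(res$ranking$condition[1], 8L)
  expect_equal(res$ranking$n_pairs_separated[1], 3L)
  expect_equal(res$top$condition, 8L)
  # among equal separation counts, fewer active perturbations rank first
  g4 <- g1; g4$table[c(2, 8), 1] <- 1L
  res2 <- best_single_experiments(list(g1, g4))
  expect_equal(res2$ranking$n_pairs_separated[1:2], c(1L, 1L))
  expect_equal(res2$ranking$condition[1], 2L)  # 1 active input beats 3
  expect_equal(res2$top$condition, 2L)
  # ranking covers every condition exactly once (total preorder, deterministic)
  expect_setequal(res$ranking$condition, 1:8)
  res_again <- best_single_experiments(list(g1, g2, g3))
  expect_identical(res, res_again)
})
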