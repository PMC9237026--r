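test_that("curveball preserves marginals and fixes degenerate cases", {
  # checkerboard: only two matrices share these marginals
  A <- matrix(c(1L, 0L, 0L, 1L), 2)
  set.seed(1)
  for (i in 1:20) {
    B <- curveball(A, 10)
    expect_true(identical(B, matrix(c(1L, 0L, 0L, 1L), 2)) ||
                  identical(B, matrix(c(0L, 1L, 1L, 0L), 2)))
    expect_equal(rowSums(B), rowSums(A))
    expect_equal(colSums(B), colSums(A))
  }

  # all-ones: nothing to swap
  ones <- matrix(1L, 3, 3)
  expect_equal(curveball(ones, 100, seed = 2), ones)

  expect_error(curveball(A, -1), "n_trades")
  expect_error(curveball(matrix(2, 2, 2), 1), "0/1")
})

test_that("curveball marginals hold on every draw from a real topology", {
  web <- niche_model(S = 30, C = 0.08, seed = 2)
  A <- binarize(to_diet_matrix(web))
  set.seed(3)
  for (i in 1:50) {
    B <- curveball(A, 150)
    expect_equal(unname(rowSums(B)), unname(rowSums(A)))
    expect_equal(unname(colSums(B)), unname(colSums(A)))
  }
})

test_that("curveball samples fixed-marginal matrices uniformly (4x4 enumeration)", {
  # all 90 binary 4x4 matrices with row and column sums (2,2,2,2)
  combs <- utils::combn(4, 2)
  cols <- lapply(1:6, function(i) { v <- integer(4); v[combs[, i]] <- 1L; v })
  mats <- list()
  for (a in 1:6) for (b in 1:6) for (cc in 1:6) for (d in 1:6) {
    M <- cbind(cols[[a]], cols[[b]], cols[[cc]], cols[[d]])
    if (all(rowSums(M) == 2)) mats[[length(mats) + 1]] <- M
  }
  expect_length(mats, 90)
  key <- vapply(mats, function(M) paste(M, collapse = ""), character(1))
  A <- mats[[1]]
  counts <- stats::setNames(numeric(90), key)
  set.seed(901)
  for (i in 1:20000) {
    B <- curveball(A, 50)
    k <- paste(B, collapse = "")
    counts[k] <- counts[k] + 1
  }
  expect_true(all(counts > 0))
  expect_gt(stats::chisq.test(counts)$p.value, 0.01)
})

test_that("diagonal pinning keeps cannibal links invariant while mixing", {
  web <- niche_model(S = 30, C = 0.08, seed = 2)
  A <- binarize(to_diet_matrix(web))
  set.seed(5)
  changed <- 0
  for (i in 1:30) {
    B <- curveball(A, 200, fix_diagonal = TRUE)
    expect_equal(unname(diag(B)), unname(diag(A)))
    expect_equal(unname(rowSums(B)), unname(rowSums(A)))
    expect_equal(unname(colSums(B)), unname(colSums(A)))
    changed <- changed + sum(B != A)
  }
  expect_gt(changed, 0)  # still actually randomizes
})

test_that("weight shuffles permute each predator's diet multiset exactly", {
  web <- niche_model(S = 40, C = 0.07, seed = 3)
  Q <- to_diet_matrix(web)
  Qs <- shuffle_weights(Q, seed = 4)
  cons <- which(colSums(unclass(Q)) > 0)
  for (j in cons) {
    expect_equal(sort(unname(Q[Q[, j] > 0, j])),
                 sort(unname(Qs[Qs[, j] > 0, j])))
  }
  expect_lt(max(abs(colSums(Qs)[cons] - 1)), 1e-12)
  # single-prey columns unchanged
  single <- cons[colSums(unclass(Q) > 0)[cons] == 1]
  if (length(single)) {
    expect_equal(unclass(Q)[, single], unclass(Qs)[, single])
  }
})

test_that("randomized webs preserve per-node in- and out-degree", {
  web <- sjg_like_scenario_pair(seed = 2)$nonfishing
  d0 <- degree_table(web)
  d0 <- d0[order(d0$id), ]
  set.seed(6)
  for (i in 1:10) {
    rw <- randomize_web(web)
    d1 <- degree_table(rw)
    d1 <- d1[order(d1$id), ]
    expect_equal(d1$in_degree, d0$in_degree)
    expect_equal(d1$out_degree, d0$out_degree)
  }
})

test_that("null distributions respect bounds, invariance and reproducibility", {
  # metric bound: mTL >= 1 always
  nd <- null_distribution(chain3(), "mTL", n = 5, seed = 1, n_trades = 15)
  expect_length(nd$values, 5)
  expect_true(all(nd$values >= 1))

  # curveball-invariant web: every draw equals the empirical value
  full <- food_web(links = expand.grid(predator = c("A", "B"),
                                       prey = c("C", "D"),
                                       stringsAsFactors = FALSE),
                   require_basal = TRUE)
  emp <- mean_trophic_level(trophic_levels(full, weighted = FALSE))
  ndf <- null_distribution(full, "mTL", n = 6, seed = 2, n_trades = 50)
  expect_true(all(abs(ndf$values - emp) < 1e-12))

  # bit-for-bit reproducibility from the recipe
  web <- niche_model(S = 25, C = 0.08, seed = 4)
  n1 <- null_distribution(web, "omnivory", n = 8, weighted = TRUE, seed = 9)
  n2 <- null_distribution(web, "omnivory", n = 8, weighted = TRUE, seed = 9)
  expect_identical(n1$values, n2$values)
  n3 <- null_distribution(web, "omnivory", n = 8, weighted = TRUE, seed = 10)
  expect_false(identical(n1$values, n3$values))

  expect_error(null_distribution(web, "degree", n = 5), "arg")
})
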