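test_that("sampled Jacobians carry the web's sign structure", {
  web <- food_web(links = data.frame(predator = "A", prey = "B", weight = 1))
  set.seed(1)
  J <- sample_jacobian(web)
  # order (A, B): A benefits from B, B harmed by A, both self-limited
  expect_gt(J["A", "B"], 0)
  expect_lt(J["B", "A"], 0)
  expect_lt(J["A", "A"], 0)
  expect_lt(J["B", "B"], 0)

  # weighted: magnitudes bounded by the diet proportion
  web2 <- food_web(links = data.frame(predator = c("A", "A"),
                                      prey = c("B", "C"),
                                      weight = c(0.2, 0.8)))
  set.seed(2)
  for (i in 1:20) {
    Jw <- sample_jacobian(web2, community_matrix_spec(weighted = TRUE))
    expect_lte(abs(Jw["A", "B"]), 0.2)
    expect_lte(abs(Jw["B", "A"]), 0.2)
  }

  # empty-link web: diagonal negative, off-diagonal zero
  wb <- food_web(nodes = c("X", "Y"), links = NULL)
  set.seed(3)
  J0 <- sample_jacobian(wb)
  expect_true(all(diag(J0) < 0))
  expect_true(all(J0[row(J0) != col(J0)] == 0))
})

test_that("local stability follows the eigenvalue real-part criterion", {
  expect_true(is_locally_stable(diag(c(-1, -2))))
  expect_false(is_locally_stable(matrix(c(0, -1, 1, 0), 2)))  # +/- i pair
  # trace -2, det 21 -> complex pair with real part -1
  expect_true(is_locally_stable(matrix(c(-1, 4, -5, -1), 2)))
  expect_false(is_locally_stable(matrix(0, 1, 1)))  # zero real part
  expect_error(is_locally_stable(matrix(0, 1, 2)), "square")
})

test_that("sign-stable modules give QSS exactly 1", {
  # 2-species predator-prey: trace < 0, det = ad + bc > 0 for all magnitudes
  web <- food_web(links = data.frame(predator = "A", prey = "B", weight = 1))
  expect_equal(qss(web, n = 500, seed = 1)$proportion_stable, 1)
  # single self-limited node
  one <- food_web(nodes = "X", links = NULL)
  expect_equal(qss(one, n = 100, seed = 2)$proportion_stable, 1)
})

test_that("QSS agrees with an independent Routh-Hurwitz Monte-Carlo oracle", {
  # 3-node omnivory module: A eats B and C, B eats C; all self-limited.
  # Oracle: vectorised draws with stability decided by the 3x3
  # Routh-Hurwitz conditions (a1 > 0, a3 > 0, a1 a2 > a3) on the
  # characteristic polynomial, never touching the package's sampler.
  web <- omnivory3()
  oracle <- function(n, seed) {
    set.seed(seed)
    dA <- -runif(n); dB <- -runif(n); dC <- -runif(n)
    ab <- runif(n); ba <- -runif(n)   # A benefits from B / B harmed
    ac <- runif(n); ca <- -runif(n)
    bc <- runif(n); cb <- -runif(n)
    a1 <- -(dA + dB + dC)
    m12 <- dA * dB - ab * ba
    m13 <- dA * dC - ac * ca
    m23 <- dB * dC - bc * cb
    a2 <- m12 + m13 + m23
    det <- dA * (dB * dC - bc * cb) - ab * (ba * dC - bc * ca) +
      ac * (ba * cb - dB * ca)
    a3 <- -det
    mean(a1 > 0 & a3 > 0 & a1 * a2 > a3)
  }
  p_ref <- oracle(1e6, 2024)
  r <- qss(web, n = 10000, seed = 77)
  se <- sqrt(p_ref * (1 - p_ref) / 10000)
  expect_lt(abs(r$proportion_stable - p_ref), 3 * se)
})

test_that("QSS runs are seed-deterministic and consistent across seeds", {
  web <- niche_model(S = 20, C = 0.1, seed = 3)
  r1 <- qss(web, n = 400, seed = 5)
  r2 <- qss(web, n = 400, seed = 5)
  expect_identical(r1$proportion_stable, r2$proportion_stable)
  expect_equal(r1$n_stable / r1$n_samples, r1$proportion_stable)
  ps <- vapply(1:8, function(s) qss(web, n = 400, seed = s)$proportion_stable,
               numeric(1))
  pbar <- mean(ps)
  tol <- 4 * sqrt(pbar * (1 - pbar) / 400)
  expect_true(all(abs(ps - pbar) <= tol + 1e-12))
  expect_error(qss(web, n = 0), "n must be")
})

test_that("stronger self-limitation never lowers the expected stable fraction", {
  web <- niche_model(S = 20, C = 0.1, seed = 6)
  scales <- c(0.5, 1, 2, 4)
  means <- vapply(seq_along(scales), function(i) {
    mean(vapply(1:6, function(s) {
      qss(web, n = 150, seed = 10 * i + s,
          spec = community_matrix_spec(diag_scale = scales[i]))$proportion_stable
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(means) >= -0.02))  # monotone trend, small MC slack
})

test_that("mean QSS does not increase with connectance on niche webs", {
  qbar <- function(C) {
    mean(vapply(1:6, function(s) {
      web <- niche_model(S = 18, C = C, seed = 100 + s)
      qss(web, n = 150, seed = 200 + s)$proportion_stable
    }, numeric(1)))
  }
  q_lo <- qbar(0.06)
  q_hi <- qbar(0.16)
  expect_gte(q_lo, q_hi - 0.02)
})

test_that("keep_max_re returns the spectral abscissa sample", {
  web <- omnivory3()
  r <- qss(web, n = 50, seed = 9, keep_max_re = TRUE)
  expect_length(r$max_eigenvalue_sample, 50)
  expect_equal(mean(r$max_eigenvalue_sample < -1e-10), r$proportion_stable)
})
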