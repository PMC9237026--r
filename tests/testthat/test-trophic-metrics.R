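test_that("trophic levels solve closed forms on chains and branches", {
  tl <- trophic_levels(chain3())
  expect_equal(unclass(tl)[c("A", "B", "C")], c(A = 3, B = 2, C = 1))

  # hand elimination: TL_C = 1, TL_B = 2, TL_A = 1 + 0.5*2 + 0.5*1 = 2.5
  tl2 <- trophic_levels(diamond3())
  expect_equal(unclass(tl2)[c("A", "B", "C")], c(A = 2.5, B = 2, C = 1))

  # residual of the defining linear system
  web <- niche_model(S = 40, C = 0.07, seed = 4)
  Q <- to_diet_matrix(web)
  tl3 <- trophic_levels(Q)
  res <- (diag(nrow(Q)) - t(unclass(Q))) %*% unclass(tl3) - 1
  expect_lt(max(abs(res)), 1e-9)
  expect_true(all(tl3 >= 1))
})

test_that("weighted and unweighted levels coincide exactly under equal shares", {
  web <- niche_model(S = 30, C = 0.08, seed = 7, diet_concentration = NULL)
  expect_equal(c(unclass(trophic_levels(web, weighted = TRUE))),
               c(unclass(trophic_levels(web, weighted = FALSE))))
  # and differ (generically) once diets are skewed
  web2 <- assign_diets(web, diet_concentration = 0.5, seed = 1)
  expect_false(isTRUE(all.equal(
    c(unclass(trophic_levels(web2, weighted = TRUE))),
    c(unclass(trophic_levels(web2, weighted = FALSE))))))
})

test_that("a consumer loop with no basal access names its component in the error", {
  web <- two_cycles()
  expect_error(trophic_levels(web), "singular")
  expect_error(trophic_levels(web), "a, b, c")
})

test_that("mean trophic level averages the requested node set", {
  tl <- trophic_levels(chain3())
  expect_equal(mean_trophic_level(tl), 2)
  # chain of 3 plus isolated basal D -> mean of {1,2,3,1} = 1.75
  web <- food_web(nodes = c("A", "B", "C", "D"),
                  links = data.frame(predator = c("A", "B"),
                                     prey = c("B", "C"), weight = 1))
  expect_equal(mean_trophic_level(trophic_levels(web)), 1.75)
  expect_equal(mean_trophic_level(trophic_levels(web), include = "consumers"),
               2.5)
  # all-basal web -> 1
  wb <- food_web(nodes = c("X", "Y"), links = NULL)
  expect_equal(mean_trophic_level(trophic_levels(wb)), 1)
  expect_error(mean_trophic_level(tl, include = character()), "empty")
})

test_that("unweighted omnivory counts consumers spanning more than epsilon", {
  # pure chain: single-prey consumers, never omnivorous
  expect_equal(omnivory(chain3()), 0)

  # A spans prey TLs {1, 2}: omnivorous at eps 0.5, not at eps 1.5
  web <- omnivory3()
  Q <- to_diet_matrix(web)
  expect_equal(omnivory(Q, epsilon = 0.5), 1 / 3)
  expect_equal(omnivory(Q, epsilon = 1.5), 0)

  # 5-node case, exhaustive hand check: only A omnivorous -> 1/5
  web5 <- food_web(links = data.frame(
    predator = c("A", "A", "B", "D"),
    prey = c("B", "C", "C", "E"),
    weight = c(0.5, 0.5, 1, 1)))
  expect_equal(omnivory(to_diet_matrix(web5), epsilon = 0.5), 0.2)

  expect_error(omnivory(Q, epsilon = -1), "epsilon")
})

test_that("unweighted omnivory ignores diet-weight perturbations", {
  base <- omnivory3(c(0.5, 0.5))
  skew <- omnivory3(c(0.9, 0.1))
  # topology identical; unweighted index must agree despite weights
  expect_equal(omnivory(to_diet_matrix(base), weighted = FALSE, epsilon = 0.5),
               omnivory(to_diet_matrix(skew), weighted = FALSE, epsilon = 0.5))
})

test_that("weighted omnivory is the mean diet-weighted variance of prey TLs", {
  web <- omnivory3(c(0.3, 0.7))
  Q <- to_diet_matrix(web)
  tls <- trophic_levels(Q, weighted = TRUE)
  # only A has >1 prey: prey TLs {B: 2, C: 1} with weights {0.3, 0.7}
  tbar <- 0.3 * 2 + 0.7 * 1
  vA <- 0.3 * (2 - tbar)^2 + 0.7 * (1 - tbar)^2
  # B has one prey -> variance 0; mean over consumers {A, B}
  expect_equal(omnivory(Q, tls, weighted = TRUE), (vA + 0) / 2)
})

test_that("degree table counts incident links and sorts by degree then id", {
  dt <- degree_table(chain3())
  expect_equal(dt$degree[dt$id == "B"], 2)
  expect_equal(dt$degree[dt$id %in% c("A", "C")], c(1, 1))
  expect_equal(dt$id[1], "B")

  star <- food_web(links = data.frame(predator = "hub",
                                      prey = paste0("p", 1:4),
                                      weight = 0.25))
  expect_equal(degree_table(star)$degree[1], 4)
})

test_that("trophic-class fractions partition the node set", {
  expect_equal(tl_class_fractions(chain3()),
               c(top = 33, intermediate = 33, basal = 33))
  expect_equal(unname(tl_class_fractions(chain3(), digits = NULL)),
               rep(100 / 3, 3))
  wb <- food_web(nodes = c("X", "Y"), links = NULL)
  expect_equal(tl_class_fractions(wb), c(top = 0, intermediate = 0, basal = 100))
  web <- niche_model(S = 50, C = 0.06, seed = 9)
  expect_equal(sum(tl_class_fractions(web, digits = NULL)), 100)
})

test_that("adding a new top predator never decreases the maximum TL", {
  for (s in 1:5) {
    web <- niche_model(S = 25, C = 0.08, seed = s)
    m0 <- max(trophic_levels(web))
    prey <- web$nodes$id[1:3]
    aug <- food_web(nodes = rbind(web$nodes,
                                  data.frame(id = "TOP", label = "TOP",
                                             kind = "species")),
                    links = rbind(web$links,
                                  data.frame(predator = "TOP", prey = prey,
                                             weight = 1 / 3)))
    expect_gte(max(trophic_levels(aug)), m0 - 1e-12)
  }
})
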