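test_that("edge-list reading builds a validated web, with and without weights", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("predator,prey,weight", "A,B,0.6", "A,C,0.4", "B,C,1.0"), f)
  web <- read_edge_list(f)
  expect_s3_class(web, "food_web")
  expect_equal(nrow(web$nodes), 3)
  expect_equal(nrow(web$links), 3)
  sums <- tapply(web$links$weight, web$links$predator, sum)
  expect_equal(as.numeric(sums[c("A", "B")]), c(1, 1))

  # weight column absent -> equal shares
  f2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("predator,prey", "A,B", "A,C", "B,C"), f2)
  web2 <- read_edge_list(f2)
  wA <- web2$links$weight[web2$links$predator == "A"]
  expect_equal(wA, c(0.5, 0.5))

  # custom column mapping
  f3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("consumer,resource,diet", "A,B,1"), f3)
  web3 <- read_edge_list(f3, col_map = c(predator = "consumer",
                                         prey = "resource", weight = "diet"))
  expect_equal(web3$links$predator, "A")
})

test_that("diet-sum deviations are renormalized within tolerance, rejected beyond", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("predator,prey,weight", "A,B,0.6004", "A,C,0.4"), f)
  web <- read_edge_list(f)  # deviation 4e-4 <= 1e-3 -> renormalized
  expect_equal(sum(web$links$weight), 1, tolerance = 1e-12)

  f2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("predator,prey,weight", "A,B,0.8", "A,C,0.4"), f2)
  expect_error(read_edge_list(f2), "deviate")
})

test_that("malformed inputs error: empty file, duplicate link, missing endpoint", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines("predator,prey,weight", f)
  expect_error(read_edge_list(f), "empty")

  expect_error(
    food_web(links = data.frame(predator = c("A", "A"), prey = c("B", "B"),
                                weight = c(0.5, 0.5))),
    "duplicate")
  expect_error(
    food_web(nodes = c("A"), links = data.frame(predator = "A", prey = "B",
                                                weight = 1)),
    "endpoint")
  expect_error(
    food_web(nodes = data.frame(id = c("F1", "F2"), kind = "fishery"),
             links = NULL),
    "fishery")
})

test_that("node table supplies kinds; unknown nodes default to species", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("predator,prey,weight", "A,B,1", "B,Det,1"), f)
  nt <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,label,kind", "Det,detritus pool,detritus"), nt)
  web <- read_edge_list(f, node_table = nt)
  expect_equal(web$nodes$kind[web$nodes$id == "Det"], "detritus")
  expect_equal(web$nodes$kind[web$nodes$id == "A"], "species")
  expect_equal(web$nodes$label[web$nodes$id == "Det"], "detritus pool")
})

test_that("write/read round trip is the identity on the web", {
  web <- niche_model(S = 25, C = 0.08, seed = 5)
  f <- withr::local_tempfile(fileext = ".csv")
  nt <- withr::local_tempfile(fileext = ".csv")
  write_edge_list(web, f, node_table = nt)
  back <- read_edge_list(f, node_table = nt)
  expect_web_equal(web, back)
  # weights carry >= 10 significant digits so diet sums survive
  sums <- tapply(back$links$weight, back$links$predator, sum)
  expect_lt(max(abs(sums - 1)), 1e-9)
})

test_that("empty-link web writes a header-only file", {
  web <- food_web(nodes = c("A", "B"), links = NULL)
  f <- withr::local_tempfile(fileext = ".csv")
  write_edge_list(web, f)
  expect_equal(length(readLines(f)), 1L)
})

test_that("GraphML export carries weights and kinds", {
  web <- diamond3()
  f <- withr::local_tempfile(fileext = ".graphml")
  write_graphml(web, f)
  g <- igraph::read_graph(f, format = "graphml")
  expect_equal(igraph::gorder(g), 3)
  expect_setequal(round(igraph::E(g)$weight, 6), c(0.5, 0.5, 1))
  expect_true("kind" %in% igraph::vertex_attr_names(g))
})

test_that("diet matrix has prey-rows x predator-columns with unit column sums", {
  web <- food_web(links = data.frame(predator = c("A", "A"),
                                     prey = c("B", "C"),
                                     weight = c(0.6, 0.4)))
  Q <- to_diet_matrix(web)
  expect_equal(rownames(Q), c("A", "B", "C"))  # deterministic sorted order
  expect_equal(unname(Q[, "A"]), c(0, 0.6, 0.4))
  expect_equal(unname(colSums(Q)), c(1, 0, 0))

  # basal-only web -> all-zero matrix
  wb <- food_web(nodes = c("X", "Y"), links = NULL)
  expect_true(all(to_diet_matrix(wb) == 0))

  # round trip through from_diet_matrix recovers the links
  web2 <- niche_model(S = 20, C = 0.1, seed = 2)
  expect_web_equal(web2, from_diet_matrix(to_diet_matrix(web2),
                                          template = web2))
})

test_that("binarize and equal_shares relate matrix views as expected", {
  web <- diamond3()
  Q <- to_diet_matrix(web)
  A <- binarize(Q)
  expect_true(all(A %in% c(0, 1)))
  expect_equal(A > 0, unclass(Q) > 0)
  E <- equal_shares(Q)
  expect_equal(unname(colSums(E)[colSums(A) > 0]), c(1, 1))
  expect_equal(unname(E[E[, "A"] > 0, "A"]), c(0.5, 0.5))
})

test_that("cannibal links are permitted and reported but excluded from basal status", {
  web <- food_web(links = data.frame(predator = c("A", "A", "B"),
                                     prey = c("A", "B", "B"),
                                     weight = c(0.3, 0.7, 1)))
  expect_equal(nrow(cannibal_links(web)), 2)  # A->A and B->B
  expect_true("B" %in% basal_nodes(web))      # B's only prey is itself
  expect_false("A" %in% basal_nodes(web))
})
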