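# Small webs used across the suite, built in code.

# linear chain A -> B -> C (C basal), all diet weights 1
chain3 <- function() {
  food_web(links = data.frame(predator = c("A", "B"), prey = c("B", "C"),
                              weight = c(1, 1)), name = "chain3")
}

# A eats B (0.5) and C (0.5); B eats C; C basal -> TL A 2.5, B 2, C 1
diamond3 <- function() {
  food_web(links = data.frame(predator = c("A", "A", "B"),
                              prey = c("B", "C", "C"),
                              weight = c(0.5, 0.5, 1)), name = "diamond3")
}

# omnivory module: A eats B and C, B eats C, C basal (equal shares)
omnivory3 <- function(wA = c(0.5, 0.5)) {
  food_web(links = data.frame(predator = c("A", "A", "B"),
                              prey = c("B", "C", "C"),
                              weight = c(wA, 1)), name = "omnivory3")
}

# two disjoint directed 3-cycles (no basal node)
two_cycles <- function() {
  food_web(links = data.frame(predator = c("a", "b", "c", "d", "e", "f"),
                              prey = c("b", "c", "a", "e", "f", "d")),
           name = "two_cycles", require_basal = FALSE)
}

# two dense 5-node clusters, one sparse bridge; communities recoverable
two_clusters <- function() {
  in1 <- expand.grid(p = paste0("x", 1:5), q = paste0("x", 1:5))
  in2 <- expand.grid(p = paste0("y", 1:5), q = paste0("y", 1:5))
  lk <- rbind(in1, in2)
  lk <- lk[lk$p != lk$q, ]
  food_web(links = data.frame(predator = lk$p, prey = lk$q),
           name = "two_clusters", require_basal = FALSE)
}

expect_web_equal <- function(a, b) {
  expect_setequal(a$nodes$id, b$nodes$id)
  ka <- a$links[order(a$links$predator, a$links$prey), ]
  kb <- b$links[order(b$links$predator, b$links$prey), ]
  expect_equal(ka$predator, kb$predator)
  expect_equal(ka$prey, kb$prey)
  expect_equal(ka$weight, kb$weight, tolerance = 1e-12)
}
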