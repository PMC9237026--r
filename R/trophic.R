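#' Trophic levels by linear solve
#'
#' Solves the prey-averaged trophic-level system: basal nodes (no prey) have
#' TL = 1 and every consumer j satisfies
#' \deqn{TL_j = 1 + \sum_i q_{ij} TL_i,}
#' where `q_ij` is the fraction of j's diet made of prey i. In matrix form
#' this is the sparse linear system `(I - t(Q)) TL = 1`. With `weighted =
#' FALSE` the diet matrix is first replaced by equal shares per consumer, so
#' weighted and unweighted levels coincide exactly on webs with uniform
#' diets.
#'
#' The system is singular when a set of consumers forms a feeding loop with
#' no diet leakage towards a basal resource; in that case the error names the
#' offending strongly connected component.
#'
#' @param Q a `diet_matrix` from [to_diet_matrix()], or a `food_web`.
#' @param weighted use the diet proportions (`TRUE`) or equal shares
#'   (`FALSE`).
#' @return an object of class `trophic_levels`: named numeric vector of
#'   levels (>= 1, basal exactly 1) with attribute `weighted`.
#' @examples
#' web <- food_web(links = data.frame(
#'   predator = c("A", "A", "B"), prey = c("B", "C", "C"),
#'   weight = c(0.5, 0.5, 1)))
#' trophic_levels(web)          # A 2.5, B 2, C 1
#' @export
trophic_levels <- function(Q, weighted = TRUE) {
  if (inherits(Q, "food_web")) Q <- to_diet_matrix(Q)
  Qm <- unclass(Q)
  if (!weighted) Qm <- unclass(equal_shares(Qm))
  n <- ncol(Qm)
  ids <- colnames(Qm)
  M <- Matrix::Diagonal(n) - Matrix::t(Matrix::Matrix(Qm, sparse = TRUE))
  tl <- tryCatch(
    as.numeric(Matrix::solve(M, rep(1, n))),
    error = function(e) .tl_singular_error(Qm, ids)
  )
  res <- max(abs(M %*% tl - 1))
  if (!is.finite(res) || res > 1e-9) .tl_singular_error(Qm, ids)
  names(tl) <- ids
  basal <- colSums(Qm * (row(Qm) != col(Qm))) == 0
  tl[basal] <- 1  # exact, not just up to solver round-off
  structure(tl, class = "trophic_levels", weighted = weighted)
}

.tl_singular_error <- function(Qm, ids) {
  g <- igraph::graph_from_adjacency_matrix((Qm > 0) * 1, mode = "directed")
  comp <- igraph::components(g, mode = "strong")
  bad <- which(tabulate(comp$membership) > 1)
  loops <- vapply(bad, function(b) {
    paste(ids[comp$membership == b], collapse = ", ")
  }, character(1))
  stop("trophic-level system is singular: consumer loop(s) with no diet ",
       "path to a basal resource: {", paste(loops, collapse = "} {"), "}",
       call. = FALSE)
}

#' @exportS3Method base::print
print.trophic_levels <- function(x, ...) {
  cat(sprintf("trophic levels (%s): %d nodes, max TL %.2f\n",
              if (isTRUE(attr(x, "weighted"))) "weighted" else "unweighted",
              length(x), max(x)))
  print(round(unclass(x), 3))
  invisible(x)
}

#' Mean trophic level
#'
#' Arithmetic mean of node trophic levels. The default averages over all
#' nodes (basal included); set `include = "consumers"` for a consumers-only
#' mean, or pass a character vector of node ids.
#'
#' @param tls a `trophic_levels` vector.
#' @param include `"all"`, `"consumers"`, or node ids to average over.
#' @return a single number >= 1.
#' @export
mean_trophic_level <- function(tls, include = "all") {
  if (identical(include, "all")) {
    sel <- names(tls)
  } else if (identical(include, "consumers")) {
    sel <- names(tls)[tls > 1]
  } else {
    sel <- include
  }
  sel <- intersect(sel, names(tls))
  if (!length(sel)) stop("empty node filter in mean_trophic_level", call. = FALSE)
  mean(tls[sel])
}

#' Network omnivory
#'
#' Unweighted: the fraction of all nodes that are consumers feeding at more
#' than one trophic level, operationalised as (max prey TL - min prey TL) >
#' `epsilon`. Weighted: the mean over consumers of the diet-weighted
#' variance of prey trophic levels,
#' \deqn{O_j = \sum_i q_{ij} (TL_i - \bar T_j)^2,}
#' the classical omnivory index, averaged over consumers.
#'
#' With fractional trophic levels `epsilon = 0` marks nearly every consumer
#' as omnivorous; the default `epsilon = 1` requires prey a full trophic
#' level apart. Both the threshold and the weighted index form are
#' configuration, not fixed truth: the operational definition in field use
#' varies.
#'
#' @param Q a `diet_matrix` or `food_web`.
#' @param tls trophic levels computed on the same web (recomputed when
#'   missing, with the matching `weighted` flag).
#' @param weighted logical.
#' @param epsilon TL-difference threshold (unweighted mode), >= 0.
#' @return a single number: a fraction in `[0, 1]` when unweighted, a
#'   nonnegative variance when weighted.
#' @export
omnivory <- function(Q, tls = NULL, weighted = FALSE, epsilon = 1) {
  if (epsilon < 0) stop("epsilon must be >= 0", call. = FALSE)
  if (inherits(Q, "food_web")) Q <- to_diet_matrix(Q)
  Qm <- unclass(Q)
  if (!weighted) Qm <- unclass(equal_shares(Qm))
  if (is.null(tls)) tls <- trophic_levels(Q, weighted = weighted)
  tl <- unclass(tls)[rownames(Qm)]
  cons <- which(colSums(Qm) > 0)
  if (!length(cons)) return(0)
  if (!weighted) {
    omn <- vapply(cons, function(j) {
      prey_tl <- tl[Qm[, j] > 0]
      (max(prey_tl) - min(prey_tl)) > epsilon
    }, logical(1))
    sum(omn) / ncol(Qm)
  } else {
    v <- vapply(cons, function(j) {
      q <- Qm[, j]
      keep <- q > 0
      q <- q[keep] / sum(q[keep])
      tbar <- sum(q * tl[keep])
      sum(q * (tl[keep] - tbar)^2)
    }, numeric(1))
    mean(v)
  }
}

#' Node degree table
#'
#' Total degree (in + out) of each node, counting every incident link once
#' per endpoint; a cannibal self-link contributes 2. Fishery and discard
#' links count like any other. Rows are sorted by degree (descending), ties
#' by id.
#'
#' @param web a `food_web`.
#' @return data.frame with columns `id`, `degree`, `in_degree`,
#'   `out_degree` (out = number of prey, in = number of predators).
#' @export
degree_table <- function(web) {
  ids <- web$nodes$id
  outd <- table(factor(web$links$predator, levels = ids))
  ind <- table(factor(web$links$prey, levels = ids))
  df <- data.frame(id = ids,
                   degree = as.integer(outd + ind),
                   in_degree = as.integer(ind),
                   out_degree = as.integer(outd))
  df <- df[order(-df$degree, df$id), ]
  rownames(df) <- NULL
  df
}

#' Trophic-class fractions
#'
#' Classifies nodes as basal (no prey), top (prey but no predators) or
#' intermediate (both), self-links ignored, and returns the percentage of
#' nodes in each class.
#'
#' @param web a `food_web`.
#' @param digits rounding applied to the reported percentages (default 0,
#'   integer percent as conventionally reported; use `NULL` for exact).
#' @return named numeric vector `c(top =, intermediate =, basal =)` in
#'   percent.
#' @export
tl_class_fractions <- function(web, digits = 0) {
  ids <- web$nodes$id
  lk <- web$links[web$links$predator != web$links$prey, , drop = FALSE]
  has_prey <- ids %in% lk$predator
  has_pred <- ids %in% lk$prey
  basal <- !has_prey
  top <- has_prey & !has_pred
  mid <- has_prey & has_pred
  out <- 100 * c(top = sum(top), intermediate = sum(mid), basal = sum(basal)) /
    length(ids)
  if (!is.null(digits)) out <- round(out, digits)
  out
}

#' One scenario's metric set
#'
#' Convenience wrapper computing mean trophic level, omnivory, modularity
#' and quasi-sign-stability for a web in one call, in either the weighted or
#' the unweighted version.
#'
#' @param web a `food_web`.
#' @param weighted logical flag applied to all four metrics.
#' @param epsilon omnivory threshold, see [omnivory()].
#' @param qss_n number of Jacobian draws for [qss()].
#' @param seed integer seed for the stochastic metrics (annealing, QSS).
#' @param schedule annealing schedule for [find_best_partition()].
#' @return a list of class `metric_set` with elements `mTL`, `omnivory`,
#'   `modularity`, `qss`, `weighted`, plus the full `modularity_result` and
#'   `qss_result`.
#' @export
metric_set <- function(web, weighted = FALSE, epsilon = 1, qss_n = 1000,
                       seed = 1, schedule = annealing_schedule()) {
  Q <- to_diet_matrix(web)
  tls <- trophic_levels(Q, weighted = weighted)
  mod <- find_best_partition(web, weighted = weighted, schedule = schedule,
                             seed = seed)
  qs <- qss(web, n = qss_n, weighted = weighted, seed = seed + 1L)
  structure(list(
    mTL = mean_trophic_level(tls),
    omnivory = omnivory(Q, tls, weighted = weighted, epsilon = epsilon),
    modularity = mod$q,
    qss = qs$proportion_stable,
    weighted = weighted,
    modularity_result = mod,
    qss_result = qs
  ), class = "metric_set")
}

#' @exportS3Method base::print
print.metric_set <- function(x, ...) {
  cat(sprintf("metric_set (%s): mTL %.4f, omnivory %.4f, modularity %.4f, QSS %.4f\n",
              if (x$weighted) "weighted" else "unweighted",
              x$mTL, x$omnivory, x$modularity, x$qss))
  invisible(x)
}
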