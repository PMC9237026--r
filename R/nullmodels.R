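#' Curveball randomization of a binary adjacency matrix
#'
#' Performs `n_trades` random pair-of-columns trades: two predators swap a
#' random re-deal of the prey they do not share. Every row sum (number of
#' predators per prey) and column sum (number of prey per predator) of the
#' output equals the input's, so basal/consumer identity is preserved; a
#' sufficient number of trades samples (asymptotically uniformly) from the
#' set of binary matrices with those marginals. Trades drawing a pair with
#' no swappable prey (including empty basal columns) are counted but leave
#' the matrix unchanged.
#'
#' @param A binary (0/1) matrix, conventionally the prey-by-predator
#'   support of a diet matrix, see [binarize()].
#' @param n_trades number of attempted trades (>= 0). The default used by
#'   the ensemble harness is 5 trades per node, a common mixing heuristic.
#' @param seed optional integer seed; `NULL` uses the current RNG state.
#' @param fix_diagonal treat the matrix as square over one node set and pin
#'   diagonal cells: trades never create or destroy a self (cannibal) link.
#'   Default `FALSE` (pure bipartite marginals-preserving randomization).
#' @return a 0/1 matrix with identical marginals.
#' @export
curveball <- function(A, n_trades, seed = NULL, fix_diagonal = FALSE) {
  if (n_trades < 0) stop("n_trades must be >= 0", call. = FALSE)
  storage.mode(A) <- "integer"
  if (any(A != 0L & A != 1L)) stop("A must be a 0/1 matrix", call. = FALSE)
  if (!is.null(seed)) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(as.integer(seed))
  }
  .curveball_cpp(A, as.integer(n_trades), isTRUE(fix_diagonal))
}

#' Shuffle diet weights within predator columns
#'
#' Within each predator's column the positive diet proportions are randomly
#' permuted across that predator's prey positions; the multiset of
#' proportions, and therefore the column sum of exactly 1, is preserved.
#' Columns with a single prey are unchanged.
#'
#' @param Q a `diet_matrix`.
#' @param seed optional integer seed; `NULL` uses the current RNG state.
#' @return a `diet_matrix` with shuffled columns.
#' @export
shuffle_weights <- function(Q, seed = NULL) {
  if (!is.null(seed)) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(as.integer(seed))
  }
  Qm <- unclass(Q)
  for (j in seq_len(ncol(Qm))) {
    pos <- which(Qm[, j] > 0)
    if (length(pos) > 1) Qm[pos, j] <- Qm[sample(pos), j]
  }
  class(Qm) <- c("diet_matrix", class(Qm))
  Qm
}

#' Randomize a web: curveball topology, then re-dealt diet weights
#'
#' One draw of the null model: the binary support is curveball-randomized,
#' then (in weighted mode) each predator keeps its original multiset of
#' diet proportions, assigned uniformly at random to its new prey set --
#' degree preservation guarantees the multiset sizes match, and column sums
#' stay exactly 1. In unweighted mode the new topology receives equal
#' shares.
#'
#' @param web a `food_web`.
#' @param n_trades trades per draw (default 5 per node).
#' @param weighted re-deal original diet multisets (`TRUE`) or equal shares.
#' @return a `food_web` with randomized links (node metadata retained).
#' @export
randomize_web <- function(web, n_trades = 5 * nrow(web$nodes),
                          weighted = TRUE) {
  Q <- to_diet_matrix(web)
  A0 <- binarize(Q)
  A <- curveball(A0, n_trades, fix_diagonal = TRUE)
  Qm <- unclass(Q)
  Qn <- matrix(0, nrow(A), ncol(A), dimnames = dimnames(A))
  for (j in seq_len(ncol(A))) {
    new_prey <- which(A[, j] > 0)
    if (!length(new_prey)) next
    if (weighted) {
      wts <- Qm[Qm[, j] > 0, j]
      Qn[new_prey, j] <- if (length(wts) > 1) sample(wts) else wts
    } else {
      Qn[new_prey, j] <- 1 / length(new_prey)
    }
  }
  class(Qn) <- c("diet_matrix", class(Qn))
  from_diet_matrix(Qn, template = web)
}

#' Null distribution of a metric over randomized webs
#'
#' For each of `n` draws the topology is curveball-randomized (and in
#' weighted mode the diet weights re-dealt, see [randomize_web()]) and the
#' metric recomputed. Draws whose trophic-level solve fails (a new consumer
#' loop with no basal access) are redrawn; their count is recorded and a
#' redraw rate above 10% is an error suggesting more trades or unweighted
#' mode. Deterministic given `seed`.
#'
#' @param web a `food_web`.
#' @param metric one of `"mTL"`, `"omnivory"`, `"modularity"`.
#' @param n ensemble size (the conventional choice is 1000).
#' @param weighted logical, applied both to the randomization and the
#'   metric.
#' @param seed integer seed.
#' @param n_trades curveball trades per draw.
#' @param epsilon omnivory threshold, see [omnivory()].
#' @param schedule annealing schedule for modularity draws (default
#'   [fast_schedule()]: ensemble throughput over per-run polish).
#' @return a list of class `null_ensemble`: `metric`, `values` (length
#'   `n`), `recipe` (seed, trades, n, weighted, web name), `n_redraws`.
#' @export
null_distribution <- function(web, metric = c("mTL", "omnivory", "modularity"),
                              n = 1000, weighted = FALSE, seed = 1,
                              n_trades = 5 * nrow(web$nodes), epsilon = 1,
                              schedule = fast_schedule()) {
  metric <- match.arg(metric)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  values <- numeric(n)
  n_redraws <- 0L
  max_redraws <- max(10, ceiling(0.1 * n))
  for (r in seq_len(n)) {
    repeat {
      rw <- randomize_web(web, n_trades = n_trades, weighted = weighted)
      v <- tryCatch({
        switch(metric,
          mTL = mean_trophic_level(trophic_levels(rw, weighted = weighted)),
          omnivory = omnivory(to_diet_matrix(rw), weighted = weighted,
                              epsilon = epsilon),
          modularity = {
            mseed <- as.integer(stats::runif(1, 1, 2^30))
            find_best_partition(rw, weighted = weighted,
                                schedule = schedule, seed = mseed)$q
          })
      }, error = function(e) NULL)
      if (!is.null(v)) break
      n_redraws <- n_redraws + 1L
      if (n_redraws > max_redraws) {
        stop("null_distribution: more than 10% of draws failed the ",
             "trophic-level solve; increase n_trades or use weighted = FALSE",
             call. = FALSE)
      }
    }
    values[r] <- v
  }
  structure(list(metric = metric, values = values,
                 recipe = list(seed = as.integer(seed), n = as.integer(n),
                               n_trades = as.integer(n_trades),
                               weighted = weighted, epsilon = epsilon,
                               web = web$name),
                 n_redraws = n_redraws),
            class = "null_ensemble")
}

#' @exportS3Method base::print
print.null_ensemble <- function(x, ...) {
  cat(sprintf("null_ensemble of %s (%s) on '%s': n = %d, median %.4f (%d redraws)\n",
              x$metric, if (x$recipe$weighted) "weighted" else "unweighted",
              x$recipe$web, x$recipe$n, stats::median(x$values), x$n_redraws))
  invisible(x)
}
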