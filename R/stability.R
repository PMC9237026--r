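#' Community-matrix sampling specification
#'
#' Describes how random Jacobians are drawn from a web's sign structure.
#' For every trophic link "j eats i": the effect of resource i on consumer
#' j is positive (`J[j, i] > 0`) and the effect of consumer j on resource i
#' is negative (`J[i, j] < 0`). Every node is self-limited: `J[i, i]` is
#' drawn negative. Off-diagonal magnitudes are Uniform(0, `max_magnitude`),
#' optionally multiplied by the link's diet proportion (weighted mode);
#' diagonals are Uniform(`-diag_scale`, 0).
#'
#' Near-universal self-limitation is the default because without it the
#' stable proportion of any speciose web is numerically zero and the index
#' loses all contrast. The default `self_limitation = "species"` damps
#' every biological node (species, trophospecies, detritus) but leaves the
#' fishery and discard nodes undamped: harvest effort and a discard pool
#' are externally driven, not self-regulating populations, so they enter
#' the community matrix through their trophic links alone. `"all"` damps
#' every node including those two; `"basal"` damps basal nodes only.
#'
#' @param max_magnitude upper bound of off-diagonal magnitudes.
#' @param diag_scale diagonal magnitudes are Uniform(-diag_scale, 0).
#' @param self_limitation `"species"` (default), `"all"` or `"basal"`.
#' @param weighted scale off-diagonal magnitudes by diet proportions.
#' @return a list of class `community_matrix_spec`.
#' @export
community_matrix_spec <- function(max_magnitude = 1, diag_scale = 1,
                                  self_limitation = c("species", "all",
                                                      "basal"),
                                  weighted = FALSE) {
  self_limitation <- match.arg(self_limitation)
  stopifnot(max_magnitude > 0, diag_scale > 0)
  structure(list(max_magnitude = max_magnitude, diag_scale = diag_scale,
                 self_limitation = self_limitation, weighted = weighted),
            class = "community_matrix_spec")
}

# index bookkeeping shared by sample_jacobian and qss
.jacobian_plan <- function(web, spec) {
  ids <- sort(web$nodes$id)
  n <- length(ids)
  lk <- web$links[web$links$predator != web$links$prey, , drop = FALSE]
  pred <- match(lk$predator, ids)
  prey <- match(lk$prey, ids)
  # J[pred, prey] > 0 (resource benefits consumer), J[prey, pred] < 0
  pos_idx <- cbind(pred, prey)
  neg_idx <- cbind(prey, pred)
  scale <- if (spec$weighted) lk$weight else rep(1, nrow(lk))
  diag_nodes <- switch(spec$self_limitation,
    all = seq_len(n),
    species = which(!(ids %in%
      web$nodes$id[web$nodes$kind %in% c("fishery", "discard")])),
    basal = which(ids %in% basal_nodes(web)))
  list(ids = ids, n = n, pos_idx = pos_idx, neg_idx = neg_idx,
       scale = scale * spec$max_magnitude, diag_nodes = diag_nodes)
}

#' Draw one random Jacobian respecting the web's sign structure
#'
#' @param web a `food_web`.
#' @param spec a [community_matrix_spec()].
#' @return a square matrix over the web's nodes (sorted ids), with signs
#'   fixed by topology and magnitudes drawn as described in the spec.
#'   Cannibal self-links are subsumed in the (negative) diagonal.
#' @export
sample_jacobian <- function(web, spec = community_matrix_spec()) {
  pl <- .jacobian_plan(web, spec)
  J <- matrix(0, pl$n, pl$n, dimnames = list(pl$ids, pl$ids))
  L <- nrow(pl$pos_idx)
  if (L) {
    J[pl$pos_idx] <- stats::runif(L) * pl$scale
    J[pl$neg_idx] <- -stats::runif(L) * pl$scale
  }
  d <- numeric(pl$n)
  d[pl$diag_nodes] <- -stats::runif(length(pl$diag_nodes)) * spec$diag_scale
  diag(J) <- d
  J
}

#' Local stability of a community matrix
#'
#' A matrix is locally stable when every eigenvalue has real part below
#' `-tol`; the strict tolerance guards against numerically zero real parts
#' being counted as stable.
#'
#' @param J square real matrix.
#' @param tol nonnegative margin (default `1e-10`).
#' @return logical.
#' @export
is_locally_stable <- function(J, tol = 1e-10) {
  if (!is.matrix(J) || nrow(J) != ncol(J)) stop("J must be square", call. = FALSE)
  ev <- eigen(J, only.values = TRUE)$values
  max(Re(ev)) < -tol
}

#' Quasi-sign-stability
#'
#' Draws `n` random Jacobians consistent with the web's predator-prey sign
#' structure (see [community_matrix_spec()]) and reports the proportion
#' that are locally stable. Deterministic given `seed`.
#'
#' @param web a `food_web`.
#' @param n number of Jacobian draws (the conventional choice is 10000).
#' @param weighted scale interaction magnitudes by diet proportions.
#' @param seed integer seed.
#' @param spec optional [community_matrix_spec()]; its `weighted` field is
#'   overridden by the `weighted` argument.
#' @param keep_max_re keep the vector of largest eigenvalue real parts.
#' @param tol stability margin, see [is_locally_stable()].
#' @return a list of class `qss_result`: `proportion_stable`, `n_samples`,
#'   `n_stable`, `se` (binomial standard error), `seed`, `weighted`, and
#'   optionally `max_eigenvalue_sample`.
#' @export
qss <- function(web, n = 10000, weighted = FALSE, seed = 1,
                spec = community_matrix_spec(), keep_max_re = FALSE,
                tol = 1e-10) {
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  spec$weighted <- weighted
  pl <- .jacobian_plan(web, spec)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  L <- nrow(pl$pos_idx)
  nd <- length(pl$diag_nodes)
  maxre <- numeric(if (keep_max_re) n else 0)
  n_stable <- 0L
  J <- matrix(0, pl$n, pl$n)
  for (r in seq_len(n)) {
    if (L) {
      J[pl$pos_idx] <- stats::runif(L) * pl$scale
      J[pl$neg_idx] <- -stats::runif(L) * pl$scale
    }
    d <- numeric(pl$n)
    if (nd) d[pl$diag_nodes] <- -stats::runif(nd) * spec$diag_scale
    diag(J) <- d
    mr <- max(Re(eigen(J, only.values = TRUE)$values))
    if (mr < -tol) n_stable <- n_stable + 1L
    if (keep_max_re) maxre[r] <- mr
  }
  p <- n_stable / n
  structure(list(proportion_stable = p, n_samples = as.integer(n),
                 n_stable = n_stable, se = sqrt(p * (1 - p) / n),
                 seed = as.integer(seed), weighted = weighted,
                 spec = spec,
                 max_eigenvalue_sample = if (keep_max_re) maxre else NULL),
            class = "qss_result")
}

#' @exportS3Method base::print
print.qss_result <- function(x, ...) {
  cat(sprintf("qss_result (%s): %d/%d stable = %.4f (SE %.4f, seed %d)\n",
              if (x$weighted) "weighted" else "unweighted",
              x$n_stable, x$n_samples, x$proportion_stable, x$se, x$seed))
  invisible(x)
}
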