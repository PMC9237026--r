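#' Directed (weighted) Newman modularity of a partition
#'
#' For a directed web with link weights `w_ij` (diet proportions, or 1s in
#' the unweighted case), out-/in-strengths `s^out`, `s^in` and total weight
#' `m`,
#' \deqn{Q = \frac{1}{m}\sum_{ij}\left[w_{ij} -
#'       \frac{s_i^{out} s_j^{in}}{m}\right]\delta(c_i, c_j).}
#' This strength-based directed null model admits negative Q on weighted
#' webs when heavy links run between, rather than within, communities.
#'
#' @param web a `food_web`.
#' @param partition named integer/character vector mapping every node id to
#'   a community, or a `modularity_result`.
#' @param weighted use diet weights (`TRUE`) or unit weights (`FALSE`).
#' @return a single number, `Q <= 1`.
#' @export
modularity_value <- function(web, partition, weighted = FALSE) {
  if (inherits(partition, "modularity_result")) partition <- partition$partition
  ids <- web$nodes$id
  if (is.null(names(partition))) {
    if (length(partition) != length(ids)) {
      stop("unnamed partition must have one entry per node", call. = FALSE)
    }
    names(partition) <- ids
  }
  if (!all(ids %in% names(partition))) {
    stop("partition does not cover every node", call. = FALSE)
  }
  lk <- web$links
  if (!nrow(lk)) stop("modularity is undefined for a web with no links (m = 0)",
                      call. = FALSE)
  w <- if (weighted) lk$weight else rep(1, nrow(lk))
  m <- sum(w)
  sout <- tapply(w, factor(lk$predator, levels = ids), sum, default = 0)
  sin <- tapply(w, factor(lk$prey, levels = ids), sum, default = 0)
  cc <- as.character(partition[ids])
  names(cc) <- ids
  w_in <- sum(w[cc[lk$predator] == cc[lk$prey]])
  So_c <- tapply(as.numeric(sout), cc, sum)
  Si_c <- tapply(as.numeric(sin), cc, sum)
  w_in / m - sum(So_c * Si_c[names(So_c)]) / m^2
}

#' Annealing schedule parameters
#'
#' Defaults follow a Guimera-style geometric schedule: the initial
#' temperature is calibrated from 100 random single-node moves so a typical
#' worsening move is accepted with probability about one half, cooling is
#' geometric, and `n^2 * proposal_factor` proposals are evaluated per
#' temperature. The search stops after `patience` temperatures without
#' improvement of the best modularity seen (or at `max_temps`).
#'
#' @param t0 initial temperature; `NA` (default) means calibrate.
#' @param cooling geometric cooling factor in (0, 1).
#' @param proposal_factor multiplier on `n^2` proposals per temperature.
#' @param patience temperatures without improvement before stopping.
#' @param max_temps hard cap on the number of temperatures.
#' @return a list of class `annealing_schedule`.
#' @export
annealing_schedule <- function(t0 = NA, cooling = 0.995, proposal_factor = 1,
                               patience = 50, max_temps = 2000) {
  if (!is.na(t0) && t0 <= 0) stop("t0 must be positive (or NA to calibrate)",
                                  call. = FALSE)
  if (cooling <= 0 || cooling >= 1) stop("cooling factor must be in (0, 1)",
                                         call. = FALSE)
  if (proposal_factor <= 0 || patience < 1 || max_temps < 1) {
    stop("invalid annealing schedule", call. = FALSE)
  }
  structure(list(t0 = t0, cooling = cooling, proposal_factor = proposal_factor,
                 patience = patience, max_temps = max_temps),
            class = "annealing_schedule")
}

#' A lighter schedule for null-model ensembles
#'
#' Same shape as [annealing_schedule()] but tuned for the many repeated
#' optimisations of a null distribution, where per-run polish matters less
#' than throughput.
#' @export
fast_schedule <- function() {
  annealing_schedule(cooling = 0.95, proposal_factor = 0.25,
                     patience = 20, max_temps = 500)
}

#' Maximise modularity by simulated annealing
#'
#' Searches partitions of the web with a stochastic algorithm using three
#' proposal kinds -- single-node moves, community merges and random
#' bipartition splits -- under Metropolis acceptance on the modularity
#' change (a zero change is always accepted). The best partition ever
#' visited is returned; runs are deterministic given `seed`. Isolated nodes
#' simply remain in their own community.
#'
#' @param web a `food_web`.
#' @param weighted maximise the weighted (diet-proportion) or unweighted Q.
#' @param schedule an [annealing_schedule()].
#' @param seed integer seed.
#' @return a list of class `modularity_result`: `q`, `partition` (named
#'   integer vector, community indices contiguous from 0 in first-appearance
#'   order), `n_communities`, `weighted`, `seed`, `schedule`, `t0`, and
#'   `trace` (data.frame of temperature and best-q).
#' @export
find_best_partition <- function(web, weighted = FALSE,
                                schedule = annealing_schedule(), seed = 1) {
  stopifnot(inherits(schedule, "annealing_schedule"))
  ids <- web$nodes$id
  lk <- web$links
  if (!nrow(lk)) stop("cannot partition a web with no links", call. = FALSE)
  w <- if (weighted) lk$weight else rep(1, nrow(lk))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  res <- .anneal_modularity(length(ids),
                            match(lk$predator, ids) - 1L,
                            match(lk$prey, ids) - 1L,
                            as.numeric(w),
                            ifelse(is.na(schedule$t0), -1, schedule$t0),
                            schedule$cooling, schedule$proposal_factor,
                            as.integer(schedule$patience),
                            as.integer(schedule$max_temps))
  part <- .canonicalize_partition(res$comm)
  names(part) <- ids
  structure(list(q = res$q, partition = part,
                 n_communities = length(unique(part)),
                 weighted = weighted, seed = as.integer(seed),
                 schedule = schedule, t0 = res$t0,
                 trace = data.frame(temperature = res$trace_temperature,
                                    best_q = res$trace_best_q)),
            class = "modularity_result")
}

# relabel community ids to 0,1,2,... in order of first appearance
.canonicalize_partition <- function(comm) {
  match(comm, unique(comm)) - 1L
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' @exportS3Method base::print
print.modularity_result <- function(x, ...) {
  cat(sprintf("modularity_result (%s): Q = %.4f over %d communities (seed %d)\n",
              if (x$weighted) "weighted" else "unweighted",
              x$q, x$n_communities, x$seed))
  invisible(x)
}

#' Exhaustive modularity optimum for tiny webs
#'
#' Enumerates every set partition (restricted-growth strings) and returns
#' the maximum modularity; intended as an oracle for webs of at most ~10
#' nodes (Bell numbers grow fast).
#'
#' @param web a `food_web` with few nodes.
#' @param weighted logical.
#' @return list with `q` and `partition`.
#' @export
exhaustive_best_partition <- function(web, weighted = FALSE) {
  n <- nrow(web$nodes)
  if (n > 10) stop("exhaustive search limited to 10 nodes", call. = FALSE)
  best <- list(q = -Inf, partition = NULL)
  rgs <- integer(n)
  recurse <- function(i, maxc) {
    if (i > n) {
      p <- rgs
      names(p) <- web$nodes$id
      q <- modularity_value(web, p, weighted = weighted)
      if (q > best$q) best <<- list(q = q, partition = p)
      return(invisible(NULL))
    }
    for (c in 0:maxc) {
      rgs[i] <<- c
      recurse(i + 1, max(maxc, c + 1))
    }
  }
  recurse(1, 0)
  best
}
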