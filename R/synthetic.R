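#' Niche-model food-web generator
#'
#' The classic niche model: each species receives a niche value
#' `n_i ~ U(0, 1)`; its feeding range is `r_i = n_i * x` with
#' `x ~ Beta(1, 1/(2C) - 1)` so that expected connectance is `C`; the range
#' centre is `c_i ~ U(r_i / 2, n_i)`; species i eats every j whose niche
#' value falls inside `[c_i - r_i/2, c_i + r_i/2]`. The species with the
#' smallest niche value gets an empty range, guaranteeing a basal node.
#' Webs with isolated species, duplicate diets, no weak connectivity, or a
#' consumer loop that defeats the trophic-level solve are redrawn (up to
#' `max_tries`). Deterministic given `seed`.
#'
#' @param S species count (>= 3).
#' @param C target connectance, links / S^2, in (0, 0.5).
#' @param seed integer seed.
#' @param diet_concentration Dirichlet concentration for [assign_diets()];
#'   `NULL` leaves the web with equal diet shares.
#' @param max_tries redraw budget before giving up.
#' @param connectance_tol accept only webs whose realized connectance
#'   `links / S^2` is within this relative tolerance of `C` (default 0.1).
#'   Repairing isolated species biases raw realized connectance upward at
#'   low `C`; screening restores the target. `Inf` disables the screen.
#' @return a `food_web` with diet weights.
#' @export
niche_model <- function(S, C, seed = 1, diet_concentration = 1,
                        max_tries = 100, connectance_tol = 0.1) {
  stopifnot(S >= 3, C > 0, C < 0.5)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  beta_par <- 1 / (2 * C) - 1
  draw_pars <- function(k) {
    nv <- stats::runif(k)
    r <- nv * stats::rbeta(k, 1, beta_par)
    list(nv = nv, r = r, cen = stats::runif(k, r / 2, pmin(nv, 1 - r / 2)))
  }
  adjacency <- function(p) {
    r_eff <- p$r
    r_eff[which.min(p$nv)] <- 0              # guaranteed basal species
    lo <- p$cen - r_eff / 2
    hi <- p$cen + r_eff / 2
    A <- outer(seq_len(S), seq_len(S), function(i, j) {
      p$nv[j] >= lo[i] & p$nv[j] <= hi[i]
    }) * 1
    A
  }
  for (try in seq_len(max_tries)) {
    p <- draw_pars(S)
    # species-level repair: redraw only isolated or duplicate-role species
    ok <- FALSE
    for (rep in 1:200) {
      A <- adjacency(p)
      deg <- rowSums(A) + colSums(A)
      bad <- which(deg == 0)
      sig <- paste(apply(A, 1, paste, collapse = ""),
                   apply(A, 2, paste, collapse = ""))
      bad <- union(bad, which(duplicated(sig)))
      if (!length(bad)) { ok <- TRUE; break }
      np <- draw_pars(length(bad))
      p$nv[bad] <- np$nv; p$r[bad] <- np$r; p$cen[bad] <- np$cen
    }
    if (!ok) next
    # screen only when enough links are expected for it to be meaningful:
    # very sparse tiny webs (C S^2 < S) cannot hit a narrow integer band
    # and still be connected
    if (C * S^2 >= S &&
        abs(sum(A) - C * S^2) > max(connectance_tol * C * S^2, 1)) next
    g <- igraph::graph_from_adjacency_matrix(A, mode = "directed")
    if (igraph::components(g, mode = "weak")$no != 1) next
    nv <- p$nv
    ids <- sprintf("sp%03d", order(order(nv)))  # id order follows niche value
    # links: i (predator) eats j (prey); equal shares initially
    idx <- which(A == 1, arr.ind = TRUE)
    web <- tryCatch({
      w <- food_web(nodes = sprintf("sp%03d", seq_len(S)),
                    links = data.frame(predator = ids[idx[, 1]],
                                       prey = ids[idx[, 2]]),
                    name = sprintf("niche-S%d-C%g-seed%d", S, C, seed))
      trophic_levels(w)  # reject webs whose TL system is singular
      w
    }, error = function(e) NULL)
    if (is.null(web)) next
    if (!is.null(diet_concentration)) {
      web <- assign_diets(web, diet_concentration)
    }
    return(web)
  }
  stop("niche_model: no valid web after ", max_tries, " redraws", call. = FALSE)
}

#' Assign Dirichlet diet proportions to a topology
#'
#' Each consumer's diet over its prey is drawn from a symmetric
#' Dirichlet(alpha) (gamma draws normalised to sum exactly 1). Large alpha
#' approaches equal shares; alpha < 1 produces skewed diets dominated by a
#' few prey, the typical shape of empirical diet tables.
#'
#' @param web a `food_web` (its current weights are discarded).
#' @param diet_concentration alpha > 0.
#' @param seed optional integer seed; `NULL` continues the current RNG
#'   stream (as when called from [niche_model()]).
#' @return a `food_web` with new weights.
#' @export
assign_diets <- function(web, diet_concentration = 1, seed = NULL) {
  stopifnot(diet_concentration > 0)
  if (!is.null(seed)) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(as.integer(seed))
  }
  links <- web$links
  for (p in unique(links$predator)) {
    sel <- links$predator == p
    k <- sum(sel)
    gam <- stats::rgamma(k, shape = diet_concentration)
    while (sum(gam) == 0) gam <- stats::rgamma(k, shape = diet_concentration)
    links$weight[sel] <- gam / sum(gam)
  }
  food_web(nodes = web$nodes, links = links, name = web$name)
}

#' Synthetic non-fishing / fishing scenario pair
#'
#' A reduced-scale stand-in for a speciose coastal shelf web and its
#' fishery-augmented variant: a niche web with about 80 nodes and 400
#' links (C about 0.0625) and Dirichlet(1) diets, to which a fishery is
#' attached on the highest-degree mid-trophic-level nodes (TL in [2, 4.2])
#' and a discard node wired to a random 15% of consumers with a 10% diet
#' share each. Entirely synthetic; it emulates the statistical shape of a
#' trawl-fishery web, not any particular empirical system.
#'
#' @param seed integer seed controlling web, diets, capture weights and
#'   discard wiring.
#' @param S species count of the base web.
#' @param C connectance of the base web.
#' @param n_caught number of caught species.
#' @param discard_fraction fraction of consumers wired to discards.
#' @param discard_share per-consumer discard diet share.
#' @return list with elements `nonfishing`, `fishing` (both `food_web`)
#'   and `rules` (the [fishery_rules()] used).
#' @export
sjg_like_scenario_pair <- function(seed = 1, S = 80, C = 0.0625,
                                   n_caught = 15, discard_fraction = 0.15,
                                   discard_share = 0.1) {
  base <- niche_model(S = S, C = C, seed = seed, diet_concentration = 1)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed) + 1000003L)
  tls <- trophic_levels(base)
  deg <- degree_table(base)
  mid <- deg$id[tls[deg$id] >= 2 & tls[deg$id] <= 4.2]
  caught <- utils::head(mid, n_caught)   # deg table sorted by degree desc
  if (length(caught) < 2) caught <- utils::head(deg$id[tls[deg$id] > 1.5], 2)
  cons <- setdiff(consumer_nodes(base), character(0))
  nd <- max(1, round(discard_fraction * length(cons)))
  discard_consumers <- sample(cons, nd)
  gam <- stats::rgamma(length(caught), shape = 1)
  rules <- fishery_rules(caught = caught,
                         discard_consumers = discard_consumers,
                         capture_weights = gam / sum(gam),
                         discard_diet_share = discard_share)
  fishing <- build_fishing_web(base, rules)
  list(nonfishing = base, fishing = fishing, rules = rules)
}
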