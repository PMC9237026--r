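#' Fishery scenario rules
#'
#' Describes how a fishing scenario is derived from a base web: the fishery
#' node consumes the caught species with the given capture (diet) weights,
#' and the discard node acts as a novel basal resource for the listed
#' scavenger/opportunist consumers, each of which assigns
#' `discard_diet_share` of its rebalanced diet to discards.
#'
#' @param caught character vector of caught node ids (nonempty).
#' @param discard_consumers character vector of node ids feeding on
#'   discards (may be empty).
#' @param capture_weights numeric diet composition of the fishery over
#'   `caught`, summing to 1; default equal shares.
#' @param discard_diet_share either a single share in (0, 1) applied to all
#'   discard consumers or a named vector per consumer.
#' @return a list of class `fishery_rules`.
#' @export
fishery_rules <- function(caught, discard_consumers = character(),
                          capture_weights = NULL, discard_diet_share = 0.1) {
  if (!length(caught)) stop("`caught` must be nonempty", call. = FALSE)
  if (is.null(capture_weights)) {
    capture_weights <- rep(1 / length(caught), length(caught))
  }
  if (length(capture_weights) != length(caught) ||
      abs(sum(capture_weights) - 1) > 1e-6) {
    stop("capture_weights must match `caught` and sum to 1", call. = FALSE)
  }
  names(capture_weights) <- caught
  if (length(discard_consumers)) {
    if (length(discard_diet_share) == 1 && is.null(names(discard_diet_share))) {
      discard_diet_share <- stats::setNames(
        rep(discard_diet_share, length(discard_consumers)), discard_consumers)
    }
    if (!all(discard_consumers %in% names(discard_diet_share))) {
      stop("discard_diet_share must cover every discard consumer", call. = FALSE)
    }
    discard_diet_share <- discard_diet_share[discard_consumers]
    if (any(discard_diet_share <= 0 | discard_diet_share >= 1)) {
      stop("discard diet shares must lie in (0, 1)", call. = FALSE)
    }
  } else {
    discard_diet_share <- numeric()
  }
  structure(list(caught = caught, discard_consumers = discard_consumers,
                 capture_weights = capture_weights,
                 discard_diet_share = discard_diet_share),
            class = "fishery_rules")
}

#' Build the fishing-scenario web
#'
#' Adds to the base web a `Fishery` node (top consumer of the caught
#' species, no predators) and a `Discard` node (basal resource, no prey).
#' Each discard consumer gains a link to `Discard` with its share s and has
#' its existing diet weights rescaled by (1 - s), so diet sums stay exactly
#' 1. The link count grows by `length(caught) + length(discard_consumers)`,
#' and removing the two nodes and undoing the rescaling recovers the base
#' web exactly.
#'
#' @param base a `food_web` without fishery or discard nodes.
#' @param rules a [fishery_rules()].
#' @param fishery_id,discard_id ids for the two added nodes.
#' @return a `food_web` named `paste0(base$name, "-fishing")`.
#' @export
build_fishing_web <- function(base, rules, fishery_id = "Fishery",
                              discard_id = "Discard") {
  stopifnot(inherits(base, "food_web"), inherits(rules, "fishery_rules"))
  if (any(base$nodes$kind %in% c("fishery", "discard"))) {
    stop("base web already contains fishery/discard nodes", call. = FALSE)
  }
  missing <- setdiff(c(rules$caught, rules$discard_consumers), base$nodes$id)
  if (length(missing)) {
    stop("rule id(s) not in base web: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  nodes <- rbind(base$nodes,
                 data.frame(id = c(fishery_id, discard_id),
                            label = c(fishery_id, discard_id),
                            kind = c("fishery", "discard")))
  links <- base$links
  for (i in seq_along(rules$discard_consumers)) {
    cid <- rules$discard_consumers[i]
    s <- rules$discard_diet_share[[cid]]
    sel <- links$predator == cid
    if (!any(sel)) {
      stop("discard consumer ", cid, " has no diet to rebalance", call. = FALSE)
    }
    links$weight[sel] <- links$weight[sel] * (1 - s)
    links <- rbind(links, data.frame(predator = cid, prey = discard_id,
                                     weight = s))
  }
  links <- rbind(links,
                 data.frame(predator = fishery_id, prey = rules$caught,
                            weight = as.numeric(rules$capture_weights)))
  food_web(nodes = nodes, links = links,
           name = paste0(base$name, "-fishing"))
}

#' Remove the fishery scenario from a web
#'
#' Inverse of [build_fishing_web()]: drops the fishery and discard nodes
#' and rescales each former discard consumer's diet back to sum 1.
#'
#' @param web a fishing-scenario `food_web`.
#' @param name name for the recovered web.
#' @return a `food_web`.
#' @export
remove_fishing_nodes <- function(web, name = sub("-fishing$", "", web$name)) {
  drop_ids <- web$nodes$id[web$nodes$kind %in% c("fishery", "discard")]
  if (!length(drop_ids)) return(web)
  nodes <- web$nodes[!web$nodes$id %in% drop_ids, , drop = FALSE]
  links <- web$links[!(web$links$predator %in% drop_ids |
                         web$links$prey %in% drop_ids), , drop = FALSE]
  # renormalization with a wide tolerance exactly undoes the (1 - share)
  # rescaling of former discard consumers
  food_web(nodes = nodes, links = links, name = name,
           renormalize = TRUE, renorm_tol = 0.999)
}
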