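#' Construct a food web
#'
#' A `food_web` is the central container of the package: a set of nodes
#' (species, trophospecies, detritus, and optionally one fishery and one
#' discard node) joined by directed predator-to-prey links whose weights are
#' diet proportions. For every consumer (a node with at least one prey) the
#' diet weights must sum to one; basal nodes have no outgoing prey links.
#'
#' @param nodes data.frame with columns `id` (unique, non-empty strings),
#'   `label` (display name, defaults to `id`) and `kind` (one of
#'   `"species"`, `"trophospecies"`, `"detritus"`, `"fishery"`, `"discard"`;
#'   defaults to `"species"`). A character vector of ids is also accepted.
#' @param links data.frame with columns `predator`, `prey` (node ids) and
#'   `weight` (diet proportion in (0, 1]). If `weight` is absent each
#'   predator's prey receive equal shares.
#' @param name scenario label, e.g. `"non-fishing"`.
#' @param renormalize if `TRUE` (default), consumer diets whose sum deviates
#'   from 1 by at most `renorm_tol` are rescaled to sum exactly to 1; larger
#'   deviations are an error either way.
#' @param renorm_tol maximum tolerated deviation of a diet sum from 1 before
#'   renormalisation (default `1e-3`). Published diet tables rarely sum to
#'   exactly one, so a small slack with explicit rescaling is the norm.
#' @param require_basal require at least one basal node (default `TRUE`);
#'   purely cyclic toy webs (useful for modularity work, where no trophic
#'   levels are needed) can opt out.
#'
#' @return An object of class `food_web`: a list with elements `nodes`
#'   (data.frame `id`, `label`, `kind`), `links` (data.frame `predator`,
#'   `prey`, `weight`) and `name`.
#' @examples
#' web <- food_web(
#'   links = data.frame(predator = c("A", "A", "B"),
#'                      prey     = c("B", "C", "C"),
#'                      weight   = c(0.6, 0.4, 1))
#' )
#' web
#' @export
food_web <- function(nodes = NULL, links = NULL, name = "web",
                     renormalize = TRUE, renorm_tol = 1e-3,
                     require_basal = TRUE) {
  if (is.null(links)) {
    links <- data.frame(predator = character(), prey = character(),
                        weight = numeric())
  }
  links <- as.data.frame(links)
  if (!all(c("predator", "prey") %in% names(links))) {
    stop("`links` must have columns `predator` and `prey`", call. = FALSE)
  }
  links$predator <- as.character(links$predator)
  links$prey <- as.character(links$prey)

  if (is.null(nodes)) {
    nodes <- unique(c(links$predator, links$prey))
  }
  if (is.character(nodes)) {
    nodes <- data.frame(id = nodes)
  }
  nodes <- as.data.frame(nodes)
  if (!"id" %in% names(nodes)) stop("`nodes` must have an `id` column", call. = FALSE)
  nodes$id <- as.character(nodes$id)
  if (is.null(nodes$label)) nodes$label <- nodes$id
  if (is.null(nodes$kind)) nodes$kind <- "species"
  nodes <- nodes[, c("id", "label", "kind")]

  if (anyDuplicated(nodes$id)) {
    stop("duplicate node ids: ",
         paste(unique(nodes$id[duplicated(nodes$id)]), collapse = ", "),
         call. = FALSE)
  }
  if (any(!nzchar(nodes$label))) stop("node labels must be non-empty", call. = FALSE)
  kinds <- c("species", "trophospecies", "detritus", "fishery", "discard")
  if (!all(nodes$kind %in% kinds)) {
    stop("node kind must be one of: ", paste(kinds, collapse = ", "), call. = FALSE)
  }
  for (k in c("fishery", "discard")) {
    if (sum(nodes$kind == k) > 1L) {
      stop("at most one ", k, " node is allowed per web", call. = FALSE)
    }
  }

  missing_ep <- setdiff(c(links$predator, links$prey), nodes$id)
  if (length(missing_ep)) {
    stop("link endpoint(s) not in node set: ",
         paste(missing_ep, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(links[, c("predator", "prey")])) {
    stop("duplicate (predator, prey) links are forbidden", call. = FALSE)
  }

  if (is.null(links$weight)) {
    # unweighted input: materialize equal diet shares per predator
    npr <- table(links$predator)
    links$weight <- 1 / as.numeric(npr[links$predator])
  }
  links$weight <- as.numeric(links$weight)
  if (nrow(links) && any(!is.finite(links$weight) | links$weight <= 0)) {
    stop("link weights must be finite and > 0", call. = FALSE)
  }
  links <- links[, c("predator", "prey", "weight")]

  if (nrow(links)) {
    sums <- tapply(links$weight, links$predator, sum)
    dev <- abs(sums - 1)
    if (any(dev > renorm_tol)) {
      bad <- names(sums)[dev > renorm_tol]
      stop("diet weights of ", paste(bad, collapse = ", "),
           " deviate from 1 by more than ", renorm_tol, call. = FALSE)
    }
    if (renormalize) {
      links$weight <- links$weight / as.numeric(sums[links$predator])
    } else if (any(dev > 1e-6)) {
      stop("diet sums deviate from 1 beyond 1e-6 and renormalize = FALSE",
           call. = FALSE)
    }
  }

  web <- structure(list(nodes = nodes, links = links, name = name),
                   class = "food_web")
  validate_food_web(web, require_basal = require_basal)
  web
}

#' Validate food-web invariants
#'
#' Checks that link endpoints exist, that consumer diet sums equal one within
#' `1e-6`, that fishery/discard nodes are unique, and that at least one basal
#' node (a node with no prey, self-links excluded) is present in a web that
#' has links.
#'
#' @param web a `food_web`.
#' @param require_basal also check for at least one basal node.
#' @return `web`, invisibly; errors on violation.
#' @export
validate_food_web <- function(web, require_basal = TRUE) {
  stopifnot(inherits(web, "food_web"))
  nodes <- web$nodes; links <- web$links
  if (nrow(links)) {
    if (!all(c(links$predator, links$prey) %in% nodes$id)) {
      stop("link endpoint missing from node set", call. = FALSE)
    }
    sums <- tapply(links$weight, links$predator, sum)
    if (any(abs(sums - 1) > 1e-6)) {
      stop("consumer diet sums deviate from 1 beyond 1e-6", call. = FALSE)
    }
    if (require_basal && length(basal_nodes(web)) == 0L) {
      stop("web has links but no basal node (every node has prey)", call. = FALSE)
    }
  }
  invisible(web)
}

#' @exportS3Method base::print
print.food_web <- function(x, ...) {
  nb <- length(basal_nodes(x))
  cat(sprintf("food_web '%s': %d nodes, %d links (%d basal)\n",
              x$name, nrow(x$nodes), nrow(x$links), nb))
  if (any(x$links$predator == x$links$prey)) {
    cat("  contains cannibal (self) links\n")
  }
  invisible(x)
}

#' Basal, consumer and self-link helpers
#'
#' A node is basal when it has no prey; cannibal self-links are ignored for
#' this determination, so a species that eats only itself still counts as
#' basal. Consumers are all non-basal nodes.
#'
#' @param web a `food_web`.
#' @return character vector of node ids.
#' @export
basal_nodes <- function(web) {
  out <- web$links[web$links$predator != web$links$prey, , drop = FALSE]
  setdiff(web$nodes$id, unique(out$predator))
}

#' @rdname basal_nodes
#' @export
consumer_nodes <- function(web) setdiff(web$nodes$id, basal_nodes(web))

#' Self (cannibalism) links of a web
#' @param web a `food_web`.
#' @return data.frame of links with `predator == prey`.
#' @export
cannibal_links <- function(web) {
  web$links[web$links$predator == web$links$prey, , drop = FALSE]
}

#' Read a food web from a delimited edge list
#'
#' Reads a CSV (or other delimited) file with one row per trophic link.
#' The expected columns are `predator`, `prey` and optionally `weight`
#' (the diet proportion of that prey in the predator's diet); deposited
#' data sets with different column names can be mapped via `col_map`.
#' When the weight column is absent the web is treated as unweighted and
#' each predator's prey receive equal diet shares.
#'
#' @param path path to the edge-list file.
#' @param node_table optional path to a node metadata CSV with columns
#'   `id`, `label`, `kind`; nodes not listed default to kind `"species"`.
#' @param name scenario label stored on the web.
#' @param col_map named character vector mapping the roles `predator`,
#'   `prey`, `weight` to the file's actual column names.
#' @param sep field separator (default `","`).
#' @param renormalize,renorm_tol passed to [food_web()].
#' @return a validated [food_web()].
#' @export
read_edge_list <- function(path, node_table = NULL, name = NULL,
                           col_map = c(predator = "predator", prey = "prey",
                                       weight = "weight"),
                           sep = ",", renormalize = TRUE, renorm_tol = 1e-3) {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(df) == 0L) stop("empty edge list: ", path, call. = FALSE)
  for (role in c("predator", "prey")) {
    if (!col_map[[role]] %in% names(df)) {
      stop("edge list lacks a '", col_map[[role]], "' column", call. = FALSE)
    }
  }
  links <- data.frame(predator = as.character(df[[col_map[["predator"]]]]),
                      prey = as.character(df[[col_map[["prey"]]]]))
  wcol <- col_map[["weight"]]
  if (!is.na(wcol) && wcol %in% names(df)) links$weight <- as.numeric(df[[wcol]])

  nodes <- NULL
  if (!is.null(node_table)) {
    nt <- utils::read.csv(node_table, stringsAsFactors = FALSE)
    if (!"id" %in% names(nt)) stop("node table lacks an `id` column", call. = FALSE)
    nt$id <- as.character(nt$id)
    if (is.null(nt$label)) nt$label <- nt$id
    if (is.null(nt$kind)) nt$kind <- "species"
    extra <- setdiff(unique(c(links$predator, links$prey)), nt$id)
    if (length(extra)) {
      nt <- rbind(nt[, c("id", "label", "kind")],
                  data.frame(id = extra, label = extra, kind = "species"))
    }
    nodes <- nt
  }
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  food_web(nodes = nodes, links = links, name = name,
           renormalize = renormalize, renorm_tol = renorm_tol)
}

#' Write a food web to an edge list (and node table)
#'
#' Weights are serialised with 15 significant digits so that diet sums
#' survive a write/read round trip exactly at the package's tolerance.
#'
#' @param web a `food_web`.
#' @param path output CSV path for the edge list.
#' @param node_table optional path for the node metadata CSV
#'   (`id,label,kind`).
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(web, path, node_table = NULL) {
  links <- web$links
  links$weight <- vapply(links$weight, function(w) format(w, digits = 15),
                         character(1))
  utils::write.csv(links, path, row.names = FALSE, quote = TRUE)
  if (!is.null(node_table)) {
    utils::write.csv(web$nodes, node_table, row.names = FALSE, quote = TRUE)
  }
  invisible(path)
}

#' Export a food web to GraphML
#'
#' Writes the web as a directed graph with `weight` edge attributes and
#' `label`/`kind` vertex attributes, via igraph.
#'
#' @param web a `food_web`.
#' @param path output `.graphml` path.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(web, path) {
  g <- as_igraph(web)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Convert a food web to an igraph object
#'
#' Edges run predator -> prey with the diet proportion as `weight`.
#'
#' @param web a `food_web`.
#' @return an igraph directed graph.
#' @export
as_igraph <- function(web) {
  igraph::graph_from_data_frame(
    d = data.frame(from = web$links$predator, to = web$links$prey,
                   weight = web$links$weight),
    directed = TRUE,
    vertices = web$nodes
  )
}

#' Diet matrix of a food web
#'
#' Returns the prey-by-predator matrix Q with `Q[i, j]` the proportion of
#' predator j's diet made up of prey i. The orientation is fixed so that
#' "column sums" are predator diet sums: every consumer column sums to 1 and
#' basal columns are all zero, which makes the column-sum-preserving weight
#' randomisation of [shuffle_weights()] literal. Row and column order is the
#' same deterministic order (node ids sorted).
#'
#' @param web a `food_web`.
#' @return a base matrix with `dimnames = list(prey, predator)` and class
#'   `diet_matrix`.
#' @export
to_diet_matrix <- function(web) {
  ids <- sort(web$nodes$id)
  n <- length(ids)
  Q <- matrix(0, n, n, dimnames = list(ids, ids))
  if (nrow(web$links)) {
    Q[cbind(match(web$links$prey, ids), match(web$links$predator, ids))] <-
      web$links$weight
  }
  class(Q) <- c("diet_matrix", class(Q))
  Q
}

#' Rebuild a food web from a diet matrix
#'
#' Inverse of [to_diet_matrix()] up to node metadata: positive entries become
#' links. Node kinds can be carried over from a template web.
#'
#' @param Q a prey-by-predator matrix with dimnames.
#' @param template optional `food_web` supplying node metadata and name.
#' @param name scenario label if no template is given.
#' @return a [food_web()].
#' @export
from_diet_matrix <- function(Q, template = NULL, name = "web") {
  idx <- which(Q > 0, arr.ind = TRUE)
  links <- data.frame(predator = colnames(Q)[idx[, 2]],
                      prey = rownames(Q)[idx[, 1]],
                      weight = Q[idx])
  nodes <- if (!is.null(template)) template$nodes else rownames(Q)
  if (!is.null(template)) name <- template$name
  food_web(nodes = nodes, links = links, name = name)
}

#' Binary adjacency of the diet-matrix support
#'
#' @param Q a `diet_matrix` (or any numeric matrix).
#' @return 0/1 matrix of the same shape: 1 where `Q > 0`.
#' @export
binarize <- function(Q) {
  A <- (unclass(Q) > 0) * 1
  dimnames(A) <- dimnames(Q)
  A
}

#' Replace diets by equal shares (unweighted view)
#'
#' Every consumer's positive entries are replaced by 1/k where k is its
#' number of prey. This is the single code path by which all "unweighted"
#' metrics are computed.
#'
#' @param Q a `diet_matrix`.
#' @return a `diet_matrix` with equal diet shares.
#' @export
equal_shares <- function(Q) {
  A <- binarize(Q)
  cs <- colSums(A)
  cons <- cs > 0
  A[, cons] <- sweep(A[, cons, drop = FALSE], 2, cs[cons], "/")
  class(A) <- c("diet_matrix", class(A))
  A
}
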