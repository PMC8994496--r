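#' Load an interaction-edge database
#'
#' Reads (or takes) a directed edge list with evidence counts, merges
#' duplicate (source, target, relation_type) edges by summing their
#' reference counts, rejects self-loops, and indexes each node's total
#' relation degree (number of incident edges, either direction, any
#' type).
#'
#' @param edges path to a TSV with columns `source`, `target`,
#'   `relation_type` (`Regulation` or `Expression`), `n_references`, or
#'   an equivalent data.frame.
#' @return object of class `interaction_db`: list `edges` (merged),
#'   `degree` (named integer vector), `nodes`.
#' @export
load_interaction_db <- function(edges) {
  if (is.character(edges)) {
    edges <- utils::read.delim(edges, stringsAsFactors = FALSE)
  }
  need <- c("source", "target", "relation_type", "n_references")
  if (!all(need %in% names(edges))) {
    stop("malformed edge list: need columns source, target, relation_type, n_references")
  }
  bad <- which(!edges$relation_type %in% c("Regulation", "Expression") |
                 is.na(edges$n_references) | edges$n_references < 1 |
                 edges$source == "" | edges$target == "")
  if (length(bad) > 0)
    stop(sprintf("malformed edge list row(s): %s",
                 paste(utils::head(bad, 5), collapse = ", ")))
  if (any(edges$source == edges$target))
    stop("self-loop edges are not allowed")
  if (nrow(edges) > 0) {
    key <- paste(edges$source, edges$target, edges$relation_type, sep = "\r")
    refs <- tapply(edges$n_references, key, sum)
    first <- edges[!duplicated(key), c("source", "target", "relation_type")]
    first$n_references <- as.integer(refs[match(
      paste(first$source, first$target, first$relation_type, sep = "\r"),
      names(refs))])
    edges <- first
    rownames(edges) <- NULL
  }
  nodes <- unique(c(edges$source, edges$target))
  degree <- table(factor(c(edges$source, edges$target), levels = nodes))
  structure(list(edges = edges,
                 degree = stats::setNames(as.integer(degree), nodes),
                 nodes = nodes),
            class = "interaction_db")
}

#' @export
print.interaction_db <- function(x, ...) {
  cat(sprintf("interaction_db: %d nodes, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Evidence filter parameters for network extraction
#'
#' Defaults mirror curated-database admission rules: expression targets
#' need at least three bibliographic references on a qualifying edge and
#' at least six known relations in the database; regulators need three
#' references and two relations, except in the common-network profile
#' where the relation cut-off is five. A candidate must additionally be
#' connected to at least `min_connected` seed genes ("common to them").
#'
#' @param min_refs_target,min_degree_target reference / degree cut-offs
#'   for expression targets.
#' @param min_refs_regulator,min_degree_regulator same for regulators
#'   (per-muscle profile).
#' @param min_degree_regulator_common regulator degree cut-off under the
#'   common-network profile.
#' @param min_connected minimum number of seed genes a candidate must
#'   touch.
#' @return list of class `filter_params`.
#' @export
filter_params <- function(min_refs_target = 3L, min_degree_target = 6L,
                          min_refs_regulator = 3L, min_degree_regulator = 2L,
                          min_degree_regulator_common = 5L,
                          min_connected = 2L) {
  p <- list(min_refs_target = min_refs_target,
            min_degree_target = min_degree_target,
            min_refs_regulator = min_refs_regulator,
            min_degree_regulator = min_degree_regulator,
            min_degree_regulator_common = min_degree_regulator_common,
            min_connected = min_connected)
  if (any(unlist(p) < 0)) stop("filter parameters must be >= 0")
  class(p) <- "filter_params"
  p
}

#' Extract the regulator/target neighbourhood of a seed gene set
#'
#' Around a set of seed genes (typically the DEGs targeted by the
#' over-represented cis modules), admits candidate regulators (nodes
#' with `Regulation` edges into at least `min_connected` seeds, a
#' maximum seed-edge reference count of at least `min_refs_regulator`,
#' and a total relation degree meeting the profile's cut-off) and
#' candidate expression targets (nodes receiving `Expression` edges from
#' at least `min_connected` seeds, with at least `min_refs_target`
#' references on at least one such edge and degree >=
#' `min_degree_target`). Inter-seed edges are retained, together with
#' every edge among the admitted nodes and seeds.
#'
#' @param db an `interaction_db`.
#' @param seeds character vector of seed genes (need not all be in the
#'   database).
#' @param params a [filter_params()].
#' @param profile `"muscle"` (per-muscle regulator degree cut-off) or
#'   `"common"` (stricter cut-off for the cross-muscle common network).
#' @return object of class `network_extract`: `seeds`, `regulators`,
#'   `targets`, `edges` (subgraph on seeds and admitted nodes),
#'   `profile`.
#' @export
extract_network <- function(db, seeds, params = filter_params(),
                            profile = c("muscle", "common")) {
  stopifnot(inherits(db, "interaction_db"))
  profile <- match.arg(profile)
  seeds <- unique(seeds)
  if (length(seeds) == 0) stop("seed gene set is empty")
  e <- db$edges
  reg_deg_cut <- if (profile == "common")
    params$min_degree_regulator_common else params$min_degree_regulator

  regulators <- character()
  re <- e[e$relation_type == "Regulation" & e$target %in% seeds &
            !(e$source %in% seeds), , drop = FALSE]
  if (nrow(re) > 0) {
    n_seed <- tapply(re$target, re$source, function(x) length(unique(x)))
    max_ref <- tapply(re$n_references, re$source, max)
    cand <- names(n_seed)
    ok <- n_seed >= params$min_connected &
      max_ref >= params$min_refs_regulator &
      db$degree[cand] >= reg_deg_cut
    regulators <- sort(cand[ok])
  }

  targets <- character()
  te <- e[e$relation_type == "Expression" & e$source %in% seeds &
            !(e$target %in% seeds), , drop = FALSE]
  if (nrow(te) > 0) {
    n_seed <- tapply(te$source, te$target, function(x) length(unique(x)))
    max_ref <- tapply(te$n_references, te$target, max)
    cand <- names(n_seed)
    ok <- n_seed >= params$min_connected &
      max_ref >= params$min_refs_target &
      db$degree[cand] >= params$min_degree_target
    targets <- sort(cand[ok])
  }

  keep_nodes <- c(seeds, regulators, targets)
  sub <- e[e$source %in% keep_nodes & e$target %in% keep_nodes, ,
           drop = FALSE]
  rownames(sub) <- NULL
  structure(list(seeds = seeds, regulators = regulators, targets = targets,
                 edges = sub, profile = profile, params = params),
            class = "network_extract")
}

#' @export
print.network_extract <- function(x, ...) {
  cat(sprintf("network_extract (%s): %d seeds, %d regulators, %d targets, %d edges\n",
              x$profile, length(x$seeds), length(x$regulators),
              length(x$targets), nrow(x$edges)))
  invisible(x)
}

#' Major regulators or targets shared by several networks
#'
#' Intersects the regulator (or target) sets of two or more network
#' extracts, identifying the nodes common to every network.
#'
#' @param extracts list of `network_extract` objects (length >= 2).
#' @param role `"regulator"` or `"target"`.
#' @return sorted character vector of shared gene ids.
#' @export
major_nodes <- function(extracts, role = c("regulator", "target")) {
  role <- match.arg(role)
  if (length(extracts) < 2) stop("need at least two network extracts")
  sets <- lapply(extracts, function(x)
    if (role == "regulator") x$regulators else x$targets)
  sort(Reduce(intersect, sets))
}

#' Edge subgraph on seeds plus a node set
#'
#' All database edges whose endpoints both lie in `seeds` or `nodes`.
#'
#' @param db an `interaction_db`.
#' @param seeds,nodes character vectors of gene ids.
#' @return data.frame of edges.
#' @export
subnetwork <- function(db, seeds, nodes = character()) {
  stopifnot(inherits(db, "interaction_db"))
  keep <- union(seeds, nodes)
  out <- db$edges[db$edges$source %in% keep & db$edges$target %in% keep, ,
                  drop = FALSE]
  rownames(out) <- NULL
  out
}
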