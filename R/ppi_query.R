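# Subnetwork queries over an interactome: induced subgraphs from a gene list,
# k-hop neighborhood expansion around a seed, and annotation-driven filtering.

#' Resolve mixed identifiers against an interactome
#'
#' Query lists may mix node ids, NCBI-style gene ids, symbols and protein
#' accessions. Resolution order per entry: exact `node_id`, then `gene_id`,
#' then `symbol` (case-insensitive), then `protein_id`. A symbol matching
#' several distinct nodes is an error naming the candidates.
#'
#' @param graph An `interactome`.
#' @param ids Character (or integer) vector of identifiers.
#' @return Tibble with columns `query`, `node_id` (`NA` when unresolved).
#' @export
resolve_ids <- function(graph, ids) {
  stopifnot(inherits(graph, "interactome"))
  nd <- graph$nodes
  resolve1 <- function(q) {
    if (q %in% nd$node_id) return(q)
    hit <- nd$node_id[!is.na(nd$gene_id) & as.character(nd$gene_id) == q]
    if (length(hit) == 1) return(hit)
    hit <- nd$node_id[!is.na(nd$symbol) & tolower(nd$symbol) == tolower(q)]
    if (length(hit) > 1) {
      abort(sprintf("ambiguous symbol '%s': candidates %s",
                    q, paste(sort(hit), collapse = ", ")),
            class = "sgpnet_lookup_error")
    }
    if (length(hit) == 1) return(hit)
    hit <- nd$node_id[!is.na(nd$protein_id) & nd$protein_id == q]
    if (length(hit) == 1) return(hit)
    NA_character_
  }
  ids <- as.character(ids)
  tibble(query = ids,
         node_id = unname(vapply(ids, resolve1, character(1))))
}

#' Induce the subnetwork on a query gene list
#'
#' Returns the subgraph induced on the resolved query set: exactly the edges
#' of `graph` whose both endpoints were queried — the pairwise "binary
#' associations" among the listed genes. Unresolvable entries are reported
#' with a warning, never fatal; an empty query warns and returns an empty
#' graph.
#'
#' @param genes Character vector of identifiers (any kind [resolve_ids()]
#'   accepts).
#' @param graph An `interactome`.
#' @return An `interactome` on the resolved nodes; attribute `"unresolved"`
#'   lists query entries that matched nothing.
#' @examples
#' g <- toy_interactome()
#' tidy(induce_subnetwork(c("A2M", "APP", "APOE"), g))
#' @export
induce_subnetwork <- function(genes, graph) {
  stopifnot(inherits(graph, "interactome"))
  if (length(genes) == 0) {
    warn("empty query list; returning empty graph")
    out <- interactome()
    attr(out, "unresolved") <- character()
    return(out)
  }
  res <- resolve_ids(graph, genes)
  unresolved <- res$query[is.na(res$node_id)]
  if (length(unresolved) > 0) {
    warn(sprintf("unresolved identifiers dropped: %s",
                 paste(unresolved, collapse = ", ")))
  }
  keep <- unique(res$node_id[!is.na(res$node_id)])
  out <- subgraph_on(graph, keep)
  attr(out, "unresolved") <- unresolved
  out
}

# induced subgraph on a node-id set, annotations restricted alongside
subgraph_on <- function(graph, node_ids) {
  nodes <- graph$nodes[graph$nodes$node_id %in% node_ids, ]
  edges <- graph$edges[graph$edges$a %in% node_ids &
                         graph$edges$b %in% node_ids, ]
  ann <- graph$annotations[graph$annotations$node_id %in% node_ids, ]
  g <- interactome(edges = edges, nodes = nodes)
  g$annotations <- ann
  g
}

#' Expand the k-hop neighborhood around a seed protein
#'
#' Returns the subgraph induced on every node at shortest-path distance
#' `<= k` from the seed (the seed's degree-`k` neighborhood). Neighborhood
#' degree is capped — by default at 3, mirroring the usual limit beyond
#' which PPI neighborhoods explode — but the cap is overridable.
#'
#' The result carries a per-level summary (attribute `"levels"`, also
#' returned by [neighborhood_levels()]): for each distance `d = 0..k`, the
#' number of new nodes at that level and cumulative node/edge counts of the
#' induced subgraph on the ball of radius `d`.
#'
#' @param seed A single identifier resolvable by [resolve_ids()].
#' @param k Neighborhood degree, `1 <= k <= cap`.
#' @param graph An `interactome`.
#' @param cap Maximum permitted `k` (default 3).
#' @param include_self_loops Include self-loop edges in expansion? Default
#'   `FALSE`; stored self-loops never widen a neighborhood.
#' @return An `interactome`; `attr(, "levels")` holds the level summary.
#' @examples
#' g <- toy_interactome()
#' nb <- expand_neighborhood("ANG", 1, g)
#' setdiff(nb$nodes$node_id, "ANG")   # the seven first neighbours
#' @export
expand_neighborhood <- function(seed, k, graph, cap = 3L,
                                include_self_loops = FALSE) {
  stopifnot(inherits(graph, "interactome"))
  if (length(seed) != 1) abort("seed must be a single identifier",
                               class = "sgpnet_argument_error")
  if (!is.numeric(k) || k != as.integer(k) || k < 1 || k > cap) {
    abort(sprintf("k must be an integer in 1..%d", cap),
          class = "sgpnet_argument_error")
  }
  res <- resolve_ids(graph, seed)
  if (is.na(res$node_id[1])) {
    abort(sprintf("seed '%s' not found in graph", seed),
          class = "sgpnet_lookup_error")
  }
  seed_id <- res$node_id[1]

  work <- graph
  if (!include_self_loops) {
    work$edges <- work$edges[work$edges$a != work$edges$b, ]
  }
  ig <- as_igraph(work)
  d <- igraph::distances(ig, v = seed_id)[1, ]

  levels <- purrr::map_dfr(0:as.integer(k), function(lev) {
    ball <- names(d)[is.finite(d) & d <= lev]
    sub_edges <- work$edges[work$edges$a %in% ball & work$edges$b %in% ball, ]
    tibble(
      k = lev,
      n_new_nodes = sum(is.finite(d) & d == lev),
      n_nodes = length(ball),
      n_edges = nrow(sub_edges)
    )
  })
  ball <- names(d)[is.finite(d) & d <= k]
  out <- subgraph_on(graph, ball)
  if (!include_self_loops) {
    out$edges <- out$edges[out$edges$a != out$edges$b, ]
  }
  attr(out, "levels") <- levels
  attr(out, "seed") <- seed_id
  out
}

#' Per-level counts of a neighborhood expansion
#'
#' @param neighborhood Result of [expand_neighborhood()].
#' @return Tibble with columns `k`, `n_new_nodes`, `n_nodes`, `n_edges`
#'   (cumulative counts describe the induced subgraph on the radius-`k`
#'   ball).
#' @export
neighborhood_levels <- function(neighborhood) {
  lv <- attr(neighborhood, "levels")
  if (is.null(lv)) abort("not a neighborhood result",
                         class = "sgpnet_argument_error")
  lv
}

#' Filter or group a network by annotation
#'
#' With `term` given, returns the subgraph induced on the nodes annotated
#' with that term in the chosen category. Without `term`, partitions the
#' annotated nodes into term-wise groups (a node annotated with several
#' terms appears in several groups).
#'
#' @param graph An annotated `interactome`.
#' @param category One of `"function"`, `"phenotype"`, `"pathway"`.
#' @param term Annotation term, or `NULL` to group.
#' @return With `term`: an `interactome`. Without: a tibble with columns
#'   `term`, `n_nodes`, `node_ids` (list-column).
#' @examples
#' g <- toy_interactome()
#' nb <- expand_neighborhood("ANG", 1, g)
#' sort(filter_network(nb, "function", "apoptosis")$nodes$node_id)
#' @export
filter_network <- function(graph, category, term = NULL) {
  stopifnot(inherits(graph, "interactome"))
  if (!is.character(category) || length(category) != 1 ||
      !category %in% annotation_categories()) {
    abort(sprintf("category must be one of %s",
                  paste(annotation_categories(), collapse = ", ")),
          class = "sgpnet_argument_error")
  }
  ann <- graph$annotations[graph$annotations$category == category, ]
  if (is.null(term)) {
    return(
      ann %>%
        group_by(term = .data$term) %>%
        summarise(
          n_nodes = length(unique(.data$node_id)),
          node_ids = list(sort(unique(.data$node_id))),
          .groups = "drop"
        ) %>%
        arrange(dplyr::desc(.data$n_nodes), .data$term)
    )
  }
  hits <- unique(ann$node_id[ann$term == term])
  subgraph_on(graph, hits)
}
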