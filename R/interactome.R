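#' @import rlang
#' @importFrom dplyr %>% filter mutate select arrange distinct group_by summarise ungroup
#'   bind_rows left_join anti_join semi_join rename row_number across all_of n pull
#' @importFrom tibble tibble as_tibble
#' @importFrom rlang .data abort warn inform `%||%`
NULL

# ---- construction -----------------------------------------------------------

#' Build a molecular interaction graph from tidy node and edge tables
#'
#' An `interactome` is the package's container for an undirected molecular
#' interaction network. It is a list of two tibbles: `nodes` (one row per
#' molecule, keyed by `node_id`, optionally carrying an NCBI-style integer
#' `gene_id`, a display `symbol`, a UniProt-style `protein_id`, a cellular
#' `location`, and annotation term sets) and `edges` (one row per undirected
#' edge, stored canonically with `a <= b` under `node_id` ordering, with a
#' list-column `provenance` of source tags).
#'
#' Undirected edges are deduplicated on construction: `(a, b)` and `(b, a)`
#' are the same edge and their provenance sets are merged. Edge endpoints
#' absent from `nodes` are added as identifier-only nodes, so an interactome
#' can be built from an edge table alone.
#'
#' @param edges Data frame with character columns `a` and `b` (node ids);
#'   an optional `provenance` column (character or list of character).
#' @param nodes Optional data frame with column `node_id` and any of
#'   `gene_id`, `symbol`, `protein_id`, `location`.
#' @param annotations Optional data frame with columns `node_id`,
#'   `category` (one of `"function"`, `"phenotype"`, `"pathway"`) and `term`.
#' @return An object of class `interactome`.
#' @examples
#' g <- interactome(data.frame(a = c("A2M", "APOE"), b = c("APOE", "APP")))
#' glance(g)
#' @export
interactome <- function(edges = NULL, nodes = NULL, annotations = NULL) {
  nodes <- normalise_node_table(nodes)
  edges <- normalise_edge_table(edges)

  missing_ids <- setdiff(unique(c(edges$a, edges$b)), nodes$node_id)
  if (length(missing_ids) > 0) {
    nodes <- bind_rows(nodes, empty_node_table(missing_ids))
  }
  if (anyDuplicated(nodes$node_id)) {
    abort(sprintf(
      "duplicate node_id in node table: %s",
      paste(unique(nodes$node_id[duplicated(nodes$node_id)]), collapse = ", ")
    ), class = "sgpnet_input_error")
  }
  bad <- nodes$node_id == "" | is.na(nodes$node_id)
  if (any(bad)) {
    abort("node_id must be non-missing and non-empty", class = "sgpnet_input_error")
  }

  g <- structure(
    list(nodes = nodes, edges = edges, annotations = empty_annotation_table()),
    class = "interactome"
  )
  if (!is.null(annotations)) g <- set_annotations(g, annotations)
  g
}

normalise_node_table <- function(nodes) {
  if (is.null(nodes)) return(empty_node_table(character()))
  nodes <- as_tibble(nodes)
  if (!"node_id" %in% names(nodes)) {
    abort("node table must have a node_id column", class = "sgpnet_config_error")
  }
  for (col in c("symbol", "protein_id", "location")) {
    if (!col %in% names(nodes)) nodes[[col]] <- NA_character_
    nodes[[col]] <- as.character(nodes[[col]])
  }
  if (!"gene_id" %in% names(nodes)) nodes$gene_id <- NA_integer_
  nodes$gene_id <- as.integer(nodes$gene_id)
  nodes$node_id <- as.character(nodes$node_id)
  nodes[c("node_id", "gene_id", "symbol", "protein_id", "location")]
}

empty_node_table <- function(ids) {
  tibble(
    node_id = as.character(ids), gene_id = NA_integer_,
    symbol = NA_character_, protein_id = NA_character_,
    location = NA_character_
  )
}

empty_annotation_table <- function() {
  tibble(node_id = character(), category = character(), term = character())
}

# canonical undirected storage: a <= b, provenance sets merged across duplicates
normalise_edge_table <- function(edges) {
  if (is.null(edges) || nrow(as_tibble(edges)) == 0) {
    return(tibble(a = character(), b = character(), provenance = list()))
  }
  edges <- as_tibble(edges)
  if (!all(c("a", "b") %in% names(edges))) {
    abort("edge table must have columns a and b", class = "sgpnet_config_error")
  }
  edges$a <- as.character(edges$a)
  edges$b <- as.character(edges$b)
  if (!"provenance" %in% names(edges)) {
    edges$provenance <- vector("list", nrow(edges))
  } else if (!is.list(edges$provenance)) {
    edges$provenance <- lapply(edges$provenance, function(x) {
      if (is.na(x) || x == "") character() else as.character(x)
    })
  }
  swap <- edges$a > edges$b
  tmp <- edges$a[swap]
  edges$a[swap] <- edges$b[swap]
  edges$b[swap] <- tmp

  key <- paste(edges$a, edges$b, sep = "\r")
  merged <- lapply(split(edges$provenance, key), function(sets) {
    sort(unique(unlist(sets, use.names = FALSE)))
  })
  first <- !duplicated(key)
  out <- edges[first, c("a", "b")]
  out$provenance <- unname(merged[paste(out$a, out$b, sep = "\r")])
  arrange(out, .data$a, .data$b)
}

#' @export
print.interactome <- function(x, ...) {
  cat(sprintf(
    "<interactome> %d nodes, %d edges, %d annotation records\n",
    nrow(x$nodes), nrow(x$edges), nrow(x$annotations)
  ))
  invisible(x)
}

#' Count nodes and edges of an interactome
#'
#' @param x An `interactome`.
#' @param ... Unused.
#' @return A one-row tibble with `n_nodes`, `n_edges`, `n_annotated` (nodes
#'   carrying at least one annotation term).
#' @export
glance.interactome <- function(x, ...) {
  tibble(
    n_nodes = nrow(x$nodes),
    n_edges = nrow(x$edges),
    n_annotated = length(unique(x$annotations$node_id))
  )
}

#' Tidy an interactome into its edge table
#'
#' @param x An `interactome`.
#' @param ... Unused.
#' @return The canonical edge tibble (`a`, `b`, `provenance`).
#' @export
tidy.interactome <- function(x, ...) x$edges

#' Test whether an undirected edge is present
#'
#' Membership is symmetric: `has_edge(g, a, b)` equals `has_edge(g, b, a)`.
#'
#' @param graph An `interactome`.
#' @param a,b Node ids.
#' @return Logical scalar.
#' @export
has_edge <- function(graph, a, b) {
  stopifnot(inherits(graph, "interactome"))
  lo <- pmin(a, b); hi <- pmax(a, b)
  any(graph$edges$a == lo & graph$edges$b == hi)
}

# ---- annotations ------------------------------------------------------------

#' Attach annotation records to an interactome
#'
#' @param graph An `interactome`.
#' @param annotations Data frame with columns `node_id`, `category`
#'   (`function`/`phenotype`/`pathway`) and `term`, e.g. from
#'   [read_annotations()]. Records for node ids absent from the graph are
#'   kept (they attach if the node appears later via merging).
#' @return The graph with annotations replaced.
#' @export
set_annotations <- function(graph, annotations) {
  stopifnot(inherits(graph, "interactome"))
  annotations <- as_tibble(annotations)
  need <- c("node_id", "category", "term")
  if (!all(need %in% names(annotations))) {
    abort("annotations need columns node_id, category, term",
          class = "sgpnet_config_error")
  }
  bad <- !annotations$category %in% annotation_categories()
  if (any(bad)) {
    abort(sprintf("unknown annotation category: %s",
                  paste(unique(annotations$category[bad]), collapse = ", ")),
          class = "sgpnet_input_error")
  }
  graph$annotations <- annotations %>%
    mutate(across(all_of(need), as.character)) %>%
    select(all_of(need)) %>%
    distinct() %>%
    arrange(.data$node_id, .data$category, .data$term)
  graph
}

annotation_categories <- function() c("function", "phenotype", "pathway")

#' Annotation sets for one node
#'
#' @param graph An `interactome`.
#' @param node_id Node id.
#' @return Named list of three character vectors: `function`, `phenotype`,
#'   `pathway` (empty when unannotated).
#' @export
node_annotations <- function(graph, node_id) {
  stopifnot(inherits(graph, "interactome"))
  recs <- graph$annotations[graph$annotations$node_id == node_id, ]
  out <- lapply(annotation_categories(), function(cat) {
    sort(recs$term[recs$category == cat])
  })
  names(out) <- annotation_categories()
  out
}

# ---- file I/O ---------------------------------------------------------------

#' Read a tab-separated interaction edge table
#'
#' Reads a TSV of pairwise molecular interactions into an [interactome()].
#' The column mapping is explicit (`dialect`) rather than sniffed, so loads
#' are reproducible byte-for-byte. Duplicate pairs — in either orientation —
#' collapse to one undirected edge with merged provenance tags. Identifiers
#' seen only in the edge list become nodes with just that identifier set.
#'
#' Lines starting with `#` are comments; an empty file yields an empty graph.
#'
#' @param path Path to a UTF-8 tab-separated file.
#' @param dialect Named list mapping roles to column names:
#'   `a` and `b` (required), and optionally `provenance`, `gene_id_a`,
#'   `gene_id_b`, `protein_id_a`, `protein_id_b`, `location_a`, `location_b`.
#' @param col_names Does the file carry a header line? If `FALSE`, columns
#'   are addressed as `X1`, `X2`, ...
#' @return An `interactome`.
#' @examples
#' tsv <- tempfile(fileext = ".tsv")
#' writeLines(c("a\tb", "A2M\tAPOE", "APOE\tAPP", "APP\tAPOE"), tsv)
#' g <- read_edge_table(tsv)
#' glance(g)   # 3 nodes, 2 edges
#' @export
read_edge_table <- function(path, dialect = list(a = "a", b = "b"),
                            col_names = TRUE) {
  if (is.null(dialect$a) || is.null(dialect$b)) {
    abort("dialect must map both 'a' and 'b' to column names",
          class = "sgpnet_config_error")
  }
  raw <- readr::read_tsv(
    path, comment = "#", col_names = col_names,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE, show_col_types = FALSE
  )
  if (nrow(raw) == 0) return(interactome())

  for (role in c("a", "b")) {
    if (!dialect[[role]] %in% names(raw)) {
      abort(sprintf("mapped column '%s' (role %s) not found in %s",
                    dialect[[role]], role, path),
            class = "sgpnet_config_error")
    }
  }
  edges <- tibble(a = raw[[dialect$a]], b = raw[[dialect$b]])
  if (!is.null(dialect$provenance)) {
    if (!dialect$provenance %in% names(raw)) {
      abort(sprintf("mapped column '%s' (role provenance) not found",
                    dialect$provenance), class = "sgpnet_config_error")
    }
    edges$provenance <- raw[[dialect$provenance]]
  }

  nodes <- empty_node_table(sort(unique(c(edges$a, edges$b))))
  take <- function(role, endpoint_col, target, as_int = FALSE) {
    colname <- dialect[[role]]
    if (is.null(colname)) return()
    if (!colname %in% names(raw)) {
      abort(sprintf("mapped column '%s' (role %s) not found", colname, role),
            class = "sgpnet_config_error")
    }
    vals <- stats::setNames(raw[[colname]], raw[[endpoint_col]])
    vals <- vals[!is.na(vals) & !duplicated(names(vals))]
    idx <- match(names(vals), nodes$node_id)
    nodes[[target]][idx] <<- if (as_int) as.integer(vals) else unname(vals)
  }
  take("gene_id_a", dialect$a, "gene_id", as_int = TRUE)
  take("gene_id_b", dialect$b, "gene_id", as_int = TRUE)
  take("protein_id_a", dialect$a, "protein_id")
  take("protein_id_b", dialect$b, "protein_id")
  take("location_a", dialect$a, "location")
  take("location_b", dialect$b, "location")
  nodes$symbol <- nodes$node_id

  interactome(edges = edges, nodes = nodes)
}

#' Read a node annotation table
#'
#' Expects a headerless (or headed) TSV with three columns: node id,
#' category (`function`, `phenotype` or `pathway`) and term. Unknown
#' categories are an input error citing the offending line number.
#'
#' @param path Path to a tab-separated file; `#` lines are comments.
#' @param col_names Whether the file has a header row.
#' @return Tibble with columns `node_id`, `category`, `term`, suitable for
#'   [set_annotations()]. An empty file gives an empty tibble.
#' @export
read_annotations <- function(path, col_names = FALSE) {
  lines <- readr::read_lines(path, progress = FALSE)
  keep <- !startsWith(trimws(lines), "#") & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (col_names && length(lines) > 0) {
    lines <- lines[-1]
    lineno <- lineno[-1]
  }
  if (length(lines) == 0) return(empty_annotation_table())

  parts <- stringr::str_split_fixed(lines, "\t", 3)
  bad_shape <- parts[, 3] == "" | parts[, 1] == ""
  if (any(bad_shape)) {
    abort(sprintf("annotation line %d is not 3 tab-separated fields",
                  lineno[which(bad_shape)[1]]),
          class = "sgpnet_input_error")
  }
  cat_col <- trimws(parts[, 2])
  bad <- !cat_col %in% annotation_categories()
  if (any(bad)) {
    i <- which(bad)[1]
    abort(sprintf("unknown annotation category '%s' at line %d of %s",
                  cat_col[i], lineno[i], path),
          class = "sgpnet_input_error")
  }
  tibble(
    node_id = trimws(parts[, 1]),
    category = cat_col,
    term = trimws(parts[, 3])
  ) %>% distinct()
}

#' Write an interactome as a Cytoscape SIF file with a node-attribute sidecar
#'
#' Emits one `a<TAB>pp<TAB>b` line per edge in stable lexicographic order,
#' ready for Cytoscape import, plus a TSV of node attributes (gene and
#' protein identifiers, location) next to it.
#'
#' @param graph An `interactome`.
#' @param path Output SIF path.
#' @param attributes_path Output path of the node-attribute TSV; default
#'   `paste0(path, ".nodes.tsv")`.
#' @param interaction_type Interaction-type token on every SIF line.
#' @return Invisibly, `path`.
#' @export
write_sif <- function(graph, path, attributes_path = paste0(path, ".nodes.tsv"),
                      interaction_type = "pp") {
  stopifnot(inherits(graph, "interactome"))
  edges <- arrange(graph$edges, .data$a, .data$b)
  lines <- if (nrow(edges) == 0) character() else
    paste(edges$a, interaction_type, edges$b, sep = "\t")
  writeLines(lines, path, useBytes = TRUE)

  nodes <- arrange(graph$nodes, .data$node_id)
  readr::write_tsv(nodes, attributes_path, progress = FALSE)
  invisible(path)
}

#' Read a SIF file back into an interactome
#'
#' Companion to [write_sif()]; the interaction-type column is discarded and
#' the attribute sidecar, when present, restores node identifiers.
#'
#' @param path SIF path.
#' @param attributes_path Node-attribute TSV path (read if the file exists).
#' @return An `interactome`.
#' @export
read_sif <- function(path, attributes_path = paste0(path, ".nodes.tsv")) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  nodes <- NULL
  if (file.exists(attributes_path)) {
    nodes <- readr::read_tsv(attributes_path, show_col_types = FALSE,
                             progress = FALSE)
  }
  if (length(lines) == 0) return(interactome(nodes = nodes))
  parts <- stringr::str_split_fixed(lines, "\t", 3)
  interactome(edges = tibble(a = parts[, 1], b = parts[, 3]), nodes = nodes)
}

#' Plot an interactome
#'
#' Force-directed layout (Fruchterman-Reingold, seeded for determinism)
#' rendered with ggplot2.
#'
#' @param object An `interactome`.
#' @param seed Layout seed.
#' @param label Draw node labels?
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.interactome <- function(object, seed = 1L, label = TRUE, ...) {
  ig <- as_igraph(object)
  xy <- withr::with_seed(seed, igraph::layout_with_fr(ig))
  pts <- tibble(
    node_id = igraph::V(ig)$name,
    x = xy[, 1], y = xy[, 2]
  )
  seg <- object$edges %>%
    left_join(pts, by = c(a = "node_id")) %>%
    rename(xa = "x", ya = "y") %>%
    left_join(pts, by = c(b = "node_id")) %>%
    rename(xb = "x", yb = "y")
  p <- ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$xa, y = .data$ya, xend = .data$xb, yend = .data$yb),
      colour = "grey60"
    ) +
    ggplot2::geom_point(data = pts, ggplot2::aes(.data$x, .data$y), size = 3) +
    ggplot2::theme_void()
  if (label) {
    p <- p + ggplot2::geom_text(
      data = pts, ggplot2::aes(.data$x, .data$y, label = .data$node_id),
      vjust = -1, size = 3
    )
  }
  p
}

# igraph view used for distance queries; undirected simple graph
as_igraph <- function(graph) {
  igraph::graph_from_data_frame(
    d = graph$edges[, c("a", "b")],
    directed = FALSE,
    vertices = graph$nodes$node_id
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
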