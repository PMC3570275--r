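# Projection networks: disease-disease graphs from shared or interacting
# gene products, and pathway-pathway crosstalk from shared components.

#' Construct a disease-gene association table
#'
#' @param disease Character vector of disease names.
#' @param gene Character vector of gene identifiers (same length).
#' @param evidence Optional character vector of reference tags.
#' @return Tibble of class `disease_gene_table` with unique
#'   `(disease, gene)` pairs.
#' @export
disease_gene_table <- function(disease, gene, evidence = NA_character_) {
  out <- tibble(
    disease = as.character(disease),
    gene = as.character(gene),
    evidence = as.character(evidence)
  ) %>% distinct(.data$disease, .data$gene, .keep_all = TRUE)
  if (nrow(out) == 0) abort("disease-gene table must be non-empty",
                            class = "sgpnet_input_error")
  class(out) <- c("disease_gene_table", class(out))
  out
}

#' Read a disease-gene TSV (disease, gene, evidence)
#'
#' @param path Tab-separated file with a header; `#` lines are comments.
#' @return A `disease_gene_table`.
#' @export
read_disease_gene_table <- function(path) {
  raw <- readr::read_tsv(path, comment = "#",
                         col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE, show_col_types = FALSE)
  need <- c("disease", "gene")
  if (!all(need %in% names(raw))) {
    abort("disease-gene table needs columns: disease, gene",
          class = "sgpnet_config_error")
  }
  disease_gene_table(raw$disease, raw$gene,
                     raw$evidence %||% NA_character_)
}

#' Project a disease-gene table onto a weighted disease-disease network
#'
#' Two diseases are linked when their gene sets overlap (`mode = "shared"`,
#' weight = number of shared genes) or, given a PPI graph, when some gene
#' product of one interacts with a gene product of the other
#' (`mode = "interacting"`, weight = number of interacting cross pairs).
#' The projection is symmetric and has no self-edges; only disease pairs
#' with weight >= 1 are reported.
#'
#' @param table A `disease_gene_table` (or plain data frame with `disease`
#'   and `gene` columns).
#' @param mode `"shared"` (default) or `"interacting"`.
#' @param ppi An `interactome`; required for `mode = "interacting"`.
#' @return Tibble with columns `disease_a`, `disease_b` (`a < b`
#'   lexicographically), `weight`, `mode`, sorted by weight descending then
#'   names.
#' @export
disease_projection <- function(table, mode = c("shared", "interacting"),
                               ppi = NULL) {
  mode <- match.arg(mode)
  table <- as_tibble(table)
  if (nrow(table) == 0) abort("disease-gene table must be non-empty",
                              class = "sgpnet_input_error")
  if (mode == "interacting" && is.null(ppi)) {
    abort("mode 'interacting' requires a ppi graph", class = "sgpnet_argument_error")
  }
  gene_sets <- split(table$gene, table$disease)
  gene_sets <- lapply(gene_sets, unique)
  diseases <- sort(names(gene_sets))
  if (length(diseases) < 2) {
    out <- tibble(disease_a = character(), disease_b = character(),
                  weight = integer(), mode = character())
    return(out)
  }
  pairs <- utils::combn(diseases, 2)
  weight <- vapply(seq_len(ncol(pairs)), function(i) {
    ga <- gene_sets[[pairs[1, i]]]
    gb <- gene_sets[[pairs[2, i]]]
    if (mode == "shared") {
      length(intersect(ga, gb))
    } else {
      grid <- expand.grid(a = ga, b = gb, stringsAsFactors = FALSE)
      sum(mapply(function(x, y) has_edge(ppi, x, y), grid$a, grid$b))
    }
  }, integer(1))
  tibble(
    disease_a = pairs[1, ], disease_b = pairs[2, ],
    weight = weight, mode = mode
  ) %>%
    filter(.data$weight >= 1) %>%
    arrange(dplyr::desc(.data$weight), .data$disease_a, .data$disease_b)
}

# ---- pathway definitions ----------------------------------------------------

pathway_edge_classes <- function() {
  c("sig_sig", "sig_prot", "sig_gene", "prot_prot", "prot_gene", "gene_gene")
}
species_classes <- function() c("signal", "protein", "gene")

# a typed edge class is consistent with its endpoints' species classes
class_endpoint_species <- function(cls) {
  switch(cls,
    sig_sig   = c("signal", "signal"),
    sig_prot  = c("signal", "protein"),
    sig_gene  = c("signal", "gene"),
    prot_prot = c("protein", "protein"),
    prot_gene = c("protein", "gene"),
    gene_gene = c("gene", "gene")
  )
}

#' Construct a typed pathway definition
#'
#' A pathway is a named set of members, each a signal, protein or gene,
#' plus signed interactions split into six typed classes by endpoint
#' species (signal-signal, signal-protein, signal-gene, protein-protein,
#' protein-gene, gene-gene). Each interaction is directed `from -> to` and
#' carries a sign: `activation` or `inhibition`.
#'
#' @param name Pathway name.
#' @param members Data frame with columns `id`, `species`
#'   (`signal`/`protein`/`gene`) and optionally `location`.
#' @param interactions Data frame with columns `class` (one of the six
#'   types), `from`, `to`, `sign` (`activation`/`inhibition`). May be empty.
#' @return Object of class `pathway_definition`.
#' @export
pathway_definition <- function(name, members, interactions = NULL) {
  members <- as_tibble(members)
  if (!all(c("id", "species") %in% names(members))) {
    abort("members need columns id, species", class = "sgpnet_config_error")
  }
  if (!"location" %in% names(members)) members$location <- NA_character_
  members <- members %>%
    mutate(across(c("id", "species", "location"), as.character)) %>%
    select("id", "species", "location") %>%
    distinct(.data$id, .keep_all = TRUE) %>%
    arrange(.data$id)
  bad <- !members$species %in% species_classes()
  if (any(bad)) {
    abort(sprintf("unknown species class: %s",
                  paste(unique(members$species[bad]), collapse = ", ")),
          class = "sgpnet_input_error")
  }
  if (is.null(interactions)) {
    interactions <- tibble(class = character(), from = character(),
                           to = character(), sign = character())
  }
  interactions <- as_tibble(interactions)
  need <- c("class", "from", "to", "sign")
  if (!all(need %in% names(interactions))) {
    abort("interactions need columns class, from, to, sign",
          class = "sgpnet_config_error")
  }
  interactions <- interactions %>%
    mutate(across(all_of(need), as.character)) %>%
    select(all_of(need)) %>%
    arrange(.data$class, .data$from, .data$to)
  if (nrow(interactions) > 0) {
    bad_cls <- !interactions$class %in% pathway_edge_classes()
    if (any(bad_cls)) {
      abort(sprintf("unknown interaction class: %s",
                    paste(unique(interactions$class[bad_cls]), collapse = ", ")),
            class = "sgpnet_input_error")
    }
    bad_sign <- !interactions$sign %in% c("activation", "inhibition")
    if (any(bad_sign)) {
      abort("interaction sign must be activation or inhibition",
            class = "sgpnet_input_error")
    }
    ends <- unique(c(interactions$from, interactions$to))
    missing <- setdiff(ends, members$id)
    if (length(missing) > 0) {
      abort(sprintf("interaction endpoint(s) not in members: %s",
                    paste(missing, collapse = ", ")),
            class = "sgpnet_input_error")
    }
    sp <- stats::setNames(members$species, members$id)
    for (i in seq_len(nrow(interactions))) {
      want <- class_endpoint_species(interactions$class[i])
      got <- c(sp[[interactions$from[i]]], sp[[interactions$to[i]]])
      ok <- identical(sort(got), sort(want))
      if (!ok) {
        abort(sprintf(
          "interaction %s -> %s typed %s but endpoints are %s/%s",
          interactions$from[i], interactions$to[i],
          interactions$class[i], got[1], got[2]
        ), class = "sgpnet_input_error")
      }
    }
  }
  structure(
    list(name = as.character(name), members = members,
         interactions = interactions),
    class = "pathway_definition"
  )
}

#' @export
print.pathway_definition <- function(x, ...) {
  cat(sprintf("<pathway_definition> %s: %d members, %d interactions\n",
              x$name, nrow(x$members), nrow(x$interactions)))
  invisible(x)
}

#' @describeIn pathway_definition one-row summary (member and interaction
#'   counts, per-class breakdown columns).
#' @param x A `pathway_definition`.
#' @param ... Unused.
#' @export
glance.pathway_definition <- function(x, ...) {
  counts <- table(factor(x$interactions$class, levels = pathway_edge_classes()))
  out <- tibble(name = x$name, n_members = nrow(x$members),
                n_interactions = nrow(x$interactions))
  for (cls in pathway_edge_classes()) out[[cls]] <- as.integer(counts[[cls]])
  out
}

#' Read / write pathway definitions as structured YAML
#'
#' One YAML document per pathway: `name`, `members` (list of `id`,
#' `species`, optional `location`) and `interactions` (list of `class`,
#' `from`, `to`, `sign`).
#'
#' @param path YAML file path.
#' @return `read_pathway()` returns a `pathway_definition`;
#'   `write_pathway()` invisibly returns `path`.
#' @export
read_pathway <- function(path) {
  doc <- yaml::read_yaml(path)
  members <- purrr::map_dfr(doc$members, function(m) {
    tibble(id = m$id, species = m$species,
           location = m$location %||% NA_character_)
  })
  interactions <- if (length(doc$interactions) == 0) NULL else
    purrr::map_dfr(doc$interactions, as_tibble)
  pathway_definition(doc$name, members, interactions)
}

#' @rdname read_pathway
#' @param pathway A `pathway_definition`.
#' @export
write_pathway <- function(pathway, path) {
  stopifnot(inherits(pathway, "pathway_definition"))
  doc <- list(
    name = pathway$name,
    members = purrr::pmap(pathway$members, function(id, species, location) {
      m <- list(id = id, species = species)
      if (!is.na(location)) m$location <- location
      m
    }),
    interactions = purrr::pmap(pathway$interactions,
                               function(class, from, to, sign) {
                                 list(class = class, from = from,
                                      to = to, sign = sign)
                               })
  )
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' Rank pathway crosstalk by shared components
#'
#' For every catalog pathway other than the query that shares at least one
#' member, reports the shared-member count and list, ranked by count
#' descending then name — the standard shared-components notion of pathway
#' crosstalk. A secondary column counts shared interactions (same class,
#' endpoints and sign in both pathways), since crosstalk is sometimes read
#' at the edge level.
#'
#' @param query A `pathway_definition`.
#' @param catalog List of `pathway_definition`s (the query itself may or
#'   may not be among them; it is skipped by name). Duplicate names are an
#'   input error.
#' @return Tibble with columns `pathway`, `shared_n`, `shared_members`
#'   (list-column, sorted), `shared_edges`.
#' @export
pathway_crosstalk <- function(query, catalog) {
  stopifnot(inherits(query, "pathway_definition"))
  if (length(catalog) == 0) abort("catalog must be non-empty",
                                  class = "sgpnet_input_error")
  names_cat <- vapply(catalog, function(p) p$name, character(1))
  if (anyDuplicated(names_cat)) {
    abort(sprintf("duplicate pathway names in catalog: %s",
                  paste(unique(names_cat[duplicated(names_cat)]), collapse = ", ")),
          class = "sgpnet_input_error")
  }
  edge_key <- function(p) {
    if (nrow(p$interactions) == 0) return(character())
    with(p$interactions, paste(class, from, to, sign, sep = "\r"))
  }
  q_members <- query$members$id
  q_edges <- edge_key(query)
  rows <- purrr::map_dfr(catalog, function(p) {
    if (p$name == query$name) return(NULL)
    shared <- sort(intersect(q_members, p$members$id))
    if (length(shared) == 0) return(NULL)
    tibble(
      pathway = p$name,
      shared_n = length(shared),
      shared_members = list(shared),
      shared_edges = length(intersect(q_edges, edge_key(p)))
    )
  })
  if (nrow(rows) == 0) {
    return(tibble(pathway = character(), shared_n = integer(),
                  shared_members = list(), shared_edges = integer()))
  }
  arrange(rows, dplyr::desc(.data$shared_n), .data$pathway)
}

#' Write a ranked crosstalk table as plain text
#'
#' One line per partner pathway: name, shared count, shared-edge count and
#' the comma-separated shared members; a `#`-header records the query name.
#'
#' @param crosstalk Result of [pathway_crosstalk()].
#' @param path Output path.
#' @param query_name Query pathway name recorded in the header.
#' @return Invisibly, `path`.
#' @export
write_crosstalk <- function(crosstalk, path, query_name = "") {
  header <- sprintf("# pathway crosstalk for query: %s", query_name)
  body <- if (nrow(crosstalk) == 0) character() else
    sprintf("%s\t%d\t%d\t%s", crosstalk$pathway, crosstalk$shared_n,
            crosstalk$shared_edges,
            vapply(crosstalk$shared_members, paste, character(1), collapse = ","))
  writeLines(c(header, body), path, useBytes = TRUE)
  invisible(path)
}
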