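# Bundled worked-example fixtures and seeded random generators. Everything a
# test needs is built here in code; no downloads, no binary data.

#' Mammalian cell-cycle Boolean rules
#'
#' The ten-node logical model of the mammalian cell cycle (Faure et al.
#' 2006), written in the `$node[i] = expr;` rule syntax. Nodes, in index
#' order 1..10: CycD, Rb, E2F, CycE, CycA, p27, CDC20, CDH1, UbcH10, CycB.
#' The rule set has 49 literal occurrences (network edges). Synchronous
#' analysis yields one singleton attractor — the quiescent G0 state
#' `0100010100` (Rb, p27 and CDH1 on, cyclins off) — and a seven-state
#' cyclic attractor tracing the division cycle.
#'
#' @return `cellcycle_rules()`: the rule text (one statement per line) with
#'   node labels in `attr(, "labels")`. `cellcycle_network()`: the parsed
#'   logic-mode `boolean_network` with labels attached.
#' @examples
#' net <- cellcycle_network()
#' glance(net)   # 10 nodes, 49 edges
#' @export
cellcycle_rules <- function() {
  rules <- c(
    "$node[1] = $node[1];",
    "$node[2] = (!($node[1]) & !($node[4]) & !($node[5]) & !($node[10])) | ($node[6] & !($node[1]) & !($node[10]));",
    "$node[3] = (!($node[2]) & !($node[5]) & !($node[10])) | ($node[6] & !($node[2]) & !($node[10]));",
    "$node[4] = ($node[3] & !($node[2]));",
    "$node[5] = ($node[3] & !($node[2]) & !($node[7]) & !($node[8] & $node[9])) | ($node[5] & !($node[2]) & !($node[7]) & !($node[8] & $node[9]));",
    "$node[6] = (!($node[1]) & !($node[4]) & !($node[5]) & !($node[10])) |($node[6] & !($node[4] & $node[5]) & !($node[10]) & !($node[1]));",
    "$node[7] = $node[10];",
    "$node[8] = (!($node[5]) & !($node[10])) |$node[7] |($node[6] & !($node[10]));",
    "$node[9] = !($node[8]) |($node[8] & $node[9] & ($node[7] | $node[5] | $node[10]));",
    "$node[10] = (!($node[7]) & !($node[8]));"
  )
  text <- paste(rules, collapse = "\n")
  attr(text, "labels") <- cellcycle_labels()
  text
}

cellcycle_labels <- function() {
  c("CycD", "Rb", "E2F", "CycE", "CycA", "p27", "CDC20", "CDH1", "UbcH10",
    "CycB")
}

#' @rdname cellcycle_rules
#' @export
cellcycle_network <- function() {
  parse_rules(cellcycle_rules(), labels = cellcycle_labels())
}

#' Toy interactome for the worked examples
#'
#' A minimal annotated PPI fixture: the amyloid trio A2M-APOE-APP (whose
#' induced subnetwork is exactly the two binary associations A2M-APOE and
#' APOE-APP) plus angiogenin (ANG) with its seven first-neighbour proteins
#' ACTC1, ACTN2, ATP6AP1, PTEN, RNH1, TDGF1 and TNFSF8, annotated with the
#' functional groupings of the ALS case study (regulation of angiogenesis,
#' cardiac muscle development, vasculature development, apoptosis).
#'
#' @return An annotated `interactome` with 11 nodes and 9 edges.
#' @examples
#' g <- toy_interactome()
#' tidy(induce_subnetwork(c("A2M", "APP", "APOE"), g))
#' @export
toy_interactome <- function() {
  nodes <- tibble(
    node_id = c("A2M", "ACTC1", "ACTN2", "ANG", "APOE", "APP", "ATP6AP1",
                "PTEN", "RNH1", "TDGF1", "TNFSF8"),
    gene_id = c(2L, 70L, 88L, 283L, 348L, 351L, 537L, 5728L, 6050L, 6997L,
                944L),
    symbol = c("A2M", "ACTC1", "ACTN2", "ANG", "APOE", "APP", "ATP6AP1",
               "PTEN", "RNH1", "TDGF1", "TNFSF8"),
    protein_id = c("P01023", "P68032", "P35609", "P03950", "P02649",
                   "P05067", "Q15904", "P60484", "P13489", "P13385",
                   "P32971"),
    location = c("extracellular", "cytoplasm", "cytoplasm", "extracellular",
                 "extracellular", "membrane", "membrane", "cytoplasm",
                 "cytoplasm", "membrane", "membrane")
  )
  edges <- tibble(
    a = c("A2M", "APOE", "ANG", "ANG", "ANG", "ANG", "ANG", "ANG", "ANG"),
    b = c("APOE", "APP", "ACTC1", "ACTN2", "ATP6AP1", "PTEN", "RNH1",
          "TDGF1", "TNFSF8"),
    provenance = as.list(rep("fixture", 9))
  )
  ann <- tibble(
    node_id = c("RNH1",
                "ACTC1", "TDGF1", "PTEN",
                "ANG", "TDGF1", "PTEN",
                "TDGF1", "PTEN", "ACTN2", "TNFSF8", "ATP6AP1"),
    category = "function",
    term = c("regulation of angiogenesis",
             rep("cardiac muscle development", 3),
             rep("vasculature development", 3),
             rep("apoptosis", 5))
  )
  interactome(edges = edges, nodes = nodes, annotations = ann)
}

#' Synthetic presenilin signalling pathway fixture
#'
#' A small typed signal-protein-gene pathway around PSEN1 (gamma-secretase
#' complex, NOTCH1 cleavage to NICD, APP processing, Ca2+ leak sensed by
#' calmodulin), assembled for exercising the pathway container, crosstalk
#' ranking and SBML export. It is a synthetic structure-only stand-in, not
#' a curated pathway.
#'
#' @return A `pathway_definition` with 7 members and 7 typed interactions.
#' @export
psen1_pathway_synthetic <- function() {
  members <- tibble(
    id = c("APP", "Ca2+", "CAM", "NICD", "NOTCH1", "PSEN1", "gamma_secretase"),
    species = c("protein", "signal", "protein", "protein", "gene",
                "protein", "protein"),
    location = c("membrane", "ER", "cytoplasm", "nucleus", "nucleus",
                 "ER", "membrane")
  )
  interactions <- tibble(
    class = c("prot_prot", "prot_prot", "prot_gene", "prot_prot",
              "sig_prot", "sig_prot", "prot_prot"),
    from = c("PSEN1", "gamma_secretase", "NICD", "gamma_secretase",
             "Ca2+", "Ca2+", "PSEN1"),
    to = c("gamma_secretase", "APP", "NOTCH1", "NICD",
           "CAM", "PSEN1", "NICD"),
    sign = c("activation", "inhibition", "activation", "activation",
             "activation", "inhibition", "activation")
  )
  pathway_definition("PSEN1_signalling_synthetic", members, interactions)
}

# ---- seeded random generators ----------------------------------------------
# All generators are pure functions of their arguments: the seed drives R's
# default Mersenne-Twister stream via withr::with_seed, so repeated calls
# agree bit for bit and never disturb the caller's RNG state.

#' Deterministic random interactome
#'
#' Samples exactly `m` distinct undirected node pairs (no self-loops) over
#' `n` nodes labelled `g001, g002, ...`.
#'
#' @param n Number of nodes (>= 2).
#' @param m Number of edges; at most `n (n - 1) / 2`.
#' @param seed Integer seed; same seed, same graph.
#' @return An `interactome` with `n` nodes and `m` edges.
#' @export
random_interactome <- function(n, m, seed) {
  if (n < 2 || m < 0 || m > n * (n - 1) / 2) {
    abort("need n >= 2 and 0 <= m <= n(n-1)/2",
          class = "sgpnet_argument_error")
  }
  ids <- sprintf("g%03d", seq_len(n))
  withr::with_seed(seed, {
    # sample m pairs without replacement from the n(n-1)/2 pair space
    pairs <- which(upper.tri(matrix(TRUE, n, n)), arr.ind = TRUE)
    sel <- pairs[sample.int(nrow(pairs), m), , drop = FALSE]
    interactome(
      edges = tibble(a = ids[sel[, "row"]], b = ids[sel[, "col"]]),
      nodes = empty_node_table(ids)
    )
  })
}

#' Deterministic random Boolean network
#'
#' Per node, draws between 1 and `max_in_degree` distinct regulators. In
#' logic mode the node's rule combines its regulators (each possibly
#' negated) with random AND/OR connectives; in threshold mode each
#' regulator gets a random +1/-1 sign.
#'
#' @param n Number of nodes.
#' @param max_in_degree Largest allowed in-degree (>= 1).
#' @param mode `"logic"` or `"threshold"`.
#' @param seed Integer seed.
#' @return A `boolean_network`.
#' @export
random_boolean_network <- function(n, max_in_degree, mode = c("logic", "threshold"),
                                   seed = 1L) {
  mode <- match.arg(mode)
  if (n < 1 || max_in_degree < 1) {
    abort("need n >= 1 and max_in_degree >= 1", class = "sgpnet_argument_error")
  }
  withr::with_seed(seed, {
    if (mode == "logic") {
      rules <- lapply(seq_len(n), function(i) {
        k <- sample.int(min(max_in_degree, n), 1)
        regs <- sample.int(n, k)
        ast <- NULL
        for (r in regs) {
          lit <- list(op = "lit", idx = r)
          if (stats::runif(1) < 0.5) lit <- list(op = "not", arg = lit)
          ast <- if (is.null(ast)) lit else
            list(op = sample(c("and", "or"), 1), lhs = ast, rhs = lit)
        }
        ast
      })
      new_boolean_network(n = n, mode = "logic", rules = rules)
    } else {
      regs <- purrr::map_dfr(seq_len(n), function(i) {
        k <- sample.int(min(max_in_degree, n), 1)
        tibble(target = i, regulator = sample.int(n, k),
               sign = sample(c(1L, -1L), k, replace = TRUE))
      })
      threshold_network(regs, n = n)
    }
  })
}

#' Deterministic random disease-gene table
#'
#' Each of `d` diseases gets a random subset (3 to 8 entries, capped by the
#' universe size) of `g` genes, so overlaps arise naturally.
#'
#' @param d Number of diseases.
#' @param g Size of the gene universe.
#' @param seed Integer seed.
#' @return A `disease_gene_table`.
#' @export
random_disease_table <- function(d, g, seed) {
  if (d < 1 || g < 1) abort("need d >= 1 and g >= 1",
                            class = "sgpnet_argument_error")
  genes <- sprintf("g%03d", seq_len(g))
  withr::with_seed(seed, {
    rows <- purrr::map_dfr(seq_len(d), function(i) {
      k <- sample(seq_len(min(8, g)), 1)
      k <- max(k, min(3, g))
      tibble(disease = sprintf("disease_%02d", i),
             gene = sample(genes, k))
    })
    disease_gene_table(rows$disease, rows$gene)
  })
}

#' Deterministic random pathway catalog
#'
#' Draws `p` pathways, each a random subset of a shared identifier
#' universe with random protein/gene/signal species classes and sparse
#' random typed interactions among members of compatible classes.
#'
#' @param p Number of pathways.
#' @param universe Character vector of candidate member ids (or an integer
#'   size, expanded to `m001...`).
#' @param seed Integer seed.
#' @return List of `pathway_definition`s with distinct names.
#' @export
random_pathways <- function(p, universe, seed) {
  if (p < 1) abort("need p >= 1", class = "sgpnet_argument_error")
  if (is.numeric(universe)) universe <- sprintf("m%03d", seq_len(universe))
  if (length(universe) < 2) abort("universe must hold at least 2 ids",
                                  class = "sgpnet_argument_error")
  withr::with_seed(seed, {
    lapply(seq_len(p), function(i) {
      k <- sample(2:min(10, length(universe)), 1)
      ids <- sort(sample(universe, k))
      sp <- sample(species_classes(), k, replace = TRUE)
      members <- tibble(id = ids, species = sp)
      # sparse random signed edges with class derived from endpoint species
      n_edges <- sample(0:min(6, k * (k - 1)), 1)
      inter <- NULL
      if (n_edges > 0) {
        pairs <- expand.grid(from = ids, to = ids, stringsAsFactors = FALSE)
        pairs <- pairs[pairs$from != pairs$to, ]
        pick <- pairs[sample.int(nrow(pairs), n_edges), ]
        spec_of <- stats::setNames(sp, ids)
        cls <- mapply(function(f, t) {
          pair <- sort(c(spec_of[[f]], spec_of[[t]]))
          # gene < protein < signal alphabetically; map to class token
          key <- paste(pair, collapse = "/")
          switch(key,
            "signal/signal" = "sig_sig",
            "protein/signal" = "sig_prot",
            "gene/signal" = "sig_gene",
            "protein/protein" = "prot_prot",
            "gene/protein" = "prot_gene",
            "gene/gene" = "gene_gene"
          )
        }, pick$from, pick$to)
        inter <- tibble(
          class = unname(cls), from = pick$from, to = pick$to,
          sign = sample(c("activation", "inhibition"), n_edges, replace = TRUE)
        ) %>% distinct(.data$from, .data$to, .keep_all = TRUE)
      }
      pathway_definition(sprintf("pathway_%02d", i), members, inter)
    })
  })
}
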