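# SBML export of typed signal-gene-protein pathways with first-order rates.
#
# Mapping: one species per pathway member (compartment from its cellular
# location); one reaction per signed interaction. An activation edge X -> Y
# becomes a synthesis reaction producing Y with X as modifier and mass-action
# rate k*[X]; an inhibition edge X -> Y becomes a degradation reaction
# consuming Y with X as modifier and rate k*[X]*[Y]. Rate constants are local
# parameters initialised to a common default and annotated as placeholders
# until real kinetics are supplied.

SBML_NS <- "http://www.sbml.org/sbml/level2/version4"

sanitize_sid <- function(x) {
  out <- gsub("[^A-Za-z0-9_]", "_", x)
  ifelse(grepl("^[A-Za-z_]", out), out, paste0("s_", out))
}

#' Build an SBML Level 2 Version 4 document from a typed pathway
#'
#' Converts a [pathway_definition()] into simulation-ready SBML assuming
#' first-order mass-action rates. Output is deterministic: identical input
#' yields byte-identical XML (species in member order, reactions in the
#' pathway's canonical interaction order, stable generated ids).
#'
#' @param pathway A `pathway_definition` with at least one member.
#' @param k_default Default rate constant for every reaction's local
#'   parameter `k` (must be positive).
#' @param compartments Named character vector mapping member `location`
#'   values to compartment ids. Members with no (or unmapped) location fall
#'   into `default_compartment`; set `default_compartment = NULL` to make
#'   unmapped locations an error.
#' @param default_compartment Compartment id used when a location is
#'   unmapped.
#' @param initial_amount Initial amount given to every species, or a named
#'   vector keyed by member id for per-member overrides.
#' @param activation_law,inhibition_law Rate-law templates as MathML infix
#'   strings with placeholders `k`, `X` (modifier) and `Y` (target);
#'   defaults `"k * X"` and `"k * X * Y"`.
#' @return Single string: the serialized SBML document.
#' @examples
#' pw <- pathway_definition(
#'   "toy",
#'   members = data.frame(id = c("A", "B"), species = c("protein", "protein")),
#'   interactions = data.frame(class = "prot_prot", from = "A", to = "B",
#'                             sign = "activation")
#' )
#' doc <- build_sbml(pw)
#' sbml_summary(doc)
#' @export
build_sbml <- function(pathway, k_default = 1.0, compartments = character(),
                       default_compartment = "cell", initial_amount = 1.0,
                       activation_law = "k * X", inhibition_law = "k * X * Y") {
  stopifnot(inherits(pathway, "pathway_definition"))
  if (nrow(pathway$members) == 0) {
    abort("cannot export an empty pathway", class = "sgpnet_input_error")
  }
  if (!is.numeric(k_default) || k_default <= 0) {
    abort("k_default must be a positive rate constant",
          class = "sgpnet_argument_error")
  }

  members <- pathway$members
  comp_of <- vapply(seq_len(nrow(members)), function(i) {
    loc <- members$location[i]
    if (!is.na(loc) && loc %in% names(compartments)) return(compartments[[loc]])
    if (!is.null(default_compartment)) return(default_compartment)
    abort(sprintf("member '%s' has unmapped location '%s' and no default compartment",
                  members$id[i], loc %||% "<none>"),
          class = "sgpnet_config_error")
  }, character(1))
  comp_ids <- sort(unique(comp_of))

  sid <- stats::setNames(sanitize_sid(members$id), members$id)
  if (anyDuplicated(sid)) {
    abort("member ids collide after SBML id sanitization",
          class = "sgpnet_input_error")
  }
  amount_of <- function(id) {
    if (length(initial_amount) > 1 || !is.null(names(initial_amount))) {
      if (id %in% names(initial_amount)) return(initial_amount[[id]])
      return(1.0)
    }
    initial_amount
  }

  doc <- xml2::xml_new_root("sbml", xmlns = SBML_NS,
                            level = "2", version = "4")
  model <- xml2::xml_add_child(doc, "model",
                               id = paste0("pathway_", sanitize_sid(pathway$name)),
                               name = pathway$name)

  lc <- xml2::xml_add_child(model, "listOfCompartments")
  for (cid in comp_ids) {
    xml2::xml_add_child(lc, "compartment", id = cid, size = "1")
  }

  ls <- xml2::xml_add_child(model, "listOfSpecies")
  for (i in seq_len(nrow(members))) {
    xml2::xml_add_child(
      ls, "species",
      id = sid[[members$id[i]]], name = members$id[i],
      compartment = comp_of[i],
      initialAmount = format_num(amount_of(members$id[i]))
    )
  }

  inter <- pathway$interactions
  lr <- xml2::xml_add_child(model, "listOfReactions")
  for (i in seq_len(nrow(inter))) {
    from <- sid[[inter$from[i]]]
    to <- sid[[inter$to[i]]]
    act <- inter$sign[i] == "activation"
    rxn <- xml2::xml_add_child(
      lr, "reaction",
      id = sprintf("r%03d_%s", i, if (act) "act" else "inh"),
      name = sprintf("%s %s %s", inter$from[i],
                     if (act) "activates" else "inhibits", inter$to[i]),
      reversible = "false"
    )
    if (act) {
      prods <- xml2::xml_add_child(rxn, "listOfProducts")
      xml2::xml_add_child(prods, "speciesReference", species = to,
                          stoichiometry = "1")
    } else {
      reacts <- xml2::xml_add_child(rxn, "listOfReactants")
      xml2::xml_add_child(reacts, "speciesReference", species = to,
                          stoichiometry = "1")
    }
    mods <- xml2::xml_add_child(rxn, "listOfModifiers")
    xml2::xml_add_child(mods, "modifierSpeciesReference", species = from)

    kl <- xml2::xml_add_child(rxn, "kineticLaw")
    law <- if (act) activation_law else inhibition_law
    add_mathml_product(kl, law, k = "k", X = from, Y = to)
    lp <- xml2::xml_add_child(kl, "listOfParameters")
    par <- xml2::xml_add_child(lp, "parameter", id = "k",
                               value = format_num(k_default))
    # placeholder flag until measured kinetics replace the default
    ann <- xml2::xml_add_child(par, "annotation")
    xml2::xml_add_child(ann, "unparameterized",
                        xmlns = "https://sgpnet.invalid/sbml-annotations",
                        default = format_num(k_default))
  }

  as.character(doc)
}

format_num <- function(x) format(x, trim = TRUE, scientific = FALSE, digits = 15)

# law template is a '*'-product of tokens among {k, X, Y}; emitted as MathML
add_mathml_product <- function(kinetic_law_node, law, k, X, Y) {
  toks <- trimws(strsplit(law, "*", fixed = TRUE)[[1]])
  bad <- !toks %in% c("k", "X", "Y")
  if (length(toks) == 0 || any(bad)) {
    abort("rate-law template must be a '*'-product of k, X, Y",
          class = "sgpnet_config_error")
  }
  ids <- vapply(toks, function(t) switch(t, k = k, X = X, Y = Y), character(1))
  math <- xml2::xml_add_child(kinetic_law_node, "math",
                              xmlns = "http://www.w3.org/1998/Math/MathML")
  if (length(ids) == 1) {
    xml2::xml_add_child(math, "ci", ids[1])
  } else {
    ap <- xml2::xml_add_child(math, "apply")
    xml2::xml_add_child(ap, "times")
    for (id in ids) xml2::xml_add_child(ap, "ci", id)
  }
}

#' Summarise and structurally validate an SBML document
#'
#' `sbml_summary()` re-parses the XML and counts model elements;
#' `validate_sbml()` checks the structural contract: ids unique, every
#' species assigned to a declared compartment, every species referenced by
#' a reaction (as reactant, product or modifier) declared, and every `ci`
#' symbol in a kinetic law resolvable to a species or a local parameter of
#' that reaction.
#'
#' @param doc SBML document string (or path to an `.xml` file).
#' @return `sbml_summary()`: one-row tibble with `level`, `version`,
#'   `n_compartments`, `n_species`, `n_reactions`, `n_modifiers`.
#'   `validate_sbml()`: `TRUE` invisibly, or an error describing the first
#'   violation.
#' @export
sbml_summary <- function(doc) {
  x <- read_sbml_doc(doc)
  ns <- c(s = SBML_NS)
  tibble(
    level = xml2::xml_attr(xml2::xml_root(x), "level"),
    version = xml2::xml_attr(xml2::xml_root(x), "version"),
    n_compartments = length(xml2::xml_find_all(x, "//s:compartment", ns)),
    n_species = length(xml2::xml_find_all(x, "//s:species", ns)),
    n_reactions = length(xml2::xml_find_all(x, "//s:reaction", ns)),
    n_modifiers = length(xml2::xml_find_all(x, "//s:modifierSpeciesReference", ns))
  )
}

read_sbml_doc <- function(doc) {
  if (length(doc) == 1 && !grepl("<", doc, fixed = TRUE) && file.exists(doc)) {
    xml2::read_xml(doc)
  } else {
    xml2::read_xml(paste(doc, collapse = "\n"))
  }
}

#' @rdname sbml_summary
#' @export
validate_sbml <- function(doc) {
  x <- read_sbml_doc(doc)
  ns <- c(s = SBML_NS, m = "http://www.w3.org/1998/Math/MathML")

  comp_ids <- xml2::xml_attr(xml2::xml_find_all(x, "//s:compartment", ns), "id")
  sp_nodes <- xml2::xml_find_all(x, "//s:species", ns)
  sp_ids <- xml2::xml_attr(sp_nodes, "id")
  rxn_nodes <- xml2::xml_find_all(x, "//s:reaction", ns)
  rxn_ids <- xml2::xml_attr(rxn_nodes, "id")

  all_ids <- c(comp_ids, sp_ids, rxn_ids)
  if (anyDuplicated(all_ids)) {
    abort(sprintf("duplicate SBML id: %s",
                  paste(unique(all_ids[duplicated(all_ids)]), collapse = ", ")),
          class = "sgpnet_sbml_error")
  }
  sp_comp <- xml2::xml_attr(sp_nodes, "compartment")
  if (any(!sp_comp %in% comp_ids)) {
    abort("species assigned to undeclared compartment",
          class = "sgpnet_sbml_error")
  }
  for (rxn in rxn_nodes) {
    refs <- xml2::xml_attr(
      xml2::xml_find_all(rxn, ".//s:speciesReference | .//s:modifierSpeciesReference", ns),
      "species")
    if (any(!refs %in% sp_ids)) {
      abort(sprintf("reaction %s references undeclared species",
                    xml2::xml_attr(rxn, "id")),
            class = "sgpnet_sbml_error")
    }
    local_pars <- xml2::xml_attr(
      xml2::xml_find_all(rxn, ".//s:kineticLaw//s:parameter", ns), "id")
    cis <- xml2::xml_text(xml2::xml_find_all(rxn, ".//m:ci", ns))
    known <- c(sp_ids, local_pars)
    if (any(!trimws(cis) %in% known)) {
      abort(sprintf("kinetic law of %s references unknown symbol",
                    xml2::xml_attr(rxn, "id")),
            class = "sgpnet_sbml_error")
    }
    # every species appearing in the law that is not a parameter must be a
    # declared modifier, reactant or product of this reaction
    law_species <- intersect(trimws(cis), sp_ids)
    if (any(!law_species %in% refs)) {
      abort(sprintf("kinetic law of %s uses species not declared in the reaction",
                    xml2::xml_attr(rxn, "id")),
            class = "sgpnet_sbml_error")
    }
  }
  invisible(TRUE)
}

#' Write an SBML document string to a file
#'
#' @param doc SBML string from [build_sbml()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_sbml <- function(doc, path) {
  writeLines(doc, path, useBytes = TRUE)
  invisible(path)
}
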