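# Synchronous Boolean network engine.
#
# Networks come in two update semantics:
#   * logic mode  - per-node Boolean expressions over $node[j] literals with
#     NOT (!), AND (&), OR (|), parsed from the rule-file syntax
#     `$node[i] = <expr>;`;
#   * threshold mode - per-node signed regulator lists; node i switches on
#     iff the signed sum of its regulators' current states reaches 1:
#     S_i(t+1) = 1  <=>  sum_j a_ij S_j(t) >= 1, with a_ij = +1 for
#     activation and -1 for inhibition.
# All nodes update simultaneously, so the successor of a global state is
# unique and the dynamics over the 2^N states is a deterministic map whose
# cycles are the attractors (fixed points = singleton attractors).

# ---- state <-> string <-> code ----------------------------------------------
# Convention: node 1 is the leftmost character of the state string, and the
# integer code treats bit 1 as the most significant bit, so numeric order of
# codes equals lexicographic order of state strings.

#' Convert between state strings, bit vectors and state codes
#'
#' States of an `N`-node network are rendered as binary strings with node 1
#' leftmost (e.g. `"0100010100"`), stored as 0/1 integer vectors, and
#' indexed by an integer code in `0 .. 2^N - 1` whose most significant bit
#' is node 1 (so code order is string lexicographic order).
#'
#' @param s State string such as `"0100010100"`.
#' @param bits Integer vector of 0/1 values.
#' @param code Integer state code.
#' @param n Number of nodes.
#' @return `state_to_bits()` an integer vector; `bits_to_state()` a string;
#'   `code_to_state()` a string; `state_to_code()` a numeric code.
#' @export
state_to_bits <- function(s) {
  if (!grepl("^[01]+$", s)) abort("state string must be over {0,1}",
                                  class = "sgpnet_argument_error")
  as.integer(strsplit(s, "")[[1]])
}

#' @rdname state_to_bits
#' @export
bits_to_state <- function(bits) paste(as.integer(bits), collapse = "")

#' @rdname state_to_bits
#' @export
state_to_code <- function(s) {
  bits <- state_to_bits(s)
  sum(bits * 2^(rev(seq_along(bits)) - 1))
}

#' @rdname state_to_bits
#' @export
code_to_state <- function(code, n) {
  bits_to_state(floor(code / 2^((n - 1):0)) %% 2)
}

# all 2^n states as a 2^n x n 0/1 matrix, row order = code order
all_states_matrix <- function(n) {
  codes <- 0:(2^n - 1)
  vapply(seq_len(n), function(i) floor(codes / 2^(n - i)) %% 2,
         numeric(2^n))
}

# ---- rule parsing -----------------------------------------------------------

token_pattern <- "\\$node\\[[0-9]+\\]|[=;!&|()]|\\s+|."

tokenize_rules <- function(text) {
  lines <- unlist(strsplit(text, "\n", fixed = TRUE))
  toks <- list()
  for (ln in seq_along(lines)) {
    line <- lines[ln]
    if (grepl("^\\s*#", line)) next
    pos <- 1L
    for (m in regmatches(line, gregexpr(token_pattern, line))[[1]]) {
      col <- pos
      pos <- pos + nchar(m)
      if (grepl("^\\s+$", m)) next
      type <- if (startsWith(m, "$node[")) "lit"
      else if (m %in% c("=", ";", "!", "&", "|", "(", ")")) m
      else "bad"
      if (type == "bad") {
        abort(sprintf("rule syntax error: unexpected '%s' at line %d, column %d",
                      m, ln, col),
              class = "sgpnet_parse_error")
      }
      toks[[length(toks) + 1L]] <- list(type = type, text = m,
                                        line = ln, col = col)
    }
  }
  toks
}

#' Parse a Boolean rule file into a logic-mode network
#'
#' The rule syntax defines one statement per node, `$node[i] = <expr>;`,
#' where `<expr>` combines `$node[j]` literals with `!` (NOT), `&` (AND),
#' `|` (OR) and parentheses; precedence is NOT > AND > OR. Every node
#' `1..N` must be defined exactly once, where `N` is the largest node index
#' mentioned. The network's edge count is the total number of literal
#' occurrences across rule right-hand sides (a regulator used twice in one
#' rule counts twice).
#'
#' @param text Rule text: a single string or a character vector of lines.
#' @param labels Optional character vector of node labels (length `N`).
#' @return A `boolean_network` in logic mode.
#' @examples
#' net <- parse_rules("$node[1]=!$node[3]; $node[2]=!$node[1]; $node[3]=!$node[2];")
#' glance(net)
#' @export
parse_rules <- function(text, labels = NULL) {
  text <- paste(text, collapse = "\n")
  toks <- tokenize_rules(text)
  if (length(toks) == 0) abort("empty rule text", class = "sgpnet_parse_error")

  i <- 1L
  peek <- function() if (i <= length(toks)) toks[[i]] else NULL
  advance <- function() { t <- toks[[i]]; i <<- i + 1L; t }
  expect <- function(type) {
    t <- peek()
    if (is.null(t) || t$type != type) {
      where <- if (is.null(t)) "end of input" else
        sprintf("'%s' at line %d, column %d", t$text, t$line, t$col)
      abort(sprintf("rule syntax error: expected '%s', found %s", type, where),
            class = "sgpnet_parse_error")
    }
    advance()
  }
  lit_index <- function(t) as.integer(sub("\\$node\\[([0-9]+)\\]", "\\1", t$text))

  parse_primary <- function() {
    t <- peek()
    if (is.null(t)) abort("rule syntax error: unexpected end of input",
                          class = "sgpnet_parse_error")
    if (t$type == "lit") {
      advance()
      return(list(op = "lit", idx = lit_index(t)))
    }
    if (t$type == "(") {
      advance()
      e <- parse_or()
      expect(")")
      return(e)
    }
    abort(sprintf("rule syntax error: unexpected '%s' at line %d, column %d",
                  t$text, t$line, t$col),
          class = "sgpnet_parse_error")
  }
  parse_unary <- function() {
    t <- peek()
    if (!is.null(t) && t$type == "!") {
      advance()
      return(list(op = "not", arg = parse_unary()))
    }
    parse_primary()
  }
  parse_and <- function() {
    e <- parse_unary()
    while (!is.null(peek()) && peek()$type == "&") {
      advance()
      e <- list(op = "and", lhs = e, rhs = parse_unary())
    }
    e
  }
  parse_or <- function() {
    e <- parse_and()
    while (!is.null(peek()) && peek()$type == "|") {
      advance()
      e <- list(op = "or", lhs = e, rhs = parse_and())
    }
    e
  }

  defs <- list()
  while (!is.null(peek())) {
    lhs <- expect("lit")
    target <- lit_index(lhs)
    expect("=")
    expr <- parse_or()
    expect(";")
    if (!is.null(defs[[as.character(target)]])) {
      abort(sprintf("node %d defined more than once (line %d)",
                    target, lhs$line),
            class = "sgpnet_structural_error")
    }
    defs[[as.character(target)]] <- expr
  }

  n <- max(c(
    as.integer(names(defs)),
    vapply(defs, max_literal_index, integer(1))
  ))
  missing <- setdiff(seq_len(n), as.integer(names(defs)))
  if (length(missing) > 0) {
    abort(sprintf("missing rule definition for node(s): %s",
                  paste(missing, collapse = ", ")),
          class = "sgpnet_structural_error")
  }
  rules <- lapply(as.character(seq_len(n)), function(k) defs[[k]])
  new_boolean_network(n = n, mode = "logic", rules = rules, labels = labels)
}

max_literal_index <- function(ast) {
  switch(ast$op,
    lit = ast$idx,
    not = max_literal_index(ast$arg),
    max(max_literal_index(ast$lhs), max_literal_index(ast$rhs))
  )
}

count_literals <- function(ast) {
  switch(ast$op,
    lit = 1L,
    not = count_literals(ast$arg),
    count_literals(ast$lhs) + count_literals(ast$rhs)
  )
}

literal_indices <- function(ast) {
  switch(ast$op,
    lit = ast$idx,
    not = literal_indices(ast$arg),
    c(literal_indices(ast$lhs), literal_indices(ast$rhs))
  )
}

# evaluate an AST over a 0/1 state matrix (rows = states, cols = nodes);
# returns a 0/1 vector with one entry per row
eval_ast <- function(ast, m) {
  switch(ast$op,
    lit = m[, ast$idx],
    not = 1 - eval_ast(ast$arg, m),
    and = eval_ast(ast$lhs, m) * eval_ast(ast$rhs, m),
    or = pmax(eval_ast(ast$lhs, m), eval_ast(ast$rhs, m))
  )
}

# render an AST back to rule syntax (used by write/print paths)
deparse_ast <- function(ast) {
  switch(ast$op,
    lit = sprintf("$node[%d]", ast$idx),
    not = paste0("!(", deparse_ast(ast$arg), ")"),
    and = paste0("(", deparse_ast(ast$lhs), " & ", deparse_ast(ast$rhs), ")"),
    or = paste0("(", deparse_ast(ast$lhs), " | ", deparse_ast(ast$rhs), ")")
  )
}

# ---- network container ------------------------------------------------------

new_boolean_network <- function(n, mode, rules = NULL, regulators = NULL,
                                labels = NULL, self_degrading = integer(),
                                clamps = integer()) {
  if (n < 1) abort("network needs at least one node",
                   class = "sgpnet_argument_error")
  if (is.null(labels)) labels <- paste0("node", seq_len(n))
  if (length(labels) != n) abort("labels must have one entry per node",
                                 class = "sgpnet_argument_error")
  if (mode == "logic") {
    over <- unlist(lapply(rules, literal_indices))
    if (any(over < 1 | over > n)) {
      abort(sprintf("literal index out of range 1..%d", n),
            class = "sgpnet_structural_error")
    }
  } else {
    if (nrow(regulators) > 0 &&
        any(c(regulators$target, regulators$regulator) < 1 |
            c(regulators$target, regulators$regulator) > n)) {
      abort(sprintf("regulator index out of range 1..%d", n),
            class = "sgpnet_structural_error")
    }
  }
  overlap <- intersect(as.integer(names(clamps) %||% character()),
                       self_degrading)
  structure(
    list(n = as.integer(n), labels = as.character(labels), mode = mode,
         rules = rules, regulators = regulators,
         self_degrading = sort(unique(as.integer(self_degrading))),
         clamps = clamps),
    class = "boolean_network"
  )
}

#' Construct a threshold-mode Boolean network from a signed regulator list
#'
#' Each regulator entry contributes `+1` (activation) or `-1` (inhibition)
#' of the regulator's current state to the target's input sum; the target
#' switches on when the sum reaches 1. Nodes with no regulators hold their
#' state, unless listed as self-degrading (non-regulated), in which case
#' they decay to 0.
#'
#' @param regulators Data frame with columns `target`, `regulator`
#'   (integer node indices) and `sign` (`+1`/`-1`, or
#'   `"activation"`/`"inhibition"`).
#' @param n Number of nodes (default: largest index mentioned).
#' @param labels Optional node labels.
#' @param self_degrading Integer indices of self-degrading nodes.
#' @return A `boolean_network` in threshold mode.
#' @export
threshold_network <- function(regulators, n = NULL, labels = NULL,
                              self_degrading = integer()) {
  regulators <- as_tibble(regulators)
  need <- c("target", "regulator", "sign")
  if (!all(need %in% names(regulators))) {
    abort("regulators need columns target, regulator, sign",
          class = "sgpnet_config_error")
  }
  sign_chr <- as.character(regulators$sign)
  sign_num <- ifelse(sign_chr %in% c("activation", "+1", "1"), 1L,
                     ifelse(sign_chr %in% c("inhibition", "-1"), -1L, NA_integer_))
  if (nrow(regulators) > 0 && anyNA(sign_num)) {
    abort("sign must be +1/-1 or activation/inhibition",
          class = "sgpnet_input_error")
  }
  regulators <- tibble(
    target = as.integer(regulators$target),
    regulator = as.integer(regulators$regulator),
    sign = sign_num
  ) %>% arrange(.data$target, .data$regulator, .data$sign)
  if (is.null(n)) {
    n <- max(c(regulators$target, regulators$regulator, self_degrading, 1L))
  }
  net <- new_boolean_network(n = n, mode = "threshold",
                             regulators = regulators, labels = labels,
                             self_degrading = self_degrading)
  check_clamp_selfdeg(net)
  net
}

check_clamp_selfdeg <- function(net) {
  both <- intersect(as.integer(names(net$clamps)), net$self_degrading)
  if (length(both) > 0) {
    abort(sprintf("node(s) %s cannot be both clamped and self-degrading",
                  paste(both, collapse = ", ")),
          class = "sgpnet_argument_error")
  }
  invisible(net)
}

#' Read a threshold network from a TSV of (target, regulator, sign)
#'
#' @param path Tab-separated file with header columns `target`, `regulator`,
#'   `sign`; `#` lines are comments.
#' @param self_degrading Integer indices of self-degrading nodes.
#' @param labels Optional node labels.
#' @return A threshold-mode `boolean_network`.
#' @export
read_threshold_network <- function(path, self_degrading = integer(),
                                   labels = NULL) {
  raw <- readr::read_tsv(path, comment = "#",
                         col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE, show_col_types = FALSE)
  threshold_network(raw, labels = labels, self_degrading = self_degrading)
}

#' @export
print.boolean_network <- function(x, ...) {
  cat(sprintf("<boolean_network> %d nodes (%s mode), %d edges\n",
              x$n, x$mode, count_edges(x)))
  if (length(x$clamps) > 0) {
    cat(sprintf("  clamped: %s\n",
                paste(sprintf("%s=%d", x$labels[as.integer(names(x$clamps))],
                              x$clamps), collapse = ", ")))
  }
  if (length(x$self_degrading) > 0) {
    cat(sprintf("  self-degrading: %s\n",
                paste(x$labels[x$self_degrading], collapse = ", ")))
  }
  invisible(x)
}

#' Edge count of a Boolean network
#'
#' In logic mode, the total number of `$node[j]` literal occurrences across
#' rule right-hand sides; in threshold mode, the number of signed regulator
#' entries. Clamping does not change the count: it describes the parsed
#' rule set, not the perturbation.
#'
#' @param net A `boolean_network`.
#' @return Integer edge count.
#' @export
count_edges <- function(net) {
  stopifnot(inherits(net, "boolean_network"))
  if (net$mode == "logic") {
    sum(vapply(net$rules, count_literals, integer(1)))
  } else {
    nrow(net$regulators)
  }
}

#' Per-node regulator summary of a Boolean network
#'
#' @param x A `boolean_network`.
#' @param ... Unused.
#' @return Tibble with one row per node: `node`, `label`, `n_literals`
#'   (entries in its rule), `regulators` (list-column of distinct regulator
#'   indices), `clamped`, `self_degrading`.
#' @export
tidy.boolean_network <- function(x, ...) {
  regs <- if (x$mode == "logic") {
    lapply(x$rules, function(r) sort(unique(literal_indices(r))))
  } else {
    lapply(seq_len(x$n), function(i) {
      sort(unique(x$regulators$regulator[x$regulators$target == i]))
    })
  }
  lits <- if (x$mode == "logic") {
    vapply(x$rules, count_literals, integer(1))
  } else {
    vapply(seq_len(x$n), function(i) sum(x$regulators$target == i), integer(1))
  }
  tibble(
    node = seq_len(x$n),
    label = x$labels,
    n_literals = lits,
    regulators = regs,
    clamped = seq_len(x$n) %in% as.integer(names(x$clamps)),
    self_degrading = seq_len(x$n) %in% x$self_degrading
  )
}

#' @rdname count_edges
#' @param x A `boolean_network`.
#' @param ... Unused.
#' @return For `glance()`: one-row tibble with `n_nodes`, `n_edges`,
#'   `mode`, `n_clamped`, `n_self_degrading`.
#' @export
glance.boolean_network <- function(x, ...) {
  tibble(
    n_nodes = x$n, n_edges = count_edges(x), mode = x$mode,
    n_clamped = length(x$clamps),
    n_self_degrading = length(x$self_degrading)
  )
}

# ---- synchronous stepping ---------------------------------------------------

as_state_matrix <- function(s, n) {
  if (is.character(s)) s <- t(vapply(s, state_to_bits, integer(n)))
  if (is.vector(s)) s <- matrix(s, nrow = 1)
  if (ncol(s) != n) abort(sprintf("state must have %d bits", n),
                          class = "sgpnet_argument_error")
  s
}

apply_clamps <- function(nxt, clamps) {
  for (nm in names(clamps)) nxt[, as.integer(nm)] <- clamps[[nm]]
  nxt
}

# matrix-in, matrix-out synchronous update (both modes)
step_matrix <- function(net, m, mode = net$mode) {
  if (mode == "logic") {
    if (is.null(net$rules)) abort("network has no logic rules",
                                  class = "sgpnet_mode_error")
    nxt <- vapply(net$rules, eval_ast, numeric(nrow(m)), m = m)
    if (nrow(m) == 1) nxt <- matrix(nxt, nrow = 1)
  } else {
    if (is.null(net$regulators)) abort("network has no threshold regulators",
                                       class = "sgpnet_mode_error")
    nxt <- matrix(0, nrow(m), net$n)
    for (i in seq_len(net$n)) {
      rows <- net$regulators[net$regulators$target == i, ]
      if (nrow(rows) == 0) {
        # no regulators: hold, or decay to 0 when self-degrading
        nxt[, i] <- if (i %in% net$self_degrading) 0 else m[, i]
      } else {
        sums <- as.numeric(m[, rows$regulator, drop = FALSE] %*% rows$sign)
        nxt[, i] <- as.numeric(sums >= 1)
      }
    }
  }
  apply_clamps(nxt, net$clamps)
}

#' Advance a network state one synchronous step
#'
#' All nodes are updated simultaneously from the current state. In logic
#' mode each node's next bit is its rule evaluated on the current state; in
#' threshold mode it is 1 iff the signed regulator sum reaches 1.
#' Clamped nodes keep their clamp value regardless of the rules.
#'
#' @param net A `boolean_network` in the matching mode.
#' @param s State string or 0/1 vector.
#' @return The successor state, in the same form as the input (string in,
#'   string out).
#' @examples
#' net <- cellcycle_network()
#' step_logic(net, "0100010100")   # G0 is a fixed point
#' @export
step_logic <- function(net, s) {
  stopifnot(inherits(net, "boolean_network"))
  if (net$mode != "logic") abort("step_logic requires a logic-mode network",
                                 class = "sgpnet_mode_error")
  step_either(net, s, "logic")
}

#' @rdname step_logic
#' @export
step_threshold <- function(net, s) {
  stopifnot(inherits(net, "boolean_network"))
  if (net$mode != "threshold") {
    abort("step_threshold requires a threshold-mode network",
          class = "sgpnet_mode_error")
  }
  step_either(net, s, "threshold")
}

step_either <- function(net, s, mode) {
  as_string <- is.character(s)
  m <- as_state_matrix(s, net$n)
  nxt <- step_matrix(net, m, mode)
  if (as_string) bits_to_state(nxt[1, ]) else as.integer(nxt[1, ])
}

# ---- state-space enumeration ------------------------------------------------

#' Enumerate the full synchronous state space
#'
#' Computes the successor of every one of the `2^N` states, giving the
#' network's complete state transition map. Enumeration is exhaustive, so
#' `N` is guarded by a cap (default 20, about a million states); raise
#' `cap` explicitly for larger networks.
#'
#' @param net A `boolean_network`.
#' @param mode Update semantics; defaults to the network's own mode.
#' @param cap Largest `N` permitted.
#' @return A `state_transition_map`: list with `n` and `successor`, an
#'   integer vector of length `2^N` where entry `i` is the state code of
#'   the successor of code `i - 1`.
#' @export
enumerate_state_space <- function(net, mode = net$mode, cap = 20L) {
  stopifnot(inherits(net, "boolean_network"))
  if (net$n > cap) {
    abort(sprintf("N = %d exceeds the enumeration cap %d (2^N states); raise cap to override",
                  net$n, cap),
          class = "sgpnet_resource_error")
  }
  m <- all_states_matrix(net$n)
  nxt <- step_matrix(net, m, mode)
  weights <- 2^((net$n - 1):0)
  succ <- as.numeric(nxt %*% weights)
  structure(list(n = net$n, successor = succ),
            class = "state_transition_map")
}

#' @export
print.state_transition_map <- function(x, ...) {
  cat(sprintf("<state_transition_map> %d nodes, %d states\n",
              x$n, length(x$successor)))
  invisible(x)
}

#' Tidy a state transition map into a state/successor table
#'
#' @param x A `state_transition_map`.
#' @param ... Unused.
#' @return Tibble with columns `state`, `successor` (strings, lexicographic
#'   order).
#' @export
tidy.state_transition_map <- function(x, ...) {
  codes <- seq_along(x$successor) - 1
  tibble(
    state = vapply(codes, code_to_state, character(1), n = x$n),
    successor = vapply(x$successor, code_to_state, character(1), n = x$n)
  )
}

# ---- attractor detection ----------------------------------------------------

#' Find all attractors and basins of a state transition map
#'
#' Every state of a finite deterministic map eventually enters a cycle; the
#' cycles are the attractors (length-1 cycles are fixed points, i.e.
#' singleton attractors) and the set of states draining into a cycle is its
#' basin. Basins partition the state space, so basin sizes always sum to
#' `2^N`. Cycles are reported in canonical form: the state sequence rotated
#' to start at its lexicographically smallest state string.
#'
#' @param map A `state_transition_map` from [enumerate_state_space()].
#' @return An `attractor_set`: list with `n` and `attractors`, a tibble
#'   with columns `id`, `kind` (`singleton`/`cyclic`), `length`,
#'   `basin_size` and `states` (list-column of state-string cycles).
#' @examples
#' net <- cellcycle_network()
#' atts <- find_attractors(enumerate_state_space(net))
#' tidy(atts)[, c("kind", "length", "basin_size")]
#' @export
find_attractors <- function(map) {
  stopifnot(inherits(map, "state_transition_map"))
  S <- length(map$successor)
  succ <- map$successor + 1     # 1-based
  attr_of <- integer(S)         # 0 = unresolved; else attractor id
  on_path <- integer(S)         # position in the path being followed, else 0
  cycles <- list()
  path <- integer(S)

  for (s0 in seq_len(S)) {
    if (attr_of[s0] > 0) next
    len <- 0L
    cur <- s0
    while (attr_of[cur] == 0 && on_path[cur] == 0) {
      len <- len + 1L
      path[len] <- cur
      on_path[cur] <- len
      cur <- succ[cur]
    }
    if (attr_of[cur] > 0) {
      aid <- attr_of[cur]
    } else {
      cyc <- path[on_path[cur]:len]
      cycles[[length(cycles) + 1L]] <- cyc
      aid <- length(cycles)
    }
    walked <- path[seq_len(len)]
    attr_of[walked] <- aid
    on_path[walked] <- 0L
  }

  basin <- tabulate(attr_of, nbins = length(cycles))
  rows <- purrr::map_dfr(seq_along(cycles), function(i) {
    cyc <- cycles[[i]] - 1               # back to codes
    rot <- which.min(cyc)                # canonical rotation: smallest code first
    cyc <- c(cyc[rot:length(cyc)], cyc[seq_len(rot - 1L)])
    states <- vapply(cyc, code_to_state, character(1), n = map$n)
    tibble(
      kind = if (length(cyc) == 1) "singleton" else "cyclic",
      length = length(cyc),
      basin_size = basin[i],
      states = list(states)
    )
  })
  rows <- rows %>%
    arrange(dplyr::desc(.data$basin_size),
            vapply(.data$states, `[[`, character(1), 1)) %>%
    mutate(id = row_number()) %>%
    select("id", "kind", "length", "basin_size", "states")
  structure(list(n = map$n, attractors = rows), class = "attractor_set")
}

#' @export
print.attractor_set <- function(x, ...) {
  a <- x$attractors
  cat(sprintf("<attractor_set> %d attractor(s) over %d states\n",
              nrow(a), 2^x$n))
  for (i in seq_len(nrow(a))) {
    cat(sprintf("  [%d] %s, length %d, basin %d: %s\n", a$id[i], a$kind[i],
                a$length[i], a$basin_size[i],
                paste(a$states[[i]], collapse = " -> ")))
  }
  invisible(x)
}

#' Tidy and summarise an attractor set
#'
#' @param x An `attractor_set`.
#' @param ... Unused.
#' @return `tidy()`: the attractor tibble (`id`, `kind`, `length`,
#'   `basin_size`, `states`). `glance()`: one row with `n_states`,
#'   `n_attractors`, `n_singleton`, `n_cyclic`, `largest_basin`.
#' @export
tidy.attractor_set <- function(x, ...) x$attractors

#' @rdname tidy.attractor_set
#' @export
glance.attractor_set <- function(x, ...) {
  a <- x$attractors
  tibble(
    n_states = 2^x$n,
    n_attractors = nrow(a),
    n_singleton = sum(a$kind == "singleton"),
    n_cyclic = sum(a$kind == "cyclic"),
    largest_basin = max(a$basin_size)
  )
}

#' Plot basin sizes of an attractor set
#'
#' @param object An `attractor_set`.
#' @param ... Unused.
#' @return A ggplot bar chart of basin sizes, singletons and cycles
#'   distinguished by fill.
#' @export
autoplot.attractor_set <- function(object, ...) {
  a <- object$attractors
  a$label <- vapply(a$states, `[[`, character(1), 1)
  ggplot2::ggplot(a, ggplot2::aes(
    x = stats::reorder(.data$label, -.data$basin_size),
    y = .data$basin_size, fill = .data$kind
  )) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "attractor (first state of canonical cycle)",
                  y = "basin size", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

# ---- perturbation and trajectories ------------------------------------------

#' Clamp nodes of a Boolean network (mutant analysis)
#'
#' Clamping fixes a node's state at 0 (knockout) or 1 (constitutive
#' expression) regardless of its rule — the in-silico analogue of a mutant.
#' Returns a modified copy; the input network is untouched. Re-clamping an
#' already-clamped node to a different value is an error.
#'
#' @param net A `boolean_network`.
#' @param clamps Named vector mapping nodes to 0/1; names are node indices
#'   or node labels, e.g. `c(Rb = 0)` or `c("2" = 0)`.
#' @return The clamped network.
#' @examples
#' mutant <- apply_perturbation(cellcycle_network(), c(Rb = 0))
#' glance(find_attractors(enumerate_state_space(mutant)))
#' @export
apply_perturbation <- function(net, clamps) {
  stopifnot(inherits(net, "boolean_network"))
  if (length(clamps) == 0) return(net)
  if (is.null(names(clamps))) {
    abort("clamps must be a named vector (node index or label -> 0/1)",
          class = "sgpnet_argument_error")
  }
  idx <- suppressWarnings(as.integer(names(clamps)))
  lab <- match(names(clamps), net$labels)
  idx[is.na(idx)] <- lab[is.na(idx)]
  if (anyNA(idx) || any(idx < 1 | idx > net$n)) {
    abort(sprintf("unknown clamp node(s): %s",
                  paste(names(clamps)[is.na(idx) | idx < 1 | idx > net$n],
                        collapse = ", ")),
          class = "sgpnet_argument_error")
  }
  vals <- as.integer(clamps)
  if (any(!vals %in% c(0L, 1L))) {
    abort("clamp values must be 0 or 1", class = "sgpnet_argument_error")
  }
  existing <- net$clamps
  for (k in seq_along(idx)) {
    key <- as.character(idx[k])
    if (key %in% names(existing) && existing[[key]] != vals[k]) {
      abort(sprintf("node %s already clamped to %d; cannot re-clamp to %d",
                    key, existing[[key]], vals[k]),
            class = "sgpnet_argument_error")
    }
    existing[[key]] <- vals[k]
  }
  net$clamps <- existing[order(as.integer(names(existing)))]
  check_clamp_selfdeg(net)
  net
}

#' Follow a synchronous trajectory until it enters an attractor
#'
#' Iterates the update map from a start state, recording the visited
#' states. Determinism plus a finite state space guarantee entry into a
#' cycle within `2^N` steps; `max_steps` bounds the walk for large `N`.
#'
#' @param net A `boolean_network`.
#' @param start Start state (string or 0/1 vector).
#' @param mode Update semantics; defaults to the network's mode.
#' @param max_steps Maximum number of transitions to take.
#' @return A list of class `boolean_trajectory`: `states` (character vector
#'   `s0, s1, ...`), `attractor_entry` (1-based index of the first state on
#'   the attractor, `NA` when not converged), `period` (cycle length, `NA`
#'   when not converged), `converged` (logical).
#' @export
trajectory <- function(net, start, mode = net$mode, max_steps = 1000L) {
  stopifnot(inherits(net, "boolean_network"))
  if (max_steps < 1) abort("max_steps must be >= 1",
                           class = "sgpnet_argument_error")
  s <- if (is.character(start)) start else bits_to_state(start)
  seen <- stats::setNames(1L, s)
  states <- character(max_steps + 1L)
  states[1] <- s
  len <- 1L
  converged <- FALSE
  entry <- NA_integer_
  period <- NA_integer_
  while (len <= max_steps) {
    nxt <- step_either(net, states[len], mode)
    hit <- seen[nxt]
    if (!is.na(hit)) {
      converged <- TRUE
      entry <- unname(hit)
      period <- len + 1L - entry
      break
    }
    len <- len + 1L
    states[len] <- nxt
    seen[nxt] <- len
  }
  structure(
    list(states = states[seq_len(len)], attractor_entry = entry,
         period = period, converged = converged),
    class = "boolean_trajectory"
  )
}

#' @export
print.boolean_trajectory <- function(x, ...) {
  cat(sprintf("<boolean_trajectory> %d state(s); %s\n", length(x$states),
              if (x$converged)
                sprintf("attractor entered at step %d (period %d)",
                        x$attractor_entry - 1L, x$period)
              else "not converged within max_steps"))
  cat(paste(x$states, collapse = " -> "), "\n")
  invisible(x)
}

#' @export
tidy.boolean_trajectory <- function(x, ...) {
  tibble(
    step = seq_along(x$states) - 1L,
    state = x$states,
    on_attractor = if (x$converged)
      seq_along(x$states) >= x$attractor_entry else FALSE
  )
}

# ---- transition file I/O ----------------------------------------------------

#' Write the full transition table and attractor report
#'
#' Emits one `state<TAB>successor` line per state in lexicographic order —
#' directly loadable as an edge list by Cytoscape — followed by one
#' commented block per attractor (kind, basin size, then the cycle's states
#' one per line).
#'
#' @param map A `state_transition_map`.
#' @param attractors The matching `attractor_set` (or `NULL` to omit the
#'   report).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_transitions <- function(map, attractors, path) {
  stopifnot(inherits(map, "state_transition_map"))
  tt <- tidy(map)
  lines <- paste(tt$state, tt$successor, sep = "\t")
  if (!is.null(attractors)) {
    stopifnot(inherits(attractors, "attractor_set"))
    a <- attractors$attractors
    for (i in seq_len(nrow(a))) {
      lines <- c(lines,
                 sprintf("# attractor %d kind=%s length=%d basin=%d",
                         a$id[i], a$kind[i], a$length[i], a$basin_size[i]),
                 paste0("# ", a$states[[i]]))
    }
  }
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Re-read a transition table written by [write_transitions()]
#'
#' Attractor blocks are comments and are skipped; the transition lines
#' reconstruct the map exactly.
#'
#' @param path Path of a transitions file.
#' @return A `state_transition_map`.
#' @export
read_transitions <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- stringr::str_split_fixed(lines, "\t", 2)
  n <- nchar(parts[1, 1])
  codes <- vapply(parts[, 1], state_to_code, numeric(1))
  succ <- vapply(parts[, 2], state_to_code, numeric(1))
  if (length(codes) != 2^n || !setequal(codes, 0:(2^n - 1))) {
    abort("transition file does not cover all 2^N states exactly once",
          class = "sgpnet_input_error")
  }
  structure(list(n = n, successor = unname(succ[order(codes)])),
            class = "state_transition_map")
}
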