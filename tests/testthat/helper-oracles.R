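# Independent brute-force oracles. These deliberately avoid the package's
# own algorithms: BFS by hand, orbit-following with explicit cycle
# detection, nested-loop set intersections.

# shortest-path distances from a seed by plain queue BFS over an edge table
oracle_bfs_distances <- function(edges, node_ids, seed) {
  adj <- lapply(stats::setNames(node_ids, node_ids), function(x) character())
  for (i in seq_len(nrow(edges))) {
    a <- edges$a[i]; b <- edges$b[i]
    if (a == b) next
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  dist <- stats::setNames(rep(Inf, length(node_ids)), node_ids)
  dist[seed] <- 0
  queue <- seed
  while (length(queue) > 0) {
    cur <- queue[1]; queue <- queue[-1]
    for (nb in adj[[cur]]) {
      if (is.infinite(dist[nb])) {
        dist[nb] <- dist[cur] + 1
        queue <- c(queue, nb)
      }
    }
  }
  dist
}

# attractors by following every state's orbit independently; cycles keyed by
# their canonical rotation (start at the smallest state string)
oracle_attractors <- function(net, mode = net$mode) {
  n <- net$n
  step1 <- function(s) {
    if (mode == "logic") step_logic(net, s) else step_threshold(net, s)
  }
  canonical <- function(cycle) {
    rot <- which.min(cycle)
    c(cycle[rot:length(cycle)], cycle[seq_len(rot - 1)])
  }
  cycles <- list()
  basin <- integer()
  for (code in 0:(2^n - 1)) {
    s <- code_to_state(code, n)
    seen <- character()
    cur <- s
    while (!(cur %in% seen)) {
      seen <- c(seen, cur)
      cur <- step1(cur)
    }
    # cur repeats: the cycle is the suffix of seen starting at cur
    start <- match(cur, seen)
    cyc <- canonical(seen[start:length(seen)])
    key <- paste(cyc, collapse = ",")
    if (is.null(cycles[[key]])) {
      cycles[[key]] <- cyc
      basin[key] <- 0L
    }
    basin[key] <- basin[key] + 1L
  }
  out <- lapply(names(cycles), function(k) {
    list(states = cycles[[k]], basin_size = unname(basin[k]))
  })
  out[order(vapply(out, function(a) a$states[1], character(1)))]
}

# package attractor_set reshaped to the oracle's format for comparison
attractor_set_as_oracle <- function(atts) {
  a <- tidy(atts)
  out <- lapply(seq_len(nrow(a)), function(i) {
    list(states = a$states[[i]], basin_size = a$basin_size[i])
  })
  out[order(vapply(out, function(x) x$states[1], character(1)))]
}

# nested-loop pairwise shared-gene counts over a disease-gene table
oracle_disease_weights <- function(table) {
  sets <- lapply(split(table$gene, table$disease), unique)
  ds <- sort(names(sets))
  rows <- list()
  for (i in seq_along(ds)) {
    for (j in seq_along(ds)) {
      if (i >= j) next
      w <- 0L
      for (g in sets[[ds[i]]]) if (g %in% sets[[ds[j]]]) w <- w + 1L
      if (w >= 1) rows[[length(rows) + 1]] <-
          data.frame(disease_a = ds[i], disease_b = ds[j], weight = w)
    }
  }
  if (length(rows) == 0) {
    return(data.frame(disease_a = character(), disease_b = character(),
                      weight = integer()))
  }
  do.call(rbind, rows)
}

# nested-loop shared-member counts of a query against a catalog
oracle_crosstalk <- function(query, catalog) {
  rows <- list()
  for (p in catalog) {
    if (p$name == query$name) next
    shared <- character()
    for (m in query$members$id) if (m %in% p$members$id) shared <- c(shared, m)
    if (length(shared) >= 1) {
      rows[[length(rows) + 1]] <- list(pathway = p$name,
                                       shared = sort(shared))
    }
  }
  rows
}

read_fixture <- function(name) {
  system.file("extdata", name, package = "sgpnet", mustWork = TRUE)
}
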