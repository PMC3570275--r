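# A tiny frozen example used throughout: three nodes in a cyclic
# inhibition loop. Hand enumeration of its 8 states gives two cyclic
# attractors, {000,111} (period 2) and a 6-cycle, and no fixed point.
ring3 <- function() {
  parse_rules("$node[1]=!$node[3]; $node[2]=!$node[1]; $node[3]=!$node[2];")
}

test_that("rule parser handles the grammar, precedence and errors", {
  net <- ring3()
  expect_equal(net$n, 3)
  expect_equal(count_edges(net), 3)
  td <- tidy(net)
  expect_equal(td$regulators, list(3L, 1L, 2L))

  one <- parse_rules("$node[1] = $node[1];")
  expect_equal(one$n, 1)
  expect_equal(count_edges(one), 1)
  expect_equal(step_logic(one, "1"), "1")   # identity rule

  # precedence: AND binds tighter than OR ((a & b) | c, not a & (b | c))
  prec <- parse_rules(
    "$node[1] = $node[1] & $node[2] | $node[3]; $node[2]=$node[2]; $node[3]=$node[3];"
  )
  expect_equal(step_logic(prec, "001"), "101")
  # and NOT binds tighter than AND ((!a) & b, not !(a & b))
  prec2 <- parse_rules("$node[1] = !$node[1] & $node[2]; $node[2]=$node[2];")
  expect_equal(step_logic(prec2, "00"), "00")

  expect_error(parse_rules("$node[1] = $node[1]"), "expected ';'",
               class = "sgpnet_parse_error")
  expect_error(parse_rules("$node[1] = %;"), "line 1",
               class = "sgpnet_parse_error")
  expect_error(parse_rules("$node[1]=$node[1]; $node[1]=$node[1];"),
               class = "sgpnet_structural_error")
  expect_error(parse_rules("$node[2]=$node[2];"),  # node 1 never defined
               class = "sgpnet_structural_error")
  expect_error(parse_rules("$node[1]=$node[5];"),  # literal beyond N
               class = "sgpnet_structural_error")
})

test_that("synchronous logic stepping updates all nodes at once", {
  net <- ring3()
  expect_equal(step_logic(net, "000"), "111")
  expect_equal(step_logic(net, "111"), "000")
  expect_equal(step_logic(net, "001"), "011")
  # clamping dominates the rules
  all_clamped <- apply_perturbation(net, c("1" = 1, "2" = 0, "3" = 1))
  for (s in c("000", "101", "111")) {
    expect_equal(step_logic(all_clamped, s), "101")
  }
})

test_that("threshold stepping implements the signed-sum rule", {
  act <- threshold_network(
    data.frame(target = c(1, 2), regulator = c(2, 1), sign = c(1, 1))
  )
  expect_equal(step_threshold(act, "01"), "10")
  expect_equal(step_threshold(act, "10"), "01")
  expect_equal(step_threshold(act, "11"), "11")

  inh <- threshold_network(
    data.frame(target = c(1, 2), regulator = c(2, 1), sign = c(-1, -1))
  )
  for (s in c("00", "01", "10", "11")) {
    expect_equal(step_threshold(inh, s), "00")
  }

  # zero-regulator nodes hold state unless flagged self-degrading
  iso <- threshold_network(
    data.frame(target = 1, regulator = 2, sign = 1), n = 2
  )
  expect_equal(step_threshold(iso, "01"), "11")   # node 2 holds its 1
  dec <- threshold_network(
    data.frame(target = 1, regulator = 2, sign = 1), n = 2,
    self_degrading = 2
  )
  expect_equal(step_threshold(dec, "01"), "10")   # node 2 decays

  expect_error(step_threshold(ring3(), "000"), class = "sgpnet_mode_error")
  expect_error(step_logic(act, "00"), class = "sgpnet_mode_error")
})

test_that("state space enumeration is total, deterministic and capped", {
  net <- ring3()
  map <- enumerate_state_space(net)
  expect_equal(length(map$successor), 8)
  expect_identical(map, enumerate_state_space(net))
  # per-state agreement with direct stepping
  tt <- tidy(map)
  for (i in seq_len(nrow(tt))) {
    expect_equal(step_logic(net, tt$state[i]), tt$successor[i])
  }
  expect_error(enumerate_state_space(net, cap = 2), "cap",
               class = "sgpnet_resource_error")
})

test_that("ring3 attractors match hand enumeration", {
  atts <- find_attractors(enumerate_state_space(ring3()))
  a <- tidy(atts)
  expect_equal(sort(a$length), c(2, 6))
  expect_equal(sum(a$kind == "singleton"), 0)
  two <- a$states[[which(a$length == 2)]]
  expect_equal(two, c("000", "111"))
  expect_equal(sum(a$basin_size), 8)
})

test_that("identity map gives all-singleton attractors with unit basins", {
  net <- parse_rules("$node[1]=$node[1]; $node[2]=$node[2];")
  a <- tidy(find_attractors(enumerate_state_space(net)))
  expect_equal(nrow(a), 4)
  expect_true(all(a$kind == "singleton"))
  expect_true(all(a$basin_size == 1))
})

test_that("attractor closure and fixed-point certificates hold", {
  net <- random_boolean_network(8, 3, "logic", 17)
  map <- enumerate_state_space(net)
  atts <- find_attractors(map)
  for (i in seq_len(nrow(tidy(atts)))) {
    cyc <- tidy(atts)$states[[i]]
    nxt <- vapply(cyc, function(s) step_logic(net, s), character(1))
    expect_equal(unname(nxt), c(cyc[-1], cyc[1]))   # successor stays in cycle
    if (length(cyc) == 1) expect_equal(step_logic(net, cyc), cyc)
  }
})

test_that("basins partition the state space across random networks", {
  for (seed in 1:10) {
    n <- 2 + (seed %% 9)   # N up to 10
    mode <- if (seed %% 2 == 0) "logic" else "threshold"
    net <- random_boolean_network(n, 3, mode, seed)
    atts <- find_attractors(enumerate_state_space(net))
    expect_equal(sum(tidy(atts)$basin_size), 2^n)
  }
})

test_that("attractors equal the orbit-following oracle on random nets", {
  for (seed in 1:25) {
    n <- 2 + (seed %% 3)   # N in 2..4
    net <- random_boolean_network(n, 3, "logic", seed)
    got <- attractor_set_as_oracle(find_attractors(enumerate_state_space(net)))
    expect_equal(got, oracle_attractors(net), info = paste("seed", seed))
  }
})

test_that("a positive literal chain agrees between logic and threshold modes", {
  logic <- parse_rules("$node[1]=$node[3]; $node[2]=$node[1]; $node[3]=$node[2];")
  thr <- threshold_network(
    data.frame(target = 1:3, regulator = c(3, 1, 2), sign = 1)
  )
  ml <- enumerate_state_space(logic)
  mt <- enumerate_state_space(thr)
  expect_identical(ml$successor, mt$successor)
  expect_equal(attractor_set_as_oracle(find_attractors(ml)),
               attractor_set_as_oracle(find_attractors(mt)))
})

test_that("clamping copies the network and validates values", {
  net <- ring3()
  mut <- apply_perturbation(net, c("2" = 0))
  expect_equal(length(net$clamps), 0)   # original untouched
  expect_equal(mut$clamps[["2"]], 0L)
  expect_error(apply_perturbation(mut, c("2" = 1)),
               class = "sgpnet_argument_error")
  expect_identical(apply_perturbation(mut, c("2" = 0))$clamps, mut$clamps)
  expect_error(apply_perturbation(net, c("9" = 0)),
               class = "sgpnet_argument_error")
  expect_error(apply_perturbation(net, c("1" = 2)),
               class = "sgpnet_argument_error")
  # labels resolve too
  cc <- apply_perturbation(cellcycle_network(), c(Rb = 0))
  expect_equal(names(cc$clamps), "2")
})

test_that("clamping all nodes leaves only the clamp vector as attractor", {
  net <- ring3()
  mut <- apply_perturbation(net, c("1" = 1, "2" = 0, "3" = 0))
  a <- tidy(find_attractors(enumerate_state_space(mut)))
  expect_equal(nrow(a), 1)
  expect_equal(a$states[[1]], "100")
  expect_equal(a$basin_size, 8)
})

test_that("clamping a node at its fixed-point value preserves the fixed point", {
  net <- cellcycle_network()
  g0 <- "0100010100"
  mut <- apply_perturbation(net, c(Rb = 1))   # Rb is 1 in G0
  expect_equal(step_logic(mut, g0), g0)
})

test_that("trajectories stop when a state repeats and flag the attractor", {
  net <- cellcycle_network()
  tr <- trajectory(net, "0100010100")
  expect_equal(length(tr$states), 1)
  expect_true(tr$converged)
  expect_equal(tr$attractor_entry, 1)
  expect_equal(tr$period, 1)

  act <- threshold_network(
    data.frame(target = c(1, 2), regulator = c(2, 1), sign = c(1, 1))
  )
  tr2 <- trajectory(act, "01")
  expect_equal(tr2$states, c("01", "10"))
  expect_equal(tr2$attractor_entry, 1)
  expect_equal(tr2$period, 2)

  # determinism + finiteness: max_steps >= 2^N always converges
  net3 <- random_boolean_network(4, 2, "logic", 3)
  tr3 <- trajectory(net3, "0000", max_steps = 16)
  expect_true(tr3$converged)
  # and an over-tight budget reports non-convergence instead of raising
  long <- parse_rules("$node[1]=!$node[3]; $node[2]=!$node[1]; $node[3]=!$node[2];")
  tr4 <- trajectory(long, "001", max_steps = 2)
  expect_false(tr4$converged)
  expect_true(is.na(tr4$period))
})

test_that("transition files round-trip and list every state once", {
  net <- ring3()
  map <- enumerate_state_space(net)
  atts <- find_attractors(map)
  path <- withr::local_tempfile(fileext = ".txt")
  write_transitions(map, atts, path)
  lines <- readLines(path)
  transition_lines <- lines[!startsWith(lines, "#")]
  expect_equal(length(transition_lines), 8)
  expect_false(is.unsorted(transition_lines))
  back <- read_transitions(path)
  expect_equal(back$successor, map$successor)
  expect_equal(back$n, map$n)
})

test_that("state string, bit and code renderings interconvert losslessly", {
  for (s in c("0", "1", "0100010100", "1111", "0000")) {
    expect_equal(bits_to_state(state_to_bits(s)), s)
    expect_equal(code_to_state(state_to_code(s), nchar(s)), s)
  }
  # node 1 is the most significant position
  expect_equal(state_to_code("100"), 4)
  expect_equal(state_to_code("001"), 1)
})
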