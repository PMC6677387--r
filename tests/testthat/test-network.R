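test_that("layouts have the stated cell counts and exact 3:1 E:I ratio", {
  net1 <- build_layout(1, seed = 1)
  expect_equal(net1$n, 36000)
  expect_equal(sum(net1$is_E), 27000)
  expect_equal(sum(net1$is_E) / sum(!net1$is_E), 3)

  net4 <- build_layout(4, seed = 1)
  expect_equal(net4$n, 9000)
  expect_equal(sum(net4$is_E) / sum(!net4$is_E), 3)

  # non-even axis divisions stay within rounding of 36000/n
  for (n in c(16, 49)) {
    net <- build_layout(n, seed = 1)
    expect_lt(abs(net$n - 36000 / n) / (36000 / n), 0.05)
  }
})

test_that("layout construction enforces its argument contract", {
  expect_error(build_layout(4), "seed")
  expect_error(build_layout(0, seed = 1), "positive integer")
  expect_error(build_layout(2.5, seed = 1), "positive integer")
  expect_error(build_layout(3, seed = 1), "sublattice")
})

test_that("a reduced layout is exactly a sublattice of the full layout", {
  full <- build_layout(1, seed = 5)
  for (n in c(4, 9)) {
    red <- build_layout(n, seed = 5)
    key_full <- paste(full$pos[, 1], full$pos[, 2], full$type)
    key_red <- paste(red$pos[, 1], red$pos[, 2], red$type)
    expect_true(all(key_red %in% key_full))
    # n = 2 keeps every 2nd neuron in one axis only
  }
  half <- build_layout(2, seed = 5)
  expect_equal(half$n, 18000)
})

test_that("per-neuron LGN counts have mean 4, range 1-6, complex cells <= 2", {
  net <- build_layout(4, seed = 3)   # 9000 draws
  expect_true(all(net$lgn_count >= 1 & net$lgn_count <= 6))
  expect_equal(mean(net$lgn_count), 4, tolerance = 0.025)
  expect_equal(mean(net$lgn_count[net$is_E]), 4, tolerance = 0.03)
  expect_true(all(net$lgn_count[net$complex] <= 2))
  expect_equal(sum(net$complex), round(0.3 * sum(net$is_E)))
  expect_false(any(net$complex & !net$is_E))
})

test_that("realized in-degrees match the exhaustive binomial expectation", {
  fx <- make_fixture("ring-100", seed = 11)
  net <- fx$net
  rule <- connectivity_rule()
  net <- sample_connectivity(net, rule, seed = 12)
  for (pair in c("EE", "IE")) {
    expected <- fx$oracle(rule, pair)
    post <- if (pair == "EE") which(net$is_E) else which(!net$is_E)
    realized <- in_degree(net, "E")[post]
    # redraw narrows each neuron to ~1 binomial SD of its own expectation
    se <- sqrt(mean(expected)) / sqrt(length(post))
    expect_lt(abs(mean(realized) - mean(expected)), max(3 * se, 0.5))
  }
  # I inputs additionally respect the >= 2 floor, which can only raise the
  # mean above the plain coin-toss expectation
  exp_EI <- fx$oracle(rule, "EI")
  real_EI <- in_degree(net, "I")[net$is_E]
  expect_gte(mean(real_EI), mean(exp_EI) - 0.3)
  expect_lt(mean(real_EI), mean(exp_EI) + 1.5)
})

test_that("mean in-degree scales as 1/n and every neuron keeps >= 2 I inputs", {
  rule <- connectivity_rule()
  net16 <- build_network(16, seed = 9, rule)
  # bulk (central hypercolumn) neurons, away from the open boundary
  ctl <- which(net16$hc == 5L)
  eE <- ctl[net16$is_E[ctl] & !net16$complex[ctl]]
  expect_equal(mean(lengths(net16$adjacency$pre_E[eE])), 200 / 16,
               tolerance = 0.2)
  iI <- ctl[!net16$is_E[ctl]]
  expect_equal(mean(lengths(net16$adjacency$pre_E[iI])), 775 / 16,
               tolerance = 0.2)
  net49 <- build_network(49, seed = 9, rule)
  bulk <- which(net49$hc == 5L)  # boundary cells may expect < 2 I inputs
  expect_true(all(lengths(net49$adjacency$pre_I[bulk]) >= 2))
})

test_that("an all-zero kernel yields empty adjacency lists", {
  rule <- connectivity_rule()
  rule$p0[] <- 0
  net <- sample_connectivity(toy_network(30, 10, seed = 2), rule, seed = 3)
  expect_true(all(lengths(net$adjacency$pre_E) == 0))
  expect_true(all(lengths(net$adjacency$pre_I) == 0))
  expect_true(all(lengths(net$adjacency$pre_L6) == 0))
})

test_that("a pathological scale (expected I in-degree < 1) warns, not fails", {
  expect_warning(
    sample_connectivity(build_layout(121, seed = 1), connectivity_rule(),
                        seed = 2),
    "pathological")
})

test_that("LGN inputs come from the neuron's own wedge template", {
  net <- tiny_net(seed = 20)
  sheet <- net$lgn_sheet
  for (i in sample(net$n, 20)) {
    cells <- sheet[match(net$lgn_input$cells[[i]], sheet$id), ]
    expect_true(all(cells$angle == net$wedge_angle[i]))
    expect_true(all(cells$hc == net$hc[i]))
    expect_equal(length(net$lgn_input$cells[[i]]), net$lgn_count[i])
  }
})

test_that("template wedges partition each hypercolumn disjointly", {
  net <- build_layout(16, seed = 4)
  wp <- partition_wedges(net, "template")
  expect_length(wp$members, 54)
  all_members <- unlist(wp$members)
  expect_equal(sort(all_members), seq_len(net$n))  # disjoint cover
})

test_that("analysis wedges overlap so each neuron sits in exactly two", {
  net <- build_layout(16, seed = 4)
  wp <- partition_wedges(net, "analysis")
  expect_length(wp$members, 16)
  expect_equal(wp$angle, (0:15) * 180 / 16)
  counts <- table(unlist(wp$members))
  central <- which(net$hc == 5L)
  expect_equal(sort(as.integer(names(counts))), sort(central))
  expect_true(all(counts == 2))
})

test_that("network realizations are reproducible from their seed", {
  a <- build_network(49, seed = 33)
  b <- build_network(49, seed = 33)
  expect_identical(a$adjacency$pre_E, b$adjacency$pre_E)
  expect_identical(a$lgn_input$cells, b$lgn_input$cells)
  c2 <- build_network(49, seed = 34)
  expect_false(identical(a$adjacency$pre_E, c2$adjacency$pre_E))
})

test_that("the 1/49 optimal patch matches the stated small-patch statistics", {
  net <- build_network(49, seed = 8)
  patch <- wedge_patch(net, 90)
  expect_gt(length(patch), 5)
  expect_lt(length(patch), 20)
  expect_equal(mean(lengths(net$adjacency$pre_I[patch])), 2, tolerance = 0.5)
})
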