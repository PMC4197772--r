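counts <- list(I = c(comp = 112L, spines = 112L, exp = 194L),
               II = c(comp = 114L, spines = 114L, exp = 118L),
               III = c(comp = 89L, spines = 61L, exp = 114L))

test_that("constructed trees reproduce the per-class structural counts", {
  for (cls in names(counts)) {
    tree <- build_morphology(cls)
    expect_true(validate_morphology(tree))
    s <- summarize_morphology(tree)
    expect_identical(s$n_compartments, unname(counts[[cls]]["comp"]))
    expect_identical(s$n_spines, unname(counts[[cls]]["spines"]))
  }
})

test_that("type III places no spines on soma, proximal trunk or deep dendrites", {
  tree <- build_morphology("III")
  host <- tree$compartments[tree$spines$parent_id, ]
  expect_false(any(host$region %in% c("soma", "deep")))
  expect_false(any(host$region == "trunk" & host$zone == "proximal"))
  # but distal trunk spines exist (distal-trunk stimulation is a protocol)
  expect_gte(sum(host$region == "trunk" & host$zone == "distal"), 3)
})

test_that("construction is deterministic and rejects unknown classes", {
  expect_identical(build_cell("I"), build_cell("I"))
  expect_identical(build_morphology("II"), build_morphology("II"))
  expect_error(build_cell("IV"), "unknown cell class")
  expect_error(place_spines(build_morphology("I")), "already has spines")
})

test_that("spines have the fixed neck and head geometry", {
  tree <- build_morphology("I")
  necks <- tree$compartments[tree$spines$neck_id, ]
  heads <- tree$compartments[tree$spines$head_id, ]
  expect_true(all(necks$diameter == 0.23 & necks$length == 1.9))
  expect_true(all(heads$diameter == 0.8 & heads$length == 0.8))
  # neck parents are dendritic compartments, heads sit on necks
  expect_true(all(tree$compartments$region[necks$parent_id] %in%
                    c("soma", "trunk", "deep", "terminal")))
  expect_identical(heads$parent_id, necks$id)
})

test_that("missing-spine correction adds the reference total area", {
  for (cls in names(counts)) {
    tree <- place_spines(build_cell(cls))
    corrected <- apply_missing_spine_correction(tree)
    missing <- counts[[cls]]["exp"] - counts[[cls]]["spines"]
    expect_equal(sum(corrected$compartments$extra_area),
                 unname(missing) * 3.37, tolerance = 1e-9)
    # extra area lives only on spine-bearing compartments, uniformly
    extra <- corrected$compartments$extra_area
    hosts <- corrected$spines$parent_id
    expect_true(all(extra[-hosts] == 0))
    expect_equal(length(unique(round(extra[hosts], 12))), 1L)
    # zero area per spine leaves the tree untouched
    expect_identical(apply_missing_spine_correction(tree, area_per_spine = 0),
                     tree)
  }
  expect_equal(sum(apply_missing_spine_correction(
    place_spines(build_cell("III")))$compartments$extra_area),
    (114 - 61) * 3.37)
})

test_that("total membrane area equals the cylinder sum plus corrections", {
  tree <- build_morphology("II")
  comp <- tree$compartments
  oracle <- sum(pi * comp$diameter * comp$length) + sum(comp$extra_area)
  expect_equal(summarize_morphology(tree)$total_area_um2, oracle)
  bare <- build_cell("II")
  expect_identical(summarize_morphology(bare)$n_spines, 0L)
})

test_that("spine selection respects branches, planes and path distances", {
  tree <- build_morphology("I")
  comp <- tree$compartments
  tips <- select_spines(tree, "terminal_tip", 4)
  host <- comp[tree$spines$parent_id[match(tips, tree$spines$head_id)], ]
  expect_identical(sort(host$branch), 1:4)           # distinct branches
  expect_lt(diff(range(host$path_dist)), 1e-9)       # same horizontal plane
  # deterministic and idempotent
  expect_identical(tips, select_spines(tree, "terminal_tip", 4))

  deeps <- select_spines(tree, "deep", 4)
  hostd <- comp[tree$spines$parent_id[match(deeps, tree$spines$head_id)], ]
  expect_identical(sort(hostd$branch), 1:4)
  expect_lt(diff(range(hostd$path_dist)), 1e-9)

  tr <- select_spines(tree, "trunk", 3)
  hostt <- comp[tree$spines$parent_id[match(tr, tree$spines$head_id)], ]
  expect_true(all(diff(hostt$path_dist) > 0))        # outward from the soma
  expect_true(all(hostt$path_dist <= min(comp$path_dist[
    comp$region == "trunk" & !comp$id %in% hostt$id])))
})

test_that("spine selection rejects impossible requests with the maximum", {
  tree2 <- build_morphology("II")
  expect_error(select_spines(tree2, "deep", 4), "at most 3")
  tree3 <- build_morphology("III")
  expect_error(select_spines(tree3, "deep", 1),
               "type III granule neuron models have no spines in the deep dendrites")
  expect_error(select_spines(build_morphology("I"), "terminal_tip", 5),
               "at most 4")
})
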