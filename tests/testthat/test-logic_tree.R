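test_that("the default tree loads with 11 nodes, 6 inputs, and the right root", {
  tree <- load_tree(default_tree_path())
  expect_length(tree$nodes, 11L)
  expect_equal(sum(vapply(tree$nodes, function(n) n$kind == "input", TRUE)), 6L)
  expect_equal(tree$root, "biomass_loss_risk")
  expect_setequal(tree_input_variables(tree),
                  c("mc2_biomass_burned", "mc2_fire_frequency", "mc2_biomass",
                    "mc2_live_biomass", "vegetation_departure", "hudiburg_biomass"))
})

test_that("tree validation rejects cycles, dangling children, arity violations", {
  leaf <- list(name = "a", kind = "input", input_variable = "v1",
               conversion = list(false = 0, true = 1))
  expect_error(logic_tree(list(
    leaf, list(name = "b", kind = "and", children = list("a", "b"))
  )), "cycle")
  expect_error(logic_tree(list(
    list(name = "b", kind = "and", children = list("a", "ghost"))
  )), "dangling")
  expect_error(logic_tree(list(
    leaf, list(name = "b", kind = "and", children = list("a"))
  )), "arity")
  leaf2 <- list(name = "a2", kind = "input", input_variable = "v2",
                conversion = list(false = 0, true = 1))
  expect_error(logic_tree(list(
    leaf, leaf2,
    list(name = "c", kind = "convert", children = list("a", "a2"),
         conversion = list(false = 0, true = 1))
  )), "arity")
  # two roots
  expect_error(logic_tree(list(leaf, leaf2)), "single root")
})

single_cell_inputs <- function(vals) {
  g <- make_grid(1, 1)
  lapply(vals, function(v) make_layer(v, g))
}

test_that("all inputs at their fully-true thresholds give root value 1", {
  tree <- load_tree(default_tree_path())  # paper-profile thresholds
  inputs <- single_cell_inputs(list(
    mc2_biomass_burned = 110, mc2_fire_frequency = 1.0, mc2_biomass = 73148,
    mc2_live_biomass = 29387, vegetation_departure = 3, hudiburg_biomass = 21844))
  res <- evaluate(tree, inputs)
  expect_equal(res$layers$biomass_loss_risk$values[1, 1], 1)
})

test_that("zero observed biomass forces root value 0 regardless of other inputs", {
  tree <- load_tree(default_tree_path())
  set.seed(6)
  for (rep in 1:10) {
    inputs <- single_cell_inputs(list(
      mc2_biomass_burned = runif(1, 0, 300), mc2_fire_frequency = runif(1),
      mc2_biomass = runif(1, 0, 1e5), mc2_live_biomass = runif(1, 0, 5e4),
      vegetation_departure = sample(0:3, 1), hudiburg_biomass = 0))
    res <- evaluate(tree, inputs)
    expect_identical(res$layers$biomass_loss_risk$values[1, 1], 0)
  }
})

test_that("single-cell evaluation matches the recursive scalar oracle", {
  tree <- load_tree(default_tree_path())
  set.seed(7)
  for (rep in 1:30) {
    raw <- list(mc2_biomass_burned = runif(1, -10, 300),
                mc2_fire_frequency = runif(1, -0.2, 1.2),
                mc2_biomass = runif(1, 0, 1.2e5),
                mc2_live_biomass = runif(1, 0, 5e4),
                vegetation_departure = runif(1, 0, 3),
                hudiburg_biomass = runif(1, 0, 4e4))
    res <- evaluate(tree, single_cell_inputs(raw))
    expect_identical(res$layers$biomass_loss_risk$values[1, 1],
                     oracle_eval_root(tree, raw))
  }
})

test_that("vectorized engine equals the per-cell oracle on random trees", {
  set.seed(8)
  g <- make_grid(8, 7, mask = { m <- matrix(TRUE, 8, 7); m[4, ] <- FALSE; m })
  for (rep in 1:10) {
    tree <- random_tree(n_vars = 4, max_depth = 3)
    vars <- unique(tree_input_variables(tree))
    inputs <- lapply(vars, function(v) make_layer(runif(8 * 7), g))
    names(inputs) <- vars
    res <- evaluate(tree, inputs)
    cells <- which(g$valid_mask)
    got <- res$layers[[tree$root]]$values[cells]
    want <- vapply(cells, function(cell) {
      raw <- lapply(inputs, function(l) l$values[cell])
      oracle_eval_root(tree, raw)
    }, 0)
    expect_identical(got, want)
  }
})

test_that("permuting cells of all inputs permutes all outputs identically", {
  tree <- load_tree(default_tree_path())
  g <- make_grid(5, 5)
  set.seed(9)
  raw <- list(mc2_biomass_burned = runif(25, 0, 300),
              mc2_fire_frequency = runif(25),
              mc2_biomass = runif(25, 0, 1e5),
              mc2_live_biomass = runif(25, 0, 5e4),
              vegetation_departure = runif(25, 0, 3),
              hudiburg_biomass = runif(25, 0, 4e4))
  perm <- sample(25)
  res1 <- evaluate(tree, lapply(raw, make_layer, grid = g))
  res2 <- evaluate(tree, lapply(raw, function(v) make_layer(v[perm], grid = g)))
  for (nm in names(res1$layers)) {
    expect_identical(as.vector(res2$layers[[nm]]$values),
                     as.vector(res1$layers[[nm]]$values)[perm])
  }
})

test_that("root is monotone in every raw input under the default tree", {
  tree <- load_tree(default_tree_path())
  g <- make_grid(1, 1)
  set.seed(10)
  base <- list(mc2_biomass_burned = 40, mc2_fire_frequency = 0.3,
               mc2_biomass = 5e4, mc2_live_biomass = 2e4,
               vegetation_departure = 1.5, hudiburg_biomass = 1e4)
  root_of <- function(raw) {
    evaluate(tree, single_cell_inputs(raw))$layers$biomass_loss_risk$values[1, 1]
  }
  r0 <- root_of(base)
  for (v in names(base)) {
    for (bump in c(1.1, 2, 10)) {
      raw <- base
      raw[[v]] <- raw[[v]] * bump
      expect_gte(root_of(raw), r0)
    }
  }
})

test_that("evaluate reports missing inputs and grid mismatches", {
  tree <- load_tree(default_tree_path())
  inputs <- single_cell_inputs(list(mc2_biomass_burned = 10))
  expect_error(evaluate(tree, inputs), "missing input variable")
})

test_that("evaluate_ensemble runs each member independently", {
  b <- small_bundle()
  tree <- load_tree(default_tree_path(),
                    thresholds = derived_thresholds(b))
  sp <- b$scenarios$rcp85_nfs$late
  stacks <- sp$stacks[c("mc2_biomass_burned", "mc2_fire_frequency",
                        "mc2_biomass", "mc2_live_biomass")]
  stacks$vegetation_departure <- fuzzyrisk:::departure_stack(b, "rcp85_nfs", "late")
  shared <- list(hudiburg_biomass = b$observed_biomass)
  results <- evaluate_ensemble(tree, stacks, shared)
  expect_length(results, length(b$member_ids))
  expect_named(results, b$member_ids)

  # 1-member ensemble identical to plain evaluate on that member
  one <- lapply(stacks, function(s) {
    ensemble_stack(s$grid, s$member_ids[1], s$values[1, , , drop = FALSE],
                   s$variable_name, s$units)
  })
  r1 <- evaluate_ensemble(tree, one, shared)[[1]]
  direct <- evaluate(tree, c(lapply(stacks, stack_member, member = 1), shared))
  expect_identical(r1$layers$biomass_loss_risk$values,
                   direct$layers$biomass_loss_risk$values)

  # permuted member order is a mismatch
  perm <- stacks
  s <- perm$mc2_biomass
  perm$mc2_biomass <- ensemble_stack(s$grid, rev(s$member_ids),
                                     s$values[rev(seq_along(s$member_ids)), , ],
                                     s$variable_name, s$units)
  expect_error(evaluate_ensemble(tree, perm, shared), "member-id mismatch")
})

test_that("node_stack collects a node across members", {
  b <- small_bundle()
  rc <- run_config(bundle = b)
  res <- run_scenario(rc, "rcp45_fs", "early")
  expect_identical(res$root_stack$member_ids, b$member_ids)
  expect_equal(res$root_stack$values[2, , ],
               res$member_results[[2]]$layers$biomass_loss_risk$values)
})
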