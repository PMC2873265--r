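test_that("simulated trees are valid, deterministic, and shaped as requested", {
  expect_equal(simulate_fold_tree(1), "F0001;")
  expect_equal(simulate_fold_tree(4, "caterpillar"),
               "(F0001,(F0002,(F0003,F0004)));")
  a <- simulate_fold_tree(12, "random_bifurcating", seed = 99)
  b <- simulate_fold_tree(12, "random_bifurcating", seed = 99)
  expect_identical(a, b)
  c2 <- simulate_fold_tree(12, "random_bifurcating", seed = 100)
  expect_false(identical(a, c2))
  tr <- read_fold_tree(a)
  expect_setequal(tr$leaves, sprintf("F%04d", 1:12))
  expect_error(simulate_fold_tree(0), class = "fold_data_error")
})

test_that("caterpillar ancestries form the even ladder", {
  at <- ancestry_values(read_fold_tree(simulate_fold_tree(101, "caterpillar")))
  expect_equal(sort(unique(at$ancestry)), (0:99) / 99)
})

test_that("simulated censuses honour fold counts, redundancy, and ground truth", {
  grid <- uniform_grid_table(200)
  spec <- category_spec("cat A", 30, 1, 1, redundancy = 3)
  sim <- simulate_census(spec, grid, seed = 21)
  truth <- sim$truth[["cat A"]]
  expect_equal(nrow(truth), 30)
  mentions <- unlist(sim$records$fold_ids)
  expect_equal(length(mentions), 90)            # redundancy 3 => 3x mentions
  expect_setequal(unique(mentions), truth$fold_id)
  expect_setequal(nonredundant_fold_set(sim$records, "cat A"), truth$fold_id)
  expect_true(all(lengths(sim$records$fold_ids) %in% 1:3))

  # exhaustive sampling returns the whole table
  all_sim <- simulate_census(category_spec("all", 200, 2, 5), grid, seed = 1)
  expect_setequal(all_sim$truth[["all"]]$fold_id, grid$fold_id)
  expect_error(simulate_census(category_spec("x", 201, 1, 1), grid),
               class = "fold_data_error")
})

test_that("simulate_census is deterministic under a fixed seed", {
  grid <- uniform_grid_table(100)
  specs <- rbind(category_spec("a", 10, 1, 5), category_spec("b", 20, 3, 1))
  s1 <- simulate_census(specs, grid, seed = 8)
  s2 <- simulate_census(specs, grid, seed = 8)
  expect_identical(s1, s2)
})

test_that("ancient-biased Beta weights pull sampled ancestries low", {
  grid <- uniform_grid_table(1000)
  means <- vapply(1:20, function(s) {
    sim <- simulate_census(category_spec("c", 5, 1, 9), grid, seed = s)
    mean(sim$truth[["c"]]$ancestry)
  }, numeric(1))
  expect_lt(mean(means), 0.3)   # Beta(1,9) mean is 0.1
})

test_that("stochastically earlier categories expand earlier on average", {
  grid <- uniform_grid_table(2000)
  specs <- rbind(category_spec("early", 100, 1, 6),
                 category_spec("late", 100, 6, 1))
  th <- c(0.1, 0.25, 0.5, 0.75)
  diffs <- sapply(1:10, function(s) {
    sim <- simulate_census(specs, grid, seed = s)
    e <- join_ancestry(sim$truth[["early"]]$fold_id, grid, "early")
    l <- join_ancestry(sim$truth[["late"]]$fold_id, grid, "late")
    expansion_at(e, th) - expansion_at(l, th)
  })
  expect_true(all(rowMeans(diffs) >= 0))
})

test_that("simulated markers hit the smallest ancestry at or above the targets", {
  grid <- uniform_grid_table(101)
  mk <- simulate_markers(grid, 0.19, 0.40)
  mklist <- list(rnr = mk$fold_id[mk$marker_type == "rnr_catalytic"],
                 dom = mk$fold_id[mk$marker_type == "domain_restricted"])
  eb <- era_boundaries(grid, mklist$rnr, mklist$dom)
  expect_equal(eb$b1, 0.19)
  expect_equal(eb$b2, 0.40)

  both0 <- simulate_markers(grid, 0, 0)
  expect_equal(unique(both0$fold_id), grid$fold_id[1])
  expect_error(simulate_markers(grid, 0.5, 0.4), class = "fold_data_error")

  dec <- simulate_markers(grid, 0.19, 0.40, n_decoys = 3, seed = 4)
  expect_gt(nrow(dec), 2)
  mk2 <- list(rnr = dec$fold_id[dec$marker_type == "rnr_catalytic"],
              dom = dec$fold_id[dec$marker_type == "domain_restricted"])
  eb2 <- era_boundaries(grid, mk2$rnr, mk2$dom)
  expect_equal(c(eb2$b1, eb2$b2), c(0.19, 0.40))  # decoys never move the minima
})

test_that("generated artifacts round-trip through the package readers", {
  grid <- uniform_grid_table(150)
  sim <- simulate_census(rbind(category_spec("a", 25, 1, 4),
                               category_spec("b", 40, 4, 1)),
                         grid, seed = 31)
  cpath <- withr::local_tempfile(fileext = ".tsv")
  write_census_table(sim$records, cpath)
  back <- read_census_table(cpath)
  expect_equal(back$protein_id, sim$records$protein_id)
  expect_equal(unclass(back$fold_ids), unclass(sim$records$fold_ids))

  mpath <- withr::local_tempfile(fileext = ".tsv")
  write_marker_table(simulate_markers(grid, 0.2, 0.6), mpath)
  mk <- read_marker_table(mpath)
  expect_length(mk$rnr_catalytic, 1)
  expect_length(mk$domain_restricted, 1)
})
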