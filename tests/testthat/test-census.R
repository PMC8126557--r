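test_that("the cubic order-12 census finds 85 graphs and one constructor", {
  cen <- cached("census_12_3", run_census(12, 3))
  expect_equal(attr(cen, "L"), 85)
  expect_equal(attr(cen, "A"), 1)
  expect_equal(census_summary(cen)$ratio, 1 / 85)
  expect_equal(anyDuplicated(cen$graph6), 0L)
  # per-row quantities are consistent with a direct recomputation
  i <- which(cen$is_constructor)
  g <- read_graph6(cen$graph6[i])[[1]]
  out <- perturb_search(g)
  expect_equal(cen$n_eff_best[i], out$best_n_eff, tolerance = 1e-12)
  expect_equal(cen$max_tau[i], max(out$tau_remeet), tolerance = 1e-12)
})

test_that("census runs are deterministic and resumable", {
  cen <- cached("census_12_3", run_census(12, 3))
  again <- run_census(12, 3)
  expect_identical(cen, again)
  # interrupting after a checkpoint and resuming yields the same table
  ck <- tempfile(fileext = ".csv")
  graphs <- enumerate_regular(10, 3)
  full <- run_census(10, 3, graphs = graphs)
  partial <- run_census(10, 3, graphs = graphs[1:7], checkpoint = ck,
                        checkpoint_every = 7L)
  resumed <- run_census(10, 3, graphs = graphs, checkpoint = ck,
                        checkpoint_every = 1000L)
  for (col in c("graph6", "max_tau", "n_eff_best", "is_constructor"))
    expect_equal(resumed[[col]], full[[col]], tolerance = 1e-12)
})

test_that("the fixation stage is opt-in and respects its cap", {
  graphs <- enumerate_regular(12, 3)
  cen <- run_census(12, 3, fixation = "constructors", graphs = graphs)
  i <- which(cen$is_constructor)
  expect_false(any(is.na(cen$r_max[i])))
  expect_true(all(is.na(cen$r_max[-i])))
  expect_gt(cen$r_max[i], 1)
  expect_warning(run_census(16, 3, fixation = "constructors",
                            graphs = enumerate_regular(16, 3)[1:3],
                            fixation_cap = 14L),
                 "cap")
})

test_that("figure data export writes the documented tables", {
  cen <- cached("census_12_3", run_census(12, 3))
  dir <- tempfile("figdata")
  paths <- export_figure_data(cen, dir)
  expect_true(all(file.exists(paths)))
  expect_true(any(grepl("remeeting_scatter", paths)))
  expect_true(any(grepl("family_density", paths)))
  fam <- read.csv(paths[grepl("family_density", paths)])
  expect_equal(nrow(fam), 2001)
  expect_true(all(c("constructors", "rest", "kesten_mckay") %in% names(fam)))
  dist <- read.csv(paths[grepl("family_distance", paths)])
  expect_true(all(dist$distance >= 0))
  # re-export is byte-identical (determinism of the pipeline)
  dir2 <- tempfile("figdata2")
  paths2 <- export_figure_data(cen, dir2)
  for (i in seq_along(paths))
    expect_identical(readLines(paths[i]), readLines(paths2[i]))
})

test_that("a slice without constructors skips the density export with a
           warning", {
  cen <- cached("census_8_3", run_census(8, 3))
  expect_equal(attr(cen, "A"), 0)
  expect_warning(export_figure_data(cen, tempfile("empty")), "skipped")
})
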