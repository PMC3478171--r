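test_that("bifurcation tables round-trip through CSV", {
  ev <- data.frame(label = c("H1", "B1", "F1"),
                   alpha2 = c(0.7709, 0.94833, 0.52110))
  f <- withr::local_tempfile(fileext = ".csv")
  write_bifurcation_table(ev, f)
  back <- read_bifurcation_table(f)
  ord <- order(ev$alpha2)          # tables are written parameter-ordered
  expect_equal(back$label, ev$label[ord])
  expect_equal(back$alpha2, ev$alpha2[ord], tolerance = 1e-12)
  # empty tables write a header-only file
  write_bifurcation_table(ev[0, ], f)
  expect_equal(length(readLines(f)), 1L)
  expect_equal(nrow(read_bifurcation_table(f)), 0L)
})

test_that("the region task writes reproducible JSON with the reference geometry", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  run_task(list(task = "region", out_dir = d1))
  run_task(list(task = "region", out_dir = d2))
  j1 <- readLines(file.path(d1, "region.json"))
  expect_identical(j1, readLines(file.path(d2, "region.json")))
  reg <- jsonlite::fromJSON(file.path(d1, "region.json"))
  expect_equal(round(reg$omega_ranges$plus, 3), c(0.148, 0.150))
  expect_equal(round(reg$omega_ranges$minus, 3), c(0.250, 0.294))
})

test_that("the simulate task classifies a steady preset end to end", {
  d <- withr::local_tempdir()
  out <- run_task(list(task = "simulate", preset = "B", t_end = 1200,
                       transient = 800, out_dir = d))
  expect_equal(out$classification$class, "nontrivial_equilibrium")
  expect_true(file.exists(file.path(d, "trajectory.csv")))
  cls <- jsonlite::fromJSON(file.path(d, "classification.json"))
  expect_equal(cls$class, "nontrivial_equilibrium")
})

test_that("the lyapunov task reports the criticality change", {
  d <- withr::local_tempdir()
  out <- run_task(list(task = "lyapunov", n_steps = 40, out_dir = d))
  expect_true(file.exists(file.path(d, "lyapunov.csv")))
  sc <- out$scan
  expect_true(any(sc$criticality == "supercritical") &&
                any(sc$criticality == "subcritical"))
  expect_equal(round(out$gh$omega, 3), 0.281)
})

test_that("remaining task paths run end to end at reduced settings", {
  d <- withr::local_tempdir()
  sp <- run_task(list(task = "spectrum", k1 = 0.138, k2 = 0.66, out_dir = d))
  expect_true(file.exists(file.path(d, "spectrum.json")))
  expect_equal(sp$factor[1], "minus")
  eb <- run_task(list(task = "equilibrium-branch", range = c(1.0, 2.0),
                      n = 60, out_dir = d))
  expect_true(file.exists(file.path(d, "branch.csv")))
  expect_true(nrow(eb$points) > 0)
  t2 <- run_task(list(task = "table2-equilibrium", out_dir = d))
  expect_setequal(t2$label, c("HH1", "ZH1", "GH1", "ZH2"))
  expect_true(file.exists(file.path(d, "table2_equilibrium.csv")))
})

test_that("a short cycle continuation runs through the task interface", {
  d <- withr::local_tempdir()
  out <- run_task(list(task = "cycles", range = c(0.7, 0.8), out_dir = d))
  expect_s3_class(out$branch, "cycle_branch")
  expect_true(nrow(out$branch$points) > 3)
  expect_true(file.exists(file.path(d, "cycle_branch.csv")))
})

test_that("unknown tasks fail loudly", {
  expect_error(run_task(list(task = "nope")), "unknown task")
})
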