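small_cfg <- function(kind, ...) {
  studyConfig(kind = kind, orders = c(2, 3), steps = c(100, 200),
              outdir = tempfile("study-"), ...)
}

test_that("study configuration validates and rejects unknown keys", {
  expect_error(studyConfig("uncontrolled", orders = 1), ">= 2")
  expect_error(studyConfig("uncontrolled", steps = 0), ">= 1")
  expect_error(studyConfig("bogus"))
  f <- tempfile(fileext = ".yaml")
  writeLines(c("kind: optimal", "orders: [2, 3]", "steps: [50]", "typo_key: 1"), f)
  expect_error(readStudyConfig(f), "typo_key")
  writeLines(c("kind: dose", "steps: [50]", "q_m: 2"), f)
  cfg <- readStudyConfig(f)
  expect_identical(cfg$kind, "dose")
  expect_equal(cfg$qM, 2)
})

test_that("center-value extraction interpolates the solution grid", {
  p <- modelParams()
  sols <- lapply(c(2, 3), function(N) solveRegulator(p, N = N, nSteps = 700))
  names(sols) <- c("N2", "N3")
  tab <- centerValueTable(sols)
  expect_identical(dim(tab), c(2L, 4L))
  # per-order values agree closely (uniform-state closure)
  expect_lt(max(abs(tab[1, ] - tab[2, ])), 1e-6)
  # extraction at t = 0 returns the initial density for every order
  tab0 <- centerValueTable(sols, times = 0)
  expect_equal(tab0[[1]], rep(p@m0, 2))
  expect_error(centerValueTable(sols, times = 500), "cover")
})

test_that("convergence study emits the expected shape with tiny inter-order errors", {
  cfg <- small_cfg("convergence")
  rep_dyn <- convergenceStudy(cfg, "dynamical")
  expect_identical(nrow(rep_dyn), 2L)  # one lower order, two step counts
  expect_named(rep_dyn, c("steps", "pair", "error_max", "error_final"))
  expect_true(all(rep_dyn$error_max >= rep_dyn$error_final - 1e-18))
  # spatially uniform regime: orders are interchangeable to roundoff
  expect_true(all(rep_dyn$error_max < 1e-10))
})

test_that("study runs are deterministic and self-describing", {
  cfg1 <- studyConfig("optimal", orders = 3, steps = 300, outdir = tempfile())
  cfg2 <- studyConfig("optimal", orders = 3, steps = 300, outdir = tempfile())
  runStudy(cfg1)
  runStudy(cfg2)
  f1 <- file.path(cfg1$outdir, "optimal_N3.csv")
  f2 <- file.path(cfg2$outdir, "optimal_N3.csv")
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  man <- jsonlite::read_json(file.path(cfg1$outdir, "manifest.json"))
  expect_identical(man$kind, "optimal")
  expect_equal(man$params$m0, 8.5e-3)
  expect_equal(man$params$d_m, 1.66e-2)
  expect_true(file.exists(file.path(cfg1$outdir, "optimal_center_table.csv")))
})

test_that("dose study writes one artifact per printed dose pair", {
  cfg <- studyConfig("dose", orders = 2, steps = 200, outdir = tempfile())
  runStudy(cfg)
  expect_length(list.files(cfg$outdir, pattern = "^dose_..\\.csv$"), 4L)
  d1 <- utils::read.csv(file.path(cfg$outdir, "dose_01.csv"))
  expect_named(d1, c("t", "m_center", "m_min", "m_max", "eta_T", "eta_G"))
  expect_equal(d1$m_center[1], 8.5e-3)
})

test_that("trajectory and solution writers emit the documented columns", {
  p <- modelParams()
  sys <- buildSystem(p, N = 2)
  tr <- integrateEuler(sys, p@m0, timeGrid(0, 10, 10), etaT = 0.1, etaG = 0.2)
  f <- tempfile(fileext = ".csv")
  writeTrajectoryCSV(tr, f)
  got <- utils::read.csv(f)
  expect_named(got, c("t", "m_center", "m_min", "m_max", "eta_T", "eta_G"))
  expect_equal(got$eta_T, rep(0.1, 11))
  sol <- solveRegulator(p, N = 2, nSteps = 50)
  writeSolutionCSV(sol, f)
  got <- utils::read.csv(f)
  expect_named(got, c("t", "m_center", "eta_T", "eta_G", "lambda_center", "p", "g"))
  expect_equal(got$p[nrow(got)], 0)  # terminal condition visible in the artifact
})
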