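test_that("bundled presets load with their documented anchors", {
  expect_setequal(lvhpr_presets(),
                  c("lvhpr_only", "one_energy_degeneration",
                    "one_energy_homeostasis", "three_pair"))
  sc <- load_scenario("one_energy_homeostasis")
  expect_s3_class(sc, "lvhpr_scenario")
  expect_equal(sc$habitat$H, 4)
  sc3 <- load_scenario("three_pair")
  expect_equal(sc3$integrator$t_end, 1e6)
  expect_length(sc3$pairs, 3L)
  for (p in lvhpr_presets()) expect_s3_class(load_scenario(p), "lvhpr_scenario")
})

test_that("invalid configurations are rejected with named causes", {
  base <- yaml::read_yaml(system.file("extdata", "presets",
                                      "one_energy_homeostasis.yaml",
                                      package = "lvhpr"))
  bad_q <- base; bad_q$habitat$q <- 0.5
  expect_error(scenario_from_list(bad_q), "q.*must exceed 1")
  unknown <- base; unknown$habitat$foo <- 1
  expect_error(scenario_from_list(unknown), "unknown key.*habitat")
  unknown2 <- base; unknown2$extra_block <- list(a = 1)
  expect_error(scenario_from_list(unknown2), "unknown key")
  missing <- base; missing$relay <- NULL
  expect_error(scenario_from_list(missing), "missing block.*relay")
  badinit <- base; badinit$init$E1 <- NULL
  expect_error(scenario_from_list(badinit), "init must provide")
  expect_error(load_scenario("no_such_preset"), "no such file or preset")
})

test_that("scenario round-trip load -> write -> load is the identity", {
  for (p in c("one_energy_homeostasis", "three_pair", "lvhpr_only")) {
    sc <- load_scenario(p)
    tmp <- withr::local_tempfile(fileext = ".yaml")
    write_scenario(sc, tmp)
    sc2 <- load_scenario(tmp)
    sc2$name <- sc$name  # name derives from the file name
    expect_equal(sc2, sc)
  }
})

test_that("scenario runs export stable, byte-identical artifacts", {
  sc <- load_scenario("one_energy_homeostasis")
  sc$integrator$t_end <- 1500
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  run_scenario(sc, outdir = d1)
  run_scenario(sc, outdir = d2)
  for (f in c("trajectory.csv", "events.csv", "summary.json")) {
    expect_true(file.exists(file.path(d1, f)))
    expect_identical(readBin(file.path(d1, f), "raw", 1e7),
                     readBin(file.path(d2, f), "raw", 1e7))
  }
  tr <- utils::read.csv(file.path(d1, "trajectory.csv"))
  expect_identical(names(tr), c("t", "X1", "Y1", "E1", "vE1", "gamma_t"))
})

test_that("sweeping H scales the late-window populations linearly", {
  sc <- load_scenario("lvhpr_only")
  sc$integrator$t_end <- 2e4
  tab <- sweep_scenario(sc, "habitat.H", c(1, 2, 4))
  expect_equal(tab$value, c(1, 2, 4))
  expect_true(all(is.na(tab$error)))
  expect_equal(tab$late_X1 / tab$value, rep(tab$late_X1[1], 3), tolerance = 1e-3)
  expect_equal(tab$late_Y1 / tab$value, rep(tab$late_Y1[1], 3), tolerance = 1e-3)
})

test_that("sweep gates empty grids and records per-run failures without stopping", {
  sc <- load_scenario("lvhpr_only")
  sc$integrator$t_end <- 100
  expect_error(sweep_scenario(sc, "habitat.H", numeric(0)), "non-empty")
  expect_error(sweep_scenario(sc, "habitat.H", c(1, NA)), "finite")
  tab <- sweep_scenario(sc, "habitat.q", c(0.5, 2))  # q = 0.5 violates q > 1
  expect_equal(nrow(tab), 2L)
  expect_match(tab$error[1], "q")
  expect_true(is.na(tab$error[2]))
})

test_that("faster degeneration collapses sooner", {
  sc <- load_scenario("one_energy_degeneration")
  sc$integrator$t_end <- 6e4
  sc$energy$t0_degen <- 5e3
  tab <- sweep_scenario(sc, "energy.d", c(0, 2e-3, 8e-3))
  expect_true(is.na(tab$collapse_time[1]))            # d = 0: no collapse
  expect_false(any(is.na(tab$collapse_time[2:3])))
  expect_lt(tab$collapse_time[3], tab$collapse_time[2])
  # semi-analytic check: collapse cannot precede the break-even point of
  # gamma(t) * Y = alpha*H + beta*X at the equilibrium loads
  for (i in 2:3) {
    d <- tab$value[i]
    t_break <- 5e3 + log(0.01 * 1.6 / (0.001 * 4 + 0.002 * 4)) / d
    expect_gt(tab$collapse_time[i], t_break)
  }
})

test_that("the command-line entry point lists presets and prints equilibria", {
  cli <- system.file("cli", "lvhpr.R", package = "lvhpr")
  expect_true(nzchar(cli))
  # make sure the child Rscript sees the same library paths
  withr::local_envvar(R_LIBS = paste(.libPaths(), collapse = .Platform$path.sep))
  out <- suppressWarnings(
    system2("Rscript", c(cli, "presets", "list"), stdout = TRUE, stderr = TRUE))
  expect_true("three_pair" %in% out)
  out2 <- suppressWarnings(
    system2("Rscript", c(cli, "equilibria", "lvhpr_only"),
            stdout = TRUE, stderr = TRUE))
  expect_true(any(grepl("X_bar = 4", out2)))
})
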