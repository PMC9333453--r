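test_that("the scenario registry is discoverable and validates names", {
  expect_true(all(c("subthreshold_impedance", "psp_layers_run",
                    "gamma_int_impedance", "pyr_direct", "calcium_band")
                  %in% list_scenarios()))
  expect_error(run_scenario("not_a_scenario"), "unknown scenario")
  expect_error(run_scenario("calcium_band", overrides = list(bogus = 1)),
               "override")
})

test_that("scenario runs are deterministic given a seed and write outputs", {
  a <- run_scenario("gamma_int_spiking", seed = 3)
  b <- run_scenario("gamma_int_spiking", seed = 3)
  expect_identical(a$summary, b$summary)

  out <- file.path(tempdir(), "nr-scen")
  r <- run_scenario("subthreshold_impedance", seed = 1,
                    overrides = list(f_grid = seq(4, 12, 1)), out_dir = out)
  expect_true(file.exists(file.path(out, "subthreshold_impedance_summary.tsv")))
  expect_true(file.exists(file.path(out, "subthreshold_impedance_profile.tsv")))
  tab <- read.table(file.path(out, "subthreshold_impedance_profile.tsv"),
                    header = TRUE)
  expect_equal(nrow(tab), 9)
})

test_that("sweeps bind one row per value and handle empty grids", {
  expect_equal(nrow(sweep_scenario("calcium_band", "g_C", numeric(0))), 0)
  tab <- sweep_scenario("subthreshold_impedance", "A_in", c(0.02, 0.05),
                        seed = 1)
  expect_equal(nrow(tab), 2)
  expect_true(all(c("A_in", "f_peak") %in% names(tab)))
})

test_that("growing calcium conductance does not shrink the spiking band", {
  # band width (counting sustained-spiking grid points) is non-decreasing in
  # g_C; evaluated on a reduced frequency grid
  widths <- vapply(c(0.3, 0.6), function(gc) {
    s <- run_scenario("calcium_band", seed = 1,
                      overrides = list(g_C = gc, f_grid = seq(2, 30, 2)))$summary
    if (is.na(s[["f_lo"]])) 0 else s[["f_hi"]] - s[["f_lo"]]
  }, 0)
  expect_true(diff(widths) >= 0)
})
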