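test_that("traces round-trip losslessly through CSV", {
  tr <- simulate_trace(ref_rates(), short_opto_schedule(2, 10, 10))
  path <- withr::local_tempfile(fileext = ".csv")
  write_trace(tr, path)
  back <- read_trace(path)
  expect_equal(back$M, tr$M)
  expect_equal(back$lit, tr$lit)
  expect_true(is_normalized(back))
})

test_that("image stacks round-trip through TIFF with sidecar metadata", {
  set.seed(1)
  d <- array(runif(12 * 12 * 3 * 4, 0, 900), c(12, 12, 3, 4))
  stack <- image_stack(d, c("protein", "mitochondria", "nucleus"),
                       pixel_size = 0.2, frame_interval = 4)
  path <- withr::local_tempfile(fileext = ".tif")
  write_stack(stack, path)
  back <- read_stack(path)
  expect_equal(back$data, stack$data, tolerance = 1e-6)
  expect_equal(back$pixel_size, 0.2)
  expect_equal(back$channel_roles, stack$channel_roles)

  # sidecar channel names mapped through a role map
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  meta$channel_roles <- c("Venus", "MitoTracker", "DRAQ5")
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  mapped <- read_stack(path, role_map = c(
    Venus = "protein", MitoTracker = "mitochondria", DRAQ5 = "nucleus"
  ))
  expect_equal(mapped$channel_roles, c("protein", "mitochondria", "nucleus"))

  # missing pixel size without sidecar or override: error
  file.remove(paste0(path, ".json"))
  expect_error(read_stack(path, role_map = c("protein", "mitochondria", "nucleus")),
               "pixel size")
})

test_that("FLIP traces and FRAP series round-trip through their formats", {
  p <- flip_params(0.003, 0.002, 0.002, 0.01, 0.02)
  tr <- simulate_flip(p, "nucleus", seq(0, 60, by = 2))
  path <- withr::local_tempfile(fileext = ".csv")
  write_flip_trace(tr, path)
  back <- read_flip_trace(path)
  expect_equal(back$n, tr$n)
  expect_equal(attr(back, "bleach_site"), "nucleus")

  geom <- small_frap_geometry(size = 32)
  s <- simulate_frap(geom, frap_params(20, 0.03, 0.02, 6),
                     bleach_protocol(roi_radius = 4, n_prebleach = 2,
                                     n_postbleach = 6))
  tp <- withr::local_tempfile(fileext = ".tif")
  write_frap_series(s, tp)
  back_s <- read_frap_series(tp)
  expect_equal(back_s$frames, s$frames, tolerance = 1e-6)
  expect_equal(back_s$times, s$times)
  expect_equal(back_s$geometry$mask, geom$mask)
})

test_that("fits export to JSON and cohorts bind into one row per cell", {
  tr <- simulate_trace(ref_rates(), short_opto_schedule())
  fit <- fit_opto_model(tr, n_starts = 1)
  path <- withr::local_tempfile(fileext = ".json")
  write_fit(fit, path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(obj$model, "opto")
  expect_equal(obj$params$estimate, fit$params$estimate, tolerance = 1e-12)

  tab <- cohort_table(list(cell_a = fit, cell_b = fit))
  expect_equal(nrow(tab), 2)
  expect_true(all(c("cell", "k_imp_estimate", "k_imp_conf_low", "aic") %in% names(tab)))
})

test_that("tidy, glance, coef and autoplot work across fit and data types", {
  tr <- simulate_trace(ref_rates(), short_opto_schedule(2, 20, 20))
  td <- tidy(fit_opto_model(tr, n_starts = 1))
  expect_true(all(c("term", "estimate", "std_error", "conf_low", "conf_high") %in% names(td)))
  fit <- fit_opto_model(tr, n_starts = 1)
  g <- glance(fit)
  expect_equal(nrow(g), 1)
  expect_true(is.finite(g$aic))
  expect_named(coef(fit), fit$params$term)

  expect_s3_class(autoplot(tr), "ggplot")
  expect_s3_class(autoplot(fit), "ggplot")
  p <- flip_params(0.003, 0.002, 0.002, 0.01, 0.02)
  expect_s3_class(autoplot(simulate_flip(p, "nucleus", seq(0, 30, 2))), "ggplot")
})

test_that("the CLI simulates, fits and reports through configs, and rejects bad input", {
  out_dir <- withr::local_tempdir()
  cfg <- list(
    rates = list(k_imp = 0.002, k_exp = 0.002,
                 k_on_unlit = 0.027, k_off_unlit = 0.019,
                 k_on_lit = 0.03, k_off_lit = 0.2),
    protocol = "opto-standard",
    output_dir = out_dir
  )
  cfg_path <- file.path(out_dir, "cfg.yaml")
  yaml::write_yaml(cfg, cfg_path)
  expect_equal(cli_run(c("simulate", "--config", cfg_path)), 0L)
  expect_true(file.exists(file.path(out_dir, "trace.csv")))
  expect_true(file.exists(file.path(out_dir, "resolved-config.json")))

  fit_cfg <- list(input = file.path(out_dir, "trace.csv"), output_dir = out_dir)
  fit_cfg_path <- file.path(out_dir, "fit.yaml")
  yaml::write_yaml(fit_cfg, fit_cfg_path)
  expect_equal(cli_run(c("fit-opto", "--config", fit_cfg_path)), 0L)
  fit_json <- file.path(out_dir, "opto-fit.json")
  expect_true(file.exists(fit_json))
  fit <- jsonlite::read_json(fit_json, simplifyVector = TRUE)
  est <- setNames(fit$params$estimate, fit$params$term)
  expect_equal(est[["k_on_unlit"]], 0.027, tolerance = 0.02)

  rep_cfg_path <- file.path(out_dir, "rep.yaml")
  yaml::write_yaml(list(fits = fit_json, output_dir = out_dir), rep_cfg_path)
  expect_equal(cli_run(c("report", "--config", rep_cfg_path)), 0L)
  cohort <- readr::read_csv(file.path(out_dir, "cohort.csv"), show_col_types = FALSE)
  expect_equal(nrow(cohort), 1)
  expect_true(all(c("k_on_unlit_estimate", "aic", "akaike_weight") %in% names(cohort)))

  expect_equal(suppressMessages(cli_run(c("frobnicate", "--config", cfg_path))), 1L)
  expect_equal(suppressMessages(cli_run(c("simulate", "--config", "/nonexistent.yaml"))), 1L)
  expect_equal(suppressMessages(cli_run(character())), 1L)
})

test_that("a simulated movie flows through segment and fit-opto via the CLI", {
  out_dir <- withr::local_tempdir()
  cfg <- list(
    rates = list(k_imp = 0.002, k_exp = 0.002,
                 k_on_unlit = 0.027, k_off_unlit = 0.019,
                 k_on_lit = 0.03, k_off_lit = 0.2),
    protocol = "opto-standard",
    render_movie = TRUE,
    cell_spec = list(size = 64, n_filaments = 6, filament_length = 60,
                     expression_scale = 4000),
    seed = 3,
    output_dir = out_dir
  )
  cfg_path <- file.path(out_dir, "sim.yaml")
  yaml::write_yaml(cfg, cfg_path)
  expect_equal(cli_run(c("simulate", "--config", cfg_path)), 0L)

  seg_cfg <- list(input = file.path(out_dir, "movie.tif"),
                  protocol = "opto-standard",
                  window_profile = list(n_seeds = 2),
                  output_dir = out_dir)
  seg_path <- file.path(out_dir, "seg.yaml")
  yaml::write_yaml(seg_cfg, seg_path)
  expect_equal(cli_run(c("segment", "--config", seg_path)), 0L)
  raw <- read_trace(file.path(out_dir, "raw-trace.csv"))
  expect_false(is_normalized(raw))

  fit_cfg <- list(input = file.path(out_dir, "raw-trace.csv"), output_dir = out_dir)
  fit_path <- file.path(out_dir, "fitm.yaml")
  yaml::write_yaml(fit_cfg, fit_path)
  expect_equal(cli_run(c("fit-opto", "--config", fit_path)), 0L)
  fit <- jsonlite::read_json(file.path(out_dir, "opto-fit.json"), simplifyVector = TRUE)
  est <- setNames(fit$params$estimate, fit$params$term)
  # documented end-to-end tolerance: 10% on the dark binding rates
  expect_equal(est[["k_on_unlit"]], 0.027, tolerance = 0.1)
  expect_equal(est[["k_off_unlit"]], 0.019, tolerance = 0.1)
})
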