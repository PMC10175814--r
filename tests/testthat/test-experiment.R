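# A single small end-to-end configuration shared across these tests
# (48-pixel images, 36 nodules, 3 epochs) keeps the suite fast; full-scale
# behaviour is exercised by test-acceptance.R.
small_config <- function(out_dir = NULL, seed = 7L) {
  experiment_config(
    phantom = tiny_phantom(seed = seed),
    n_benign = 18L, n_malignant = 18L,
    train = train_config(epochs = 3L, batch_size = 12L, seed = seed),
    beta_grid = c(0, 0.01, 0.02, 0.05),
    n_repetitions = 2L,
    k_subsets = 3L,
    out_dir = out_dir,
    seed = seed)
}

test_that("the conventional-CAM experiment runs end-to-end with coherent outputs", {
  dir <- withr::local_tempdir()
  bundle <- run_experiment_regions(small_config(out_dir = dir))
  k <- bundle$config$k_regions
  expect_length(bundle$aucs, k)
  expect_true(all(bundle$aucs >= 0 & bundle$aucs <= 1))
  expect_gt(bundle$beta, 0)
  expect_equal(diag(bundle$pvalue_matrix$p_values), rep(1, k),
               ignore_attr = TRUE)
  expect_identical(bundle$pvalue_matrix$p_values,
                   t(bundle$pvalue_matrix$p_values))
  expect_equal(dim(bundle$region_scores), c(36L, k))
  expect_true(all(bundle$region_scores >= 0 & bundle$region_scores <= 1))
  # every artifact the run promises is on disk, with provenance
  for (f in c("region_aucs.csv", "beta_table.csv", "delong_pvalues.csv",
              "subset_aucs.csv", "ttest_pvalues.csv", "provenance.json",
              "roc_region_I.csv")) {
    expect_true(file.exists(file.path(dir, f)), label = f)
  }
  prov <- jsonlite::read_json(file.path(dir, "provenance.json"))
  expect_equal(prov$config$seed, 7L)
})

test_that("the malignancy experiment filters its cohort by the 0.4 rule", {
  cfg <- small_config(seed = 8L)
  ds <- generate_dataset(cfg$phantom, cfg$n_benign, cfg$n_malignant,
                         seed = cfg$seed)
  fit <- gapnet_train(model_spec(input_size = cfg$phantom$image_size),
                      ds, cfg$train)
  p <- gapnet_predict(fit$model, ds)[, 2]

  bundle <- run_experiment_malignancy(cfg)
  expect_identical(bundle$cohort, which(p > 0.4))
  expect_true(all(bundle$p_clean > 0.4))

  cfg0 <- cfg
  cfg0$malignancy_cohort_threshold <- 0
  b0 <- run_experiment_malignancy(cfg0)
  expect_length(b0$cohort, 36L)  # threshold 0 keeps every nodule

  cfg1 <- cfg
  cfg1$malignancy_cohort_threshold <- 1.0
  expect_error(run_experiment_malignancy(cfg1), "cohort")
})

test_that("identical config and seed reproduce identical tabular outputs", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  b1 <- run_experiment_regions(small_config(out_dir = d1))
  b2 <- run_experiment_regions(small_config(out_dir = d2))
  expect_identical(b1$aucs, b2$aucs)
  expect_identical(b1$region_scores, b2$region_scores)
  for (f in c("region_aucs.csv", "subset_aucs.csv", "delong_pvalues.csv")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  m1 <- run_simulate(small_config(out_dir = file.path(d1, "sim")))
  m2 <- run_simulate(small_config(out_dir = file.path(d2, "sim")))
  expect_identical(m1, m2)
  expect_identical(readBin(file.path(d1, "sim/dataset/nodule_0001.png"), "raw", 1e6),
                   readBin(file.path(d2, "sim/dataset/nodule_0001.png"), "raw", 1e6))
})

test_that("threshold sweep and dice evaluation produce sane summaries", {
  cfg <- small_config(seed = 9L)
  ds <- generate_dataset(cfg$phantom, cfg$n_benign, cfg$n_malignant,
                         seed = cfg$seed)
  fit <- gapnet_train(model_spec(input_size = cfg$phantom$image_size),
                      ds, cfg$train)
  sw <- run_threshold_sweep(fit$model, ds, c(0, 0.3, 0.6))
  expect_equal(sw$threshold, c(0, 0.3, 0.6))
  expect_true(all(sw$auc >= 0 & sw$auc <= 1))
  expect_true(all(diff(sw$mean_area) < 0))

  d <- run_dice_eval(fit$model, ds)
  expect_equal(nrow(d), 36L)
  expect_true(all(d$dice >= 0 & d$dice <= 1))
  expect_true(attr(d, "median_dice") >= 0 && attr(d, "median_dice") <= 1)
})

test_that("experiment configs round-trip through YAML", {
  cfg <- small_config(seed = 11L)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_experiment_config(cfg, path)
  back <- read_experiment_config(path)
  expect_equal(back$phantom$image_size, cfg$phantom$image_size)
  expect_equal(back$train$epochs, cfg$train$epochs)
  expect_equal(back$beta_grid, cfg$beta_grid)
  expect_equal(back$seed, cfg$seed)
})

test_that("the CLI dispatches simulate, tirads-report and rejects the unknown", {
  dir <- withr::local_tempdir()
  cfg_path <- file.path(dir, "cfg.yaml")
  write_experiment_config(small_config(seed = 5L), cfg_path)
  suppressMessages(camsens_main(c(
    "simulate", "--config", cfg_path, "--out", file.path(dir, "sim"),
    "--seed", "5", "--n-benign", "2", "--n-malignant", "1")))
  manifest <- utils::read.csv(file.path(dir, "sim", "dataset", "manifest.csv"))
  expect_equal(nrow(manifest), 3)
  expect_equal(sum(manifest$label == "malignant"), 1)

  ratings <- data.frame(region_class = "hot",
                        echogenicity = c("hypoechoic", "very hypoechoic"),
                        composition = "solid",
                        foci = c("none", "punctate calcification"))
  rpath <- file.path(dir, "ratings.csv")
  utils::write.csv(ratings, rpath, row.names = FALSE)
  rep <- suppressMessages(camsens_main(c(
    "tirads-report", "--ratings", rpath, "--out", dir)))
  expect_true(file.exists(file.path(dir, "tirads_report.csv")))
  expect_equal(unique(rep$total), (0.5 * 3 + 0.5 * 2) + 2 + 0.5 * 3)

  expect_error(suppressMessages(camsens_main(c("frobnicate"))),
               "unknown subcommand")
  expect_output(camsens_main(character(0)), "usage")
})
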