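# Trial-table construction, CSV round trips and train/validation splitting.

test_that("a valid CSV round-trips through read_trial_table identically", {
  path <- withr::local_tempfile(fileext = ".csv")
  tt <- tiny_table(3)
  write_trial_table(tt, path)
  back <- read_trial_table(path)
  expect_s3_class(back, "trial_table")
  expect_equal(n_plots(back), 3)
  expect_equal(as.data.frame(back), as.data.frame(tt),
               ignore_attr = TRUE)
})

test_that("invariant violations are rejected with row-indexed diagnostics", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("plot_id,gy,ndvi", "p1,5.0,0.6", "p2,6.0,1.3", "p3,7.0,0.7"),
             path)
  expect_error(read_trial_table(path), "ndvi.*row.*2|row.*2.*ndvi")
  writeLines(c("plot_id,gy", "p1,5.0", "p1,6.0"), path)
  expect_error(read_trial_table(path), "plot_id must be unique")
  writeLines(c("plot_id,gy", "p1,5.0", "p2,not_a_number"), path)
  expect_error(read_trial_table(path), "unparseable numeric.*gy.*row.* 2")
  writeLines(c("plot_id,ndvi", "p1,0.5"), path)
  expect_error(read_trial_table(path), "mandatory column: gy")
  expect_error(read_trial_table(file.path(tempdir(), "nope.csv")), "not found")
})

test_that("empty cells become absent values and completeness counts them", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("plot_id,gy,ears", "p1,5.0,410", "p2,6.0,", "p3,7.0,388"), path)
  tt <- read_trial_table(path)
  expect_true(is.na(tt$ears[2]))
  expect_equal(trait_completeness(tt, "ears"), 2)
  expect_equal(trait_completeness(tt, "gy"), 3)
})

test_that("dialect mapping and dd/mm/yyyy dates are accepted", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("Plot,GrainYield,NDVI_anthesis,sown",
               "p1,5.1,0.62,21/11/2016", "p2,9.3,0.81,21/11/2016"), path)
  tt <- read_trial_table(path, dialect = c(plot_id = "Plot",
                                           gy = "GrainYield",
                                           ndvi = "NDVI_anthesis",
                                           sowing_date = "sown"))
  expect_equal(tt$sowing_date[1], as.Date("2016-11-21"))
  expect_equal(tt$ndvi, c(0.62, 0.81))
  expect_error(
    read_trial_table(path, dialect = c(plot_id = "Plot", gy = "missing_col")),
    "missing column")
})

test_that("round-trip identity holds on random tables with absent values", {
  for (seed in 1:5) {
    tt <- random_table(40, seed)
    path <- withr::local_tempfile(fileext = ".csv")
    write_trial_table(tt, path)
    back <- read_trial_table(path)
    expect_equal(as.data.frame(back), as.data.frame(tt), ignore_attr = TRUE)
  }
})

test_that("a 3000-record generated table round-trips exactly", {
  cells <- data.frame(experiment_id = "E1", water_regime = "rainfed",
                      sowing_date = "2020-12-27", germplasm_class = "modern",
                      n_genotypes = 1000L, n_reps = 3L,
                      gy_mean = 5.33, gy_sd = 1.61, h2 = 0.688)
  tt <- generate_trial(generator_config(cells, seed = 42))
  path <- withr::local_tempfile(fileext = ".csv")
  write_trial_table(tt, path)
  back <- read_trial_table(path)
  expect_equal(as.data.frame(back), as.data.frame(tt), ignore_attr = TRUE)
})

test_that("stratified splits draw the validation set per class", {
  cf <- default_configs()$case1_2017
  tt <- generate_trial(cf) # 354 plots: 170 landrace, 184 modern
  scheme <- split_scheme("stratified_random",
                         strata_sizes = c(landrace = 20, modern = 20),
                         seed = 9)
  sp <- split_train_validation(tt, scheme)
  expect_equal(n_plots(sp$validation), 40)
  expect_equal(n_plots(sp$train), 314)
  expect_equal(sum(sp$validation$germplasm_class == "landrace"), 20)
  expect_equal(sum(sp$validation$germplasm_class == "modern"), 20)
  expect_length(intersect(sp$train$plot_id, sp$validation$plot_id), 0)
  expect_setequal(c(sp$train$plot_id, sp$validation$plot_id), tt$plot_id)
  # seeded determinism
  sp2 <- split_train_validation(tt, scheme)
  expect_identical(sp$validation$plot_id, sp2$validation$plot_id)
  expect_error(
    split_train_validation(tt, split_scheme("stratified_random",
                                            strata_sizes = c(landrace = 9999))),
    "stratum")
})

test_that("random_n boundary split yields an empty validation set", {
  tt <- tiny_table(6)
  sp <- split_train_validation(tt, split_scheme("random_n", train_size = 6))
  expect_equal(n_plots(sp$train), 6)
  expect_equal(n_plots(sp$validation), 0)
  expect_error(
    split_train_validation(tt, split_scheme("random_n", train_size = 7)),
    "exceeds")
})

test_that("by_experiment splits assign whole experiments", {
  tt <- generate_trial(default_configs()$case2_2021)
  sp <- split_train_validation(tt, split_scheme(
    "by_experiment", train_experiments = c("E2", "E3", "E4"),
    validation_experiments = "E1"))
  expect_setequal(unique(sp$validation$experiment_id), "E1")
  expect_equal(n_plots(sp$validation), sum(tt$experiment_id == "E1"))
  expect_setequal(unique(sp$train$experiment_id), c("E2", "E3", "E4"))
  expect_error(split_train_validation(tt, split_scheme(
    "by_experiment", train_experiments = "E2",
    validation_experiments = "E99")), "unknown experiment")
  expect_error(split_scheme("by_experiment", train_experiments = "E1",
                            validation_experiments = "E1"), "disjoint")
})

test_that("splitting does not mutate its input table", {
  tt <- tiny_table(6)
  before <- as.data.frame(tt)
  invisible(split_train_validation(tt, split_scheme("random_n", train_size = 3)))
  expect_identical(as.data.frame(tt), before)
})

test_that("write_split exports both sets with a set column", {
  tt <- tiny_table(6)
  sp <- split_train_validation(tt, split_scheme("random_n", train_size = 4))
  path <- withr::local_tempfile(fileext = ".csv")
  write_split(sp, path)
  out <- utils::read.csv(path)
  expect_equal(sort(unique(out$set)), c("train_pool", "validation"))
  expect_equal(nrow(out), 6)
})
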