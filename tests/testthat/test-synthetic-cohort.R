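test_that("schema validation rejects invalid parameters", {
  expect_s3_class(validate_schema(nafld_schema()), "cohort_schema")
  bad_sd <- cohort_schema(list(
    schema_variable("A", "continuous", mean0 = 1, sd0 = 1, mean1 = 1, sd1 = 1)))
  bad_sd$vars$A$sd1 <- -1
  expect_error(validate_schema(bad_sd), "SD")
  expect_error(cohort_schema(list(
    schema_variable("B", "nominal", levels = c("x", "y"),
                    p0 = c(0.7, 0.7), p1 = c(0.5, 0.5)))), "sum to 1")
})

test_that("schema survives a JSON round trip", {
  path <- tempfile(fileext = ".json")
  schema_to_json(nafld_schema(), path)
  back <- schema_from_json(path)
  expect_equal(length(back$vars), 30)
  expect_equal(back$vars$BMI$p1, nafld_schema()$vars$BMI$p1)
  expect_equal(back$vars$TG$mean1, 193.89)
})

test_that("cohorts match the scenario prevalence and are seed-stable", {
  co <- generate_cohort(nafld_schema(), default_scenario(seed = 1))
  expect_equal(nrow(co), 1600)
  expect_equal(ncol(co), 31)          # 30 predictors + outcome
  expect_false(anyNA(co))
  # realised prevalence within 3 SE of 359/1600
  p0 <- 359 / 1600
  se <- sqrt(p0 * (1 - p0) / 1600)
  expect_lt(abs(mean(co$NAFLD) - p0), 3 * se)
  # identical seed, identical cohort
  expect_identical(co, generate_cohort(nafld_schema(), default_scenario(seed = 1)))
  expect_false(identical(
    co, generate_cohort(nafld_schema(), default_scenario(seed = 2))))
})

test_that("a degenerate always-zero rule yields an all-zero outcome", {
  sc <- default_scenario(n_subjects = 200, seed = 3,
                         planted_rules = list(list(when = "TRUE", risk = 0)))
  expect_equal(sum(generate_cohort(nafld_schema(), sc)$NAFLD), 0)
})

test_that("mean prevalence over many seeds matches the study group split", {
  p <- vapply(1:200, function(s)
    mean(generate_cohort(nafld_schema(), default_scenario(seed = s))$NAFLD), 0)
  expect_lt(abs(mean(p) - 359 / 1600), 0.01)
})

test_that("group-conditional means converge to the schema parameters", {
  schema <- nafld_schema()
  cont <- Filter(function(v) v$kind == "continuous", schema$vars)
  for (s in 1:10) {
    co <- generate_cohort(schema, default_scenario(seed = 40 + s))
    g <- attr(co, "latent_group")
    for (v in cont) {
      for (grp in 0:1) {
        m <- if (grp == 0) v$mean0 else v$mean1
        sdv <- if (grp == 0) v$sd0 else v$sd1
        n_g <- sum(g == grp)
        # the generator mean-corrects the physiologic truncation at 0
        expect_lt(abs(mean(co[[v$name]][g == grp]) - m), 4 * sdv / sqrt(n_g))
      }
    }
  }
})

test_that("train/test split partitions with the stated sizes", {
  co <- generate_cohort(nafld_schema(), default_scenario(seed = 5))
  sp <- split_train_test(co, 0.7, seed = 9)
  expect_equal(nrow(sp$train), 1120)
  expect_equal(nrow(sp$test), 480)
  expect_setequal(c(rownames(sp$train), rownames(sp$test)), rownames(co))
  expect_length(intersect(rownames(sp$train), rownames(sp$test)), 0)
  # stratification keeps class shares close
  expect_lt(abs(mean(sp$train$NAFLD) - mean(sp$test$NAFLD)), 0.005)
  # generator attributes follow the rows
  expect_length(planted_risk(sp$test), 480)
  # determinism and error handling
  sp2 <- split_train_test(co, 0.7, seed = 9)
  expect_identical(sp$train, sp2$train)
  expect_error(split_train_test(co, 1.2), "train_fraction")
  sp3 <- split_train_test(co[1:10, ], 0.5, seed = 1)
  expect_equal(nrow(sp3$train), 5)
  expect_equal(nrow(sp3$test), 5)
})

test_that("cohorts survive a CSV round trip", {
  co <- generate_cohort(nafld_schema(),
                        default_scenario(n_subjects = 80, seed = 11))
  path <- tempfile(fileext = ".csv")
  write_cohort(co, path)
  back <- read_cohort(path, nafld_schema())
  expect_equal(back$BMI, co$BMI)
  expect_true(is.ordered(back$BMI))
  expect_equal(back$WHR, co$WHR, tolerance = 1e-12)
  expect_equal(back$NAFLD, co$NAFLD)
})
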