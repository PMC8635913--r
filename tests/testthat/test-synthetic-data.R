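test_that("generator hits the requested size, schema and positive rate", {
  ds <- sim_pima(768, seed = 1, positive_rate = 0.35)
  expect_s3_class(ds, "clinical_dataset")
  expect_equal(dim(ds$features), c(768L, 8L))
  expect_identical(colnames(ds$features),
                   c("Pregnanci", "Glucose", "BloodPressure",
                     "SkinThickness", "Insulin", "BMI",
                     "DiabetesPedigreeFunction", "Age"))
  expect_true(all(ds$labels %in% 0:1))
  expect_true(all(ds$features == round(ds$features)))  # integer fields
  expect_true(all(ds$features >= 0))
  expect_lt(abs(mean(ds$labels) - 0.35), 0.05)
  # degenerate size and determinism
  one <- sim_pima(1, seed = 9)
  expect_equal(nrow(one$features), 1L)
  expect_true(one$labels %in% 0:1)
  expect_identical(sim_pima(100, seed = 3), sim_pima(100, seed = 3))
  expect_false(identical(sim_pima(100, seed = 3)$features,
                         sim_pima(100, seed = 4)$features))
  expect_error(sim_pima(0, 1), "n")
  expect_error(sim_pima(10, 1, positive_rate = 1.2), "positive_rate")
})

test_that("train/test split follows the rounding rule and partitions rows", {
  ds <- sim_pima(768, seed = 2)
  sp <- train_test_split(ds, 0.3, seed = 5)
  expect_equal(nrow(sp$train$features), 538L)  # 768 - round(768 * 0.3)
  expect_equal(nrow(sp$test$features), 230L)
  sp2 <- train_test_split(sim_pima(10, seed = 2), 0.5, seed = 5)
  expect_equal(nrow(sp2$train$features), 5L)
  expect_equal(nrow(sp2$test$features), 5L)
  # disjoint + exhaustive: row multiset is preserved
  key <- function(ds) sort(apply(cbind(ds$features, ds$labels), 1, paste,
                                 collapse = ","))
  expect_identical(sort(c(key(sp$train), key(sp$test))), key(ds))
  expect_error(train_test_split(ds, 0, 1), "test_fraction")
})

test_that("device partition is even, disjoint and exhaustive", {
  ds <- sim_pima(768, seed = 2)
  train <- train_test_split(ds, 0.3, seed = 5)$train
  pt <- partition_devices(train, 20, seed = 7)
  sizes <- vapply(pt$shards, function(s) nrow(s$features), 0L)
  expect_equal(sort(unique(sizes)), c(26L, 27L))    # 538 = 18*27 + 2*26
  expect_equal(sum(sizes == 27L), 18L)
  key <- function(d) apply(cbind(d$features, d$labels), 1, paste,
                           collapse = ",")
  all_rows <- unlist(lapply(pt$shards, key))
  expect_identical(sort(all_rows), sort(key(train)))
  # property: true partition for assorted (n, K)
  for (case in list(c(20, 20), c(37, 5), c(11, 1))) {
    d <- sim_pima(case[1], seed = case[1])
    p <- partition_devices(d, case[2], seed = 1)
    sz <- vapply(p$shards, function(s) nrow(s$features), 0L)
    expect_lte(max(sz) - min(sz), 1L)
    expect_identical(sort(unlist(lapply(p$shards, key))), sort(key(d)))
  }
  expect_error(partition_devices(sim_pima(5, 1), 6, 1), "exceeds")
})

test_that("logistic refit on a large sample recovers every coefficient sign", {
  ds <- sim_pima(5000, seed = 13)
  pv <- ds$provenance
  xs <- scale(ds$features, center = pv$centers, scale = pv$scales)
  fit <- suppressWarnings(glm.fit(cbind(xs, 1), ds$labels,
                                  family = binomial()))
  est <- fit$coefficients[1:8]
  expect_true(all(sign(est) == sign(pv$beta)))
})

test_that("CSV round-trip preserves the dataset and enforces the schema", {
  ds <- sim_pima(60, seed = 21)
  path <- withr::local_tempfile(fileext = ".csv")
  write_pima_csv(ds, path)
  header <- readLines(path, n = 1)
  expect_identical(header,
                   paste0("Pregnanci,Glucose,BloodPressure,SkinThickness,",
                          "Insulin,BMI,DiabetesPedigreeFunction,Age,Outcome"))
  back <- read_pima_csv(path)
  expect_equal(unname(back$features), unname(ds$features))
  expect_equal(back$labels, ds$labels)
  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("a,b", "1,2"), bad)
  expect_error(read_pima_csv(bad), "header")
})
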