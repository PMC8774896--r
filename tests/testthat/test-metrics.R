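test_that("signed error and MAE follow their per-column definitions", {
  expect_equal(signed_error(c(5, 5), c(5, 5)), 0)
  expect_equal(signed_error(c(5, 5), c(4, 6)), 0)     # cancellation
  expect_equal(signed_error(c(2, 4, 6), c(1, 2, 3)), 2)
  expect_equal(mean_absolute_error(c(5, 5), c(5, 5)), 0)
  expect_equal(mean_absolute_error(c(5, 5), c(4, 6)), 1)
  expect_equal(mean_absolute_error(c(2, 4, 6), c(1, 2, 3)), 2)
  expect_error(signed_error(c(1, 2), c(1, 2, 3)), "mismatch",
               class = "oct_validation_error")
})

test_that("metric identities hold on random boundary pairs", {
  set.seed(23)
  for (i in 1:50) {
    W <- sample(2:30, 1)
    a <- runif(W, 0, 100); b <- runif(W, 0, 100)
    expect_equal(signed_error(a, b), -signed_error(b, a))
    expect_gte(mean_absolute_error(a, b), abs(signed_error(a, b)))
    expect_equal(mean_absolute_error(a, a), 0)
    expect_gt(mean_absolute_error(a, b), 0)  # a != b almost surely
    cshift <- runif(1, -5, 5)
    expect_equal(signed_error(a + cshift, b), signed_error(a, b) + cshift)
    expect_lte(abs(mean_absolute_error(a + cshift, b) -
                     mean_absolute_error(a, b)), abs(cshift) + 1e-12)
  }
})

test_that("evaluate summarises per layer with population std across images", {
  truth <- list(B1 = c(10, 10, 10))
  r1 <- list(B1 = c(11, 11, 11))   # SE +1
  r2 <- list(B1 = c(9, 9, 9))      # SE -1
  rep <- evaluate(list(r1, r2), list(truth, truth))
  b1 <- rep[rep$layer == "B1", ]
  expect_equal(b1$se_mean, 0)
  expect_equal(b1$se_std, 1)       # population, not sample, std
  expect_equal(b1$ae_mean, 1)
  expect_equal(attr(rep, "n_images"), 2)
})

test_that("perfect agreement gives an all-zero report", {
  bmap <- list(B1 = c(1, 2, 3), B7 = c(9, 9, 9))
  rep <- evaluate(bmap, bmap)
  expect_true(all(rep$se_mean == 0 & rep$ae_mean == 0 &
                    rep$se_std == 0 & rep$ae_std == 0))
  expect_true("Total" %in% rep$layer)
})

test_that("AE dominates |SE| on every layer row of random evaluations", {
  set.seed(29)
  results <- truths <- list()
  for (i in 1:4) {
    W <- 20
    truths[[i]] <- stats::setNames(
      lapply(1:9, function(j) runif(W, 20, 200)), oct_layers)
    results[[i]] <- lapply(truths[[i]], function(v) v + rnorm(W, 0, 2))
  }
  rep <- evaluate(results, truths)
  expect_true(all(rep$ae_mean >= abs(rep$se_mean) - 1e-12))
  expect_true(all(rep$se_std >= 0 & rep$ae_std >= 0))
})

test_that("missing layers in the reference are a validation error", {
  expect_error(evaluate(list(list(B1 = 1:3, B2 = 1:3)),
                        list(list(B1 = 1:3))),
               "B2", class = "oct_validation_error")
})

test_that("metrics reports serialize with the documented header", {
  f <- withr::local_tempfile(fileext = ".csv")
  rep <- evaluate(list(B1 = c(1, 2)), list(B1 = c(1, 3)))
  write_metrics(rep, f)
  lines <- readLines(f)
  expect_match(lines[1], "^# signed error")
  expect_match(lines[2], "^layer,se_mean")
  expect_length(lines, 4)  # comment + header + B1 + Total
})
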