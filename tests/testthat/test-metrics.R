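test_that("PSNR follows its closed form", {
  ref <- formula_image()
  expect_identical(psnr(ref, ref), 100)
  expect_equal(psnr(ref, ref + 0.1), 20, tolerance = 1e-12)
  # halving a constant offset raises PSNR by 20*log10(2) ~ 6.02 dB
  expect_equal(psnr(ref, ref + 0.05) - psnr(ref, ref + 0.1), 20 * log10(2),
               tolerance = 1e-12)
  expect_equal(psnr(ref, ref + 0.1, data_range = 2), 20 + 20 * log10(2),
               tolerance = 1e-12)
  # strictly decreasing in added-noise amplitude
  set.seed(3)
  noise <- matrix(rnorm(length(ref)), nrow(ref))
  vals <- vapply(c(0.01, 0.05, 0.1, 0.2), function(a) psnr(ref, ref + a * noise), 1)
  expect_true(all(diff(vals) < 0))
})

test_that("SSIM matches the independent reference implementation", {
  ref <- formula_image()
  expect_equal(ssim(ref, ref), 1, tolerance = 1e-12)
  expect_lt(ssim(ref, 1 - ref), 1)
  # values frozen from scikit-image structural_similarity
  # (gaussian_weights, sigma 1.5, win 11, no sample covariance, range 1)
  i <- matrix(seq_len(24), 24, 24); j <- t(i)
  est1 <- pmin(pmax(ref + 0.05 * sin(0.5 * i + 0.3 * j), 0), 1)
  expect_equal(ssim(ref, est1), 0.976559696481, tolerance = 1e-9)
  expect_equal(ssim(ref, ref^1.3), 0.973447988300, tolerance = 1e-9)
  expect_equal(ssim(ref, 0.9 * ref + 0.05), 0.993553179450, tolerance = 1e-9)
  expect_error(ssim(matrix(0, 8, 8), matrix(0, 8, 8)), class = "rsmoco_contract_error")
})

test_that("NMSE is the stated percent ratio and scale invariant", {
  expect_identical(nmse(formula_image(), formula_image()), 0)
  expect_equal(nmse(matrix(c(1, 0), 1), matrix(c(1.1, 0), 1)), 1, tolerance = 1e-12)
  ref <- formula_image() + 0.1
  est <- ref + 0.03
  expect_equal(nmse(ref, est), nmse(3.7 * ref, 3.7 * est), tolerance = 1e-10)
  expect_error(nmse(matrix(0, 2, 2), matrix(1, 2, 2)), class = "rsmoco_contract_error")
  # strictly increasing in noise amplitude
  set.seed(4)
  noise <- matrix(rnorm(length(ref)), nrow(ref))
  vals <- vapply(c(0.01, 0.05, 0.1), function(a) nmse(ref, ref + a * noise), 1)
  expect_true(all(diff(vals) > 0))
})

test_that("dataset evaluation aggregates with the population convention", {
  ref <- matrix(0.5, 16, 16)
  rep1 <- evaluate_dataset(list(ref), list(ref))
  expect_identical(rep1$summary$nmse$mean, 0)
  expect_identical(rep1$summary$nmse$sd, 0)
  # hand-built NMSEs of 1% and 3%: mean 2, population sd 1
  est1 <- ref + 0.05                 # 100 * 256*0.0025 / 64 = 1
  est2 <- ref + 0.05 * sqrt(3)       # 3
  rep2 <- evaluate_dataset(list(ref, ref), list(est1, est2))
  expect_equal(rep2$summary$nmse$mean, 2, tolerance = 1e-10)
  expect_equal(rep2$summary$nmse$sd, 1, tolerance = 1e-10)
  expect_error(evaluate_dataset(list(), list()), class = "rsmoco_config_error")
})

test_that("pooled Pearson correlation and JSON round trip work", {
  set.seed(8)
  refs <- replicate(3, matrix(runif(256), 16), simplify = FALSE)
  ests <- lapply(refs, function(r) 0.8 * r + 0.05 * matrix(rnorm(256), 16))
  expect_equal(pearson_pooled(refs, ests),
               stats::cor(unlist(refs), unlist(ests)), tolerance = 1e-12)
  rep3 <- evaluate_dataset(refs, ests)
  path <- tempfile(fileext = ".json")
  report_to_json(rep3, path)
  back <- report_from_json(path)
  expect_equal(back$summary$psnr$mean, rep3$summary$psnr$mean, tolerance = 1e-12)
  expect_equal(back$per_slice$nmse, rep3$per_slice$nmse, tolerance = 1e-12)
  expect_equal(back$pearson_r, rep3$pearson_r, tolerance = 1e-12)
})
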