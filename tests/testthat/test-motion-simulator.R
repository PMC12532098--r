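test_that("centered FFT pair round-trips and is unitary", {
  img <- make_phantom(32, seed = 1)
  k <- to_kspace(img)
  expect_lt(max(abs(from_kspace(k) - img)), 1e-6)
  # Parseval under the chosen normalization
  expect_equal(sum(img^2), sum(Mod(k)^2), tolerance = 1e-10)
  # constant image concentrates on the DC entry (matrix center)
  kc <- to_kspace(matrix(0.5, 16, 16))
  dc <- c(9, 9)
  expect_equal(Mod(kc[dc[1], dc[2]]), 0.5 * 16, tolerance = 1e-10)
  expect_lt(max(Mod(kc[-dc[1], ])), 1e-10)
  expect_error(to_kspace(matrix(c(NA, 1:15), 4)), class = "rsmoco_contract_error")
})

test_that("rigid transforms behave like rotations plus mm translations", {
  img <- make_phantom(32, seed = 2)
  idm <- list(rotation = 0, shift_x = 0, shift_y = 0)
  expect_identical(apply_rigid(img, idm), img)
  # +3 mm along x at 1 mm/pixel equals a 3-pixel column shift
  sh <- apply_rigid(img, list(rotation = 0, shift_x = 3, shift_y = 0), spacing = 1)
  expect_lt(max(abs(sh[, 4:32] - img[, 1:29])), 1e-12)
  expect_true(all(sh[, 1:3] == 0))
  # at 0.5 mm/pixel the same shift moves 6 pixels
  sh2 <- apply_rigid(img, list(rotation = 0, shift_x = 3, shift_y = 0), spacing = 0.5)
  expect_lt(max(abs(sh2[, 7:32] - img[, 1:26])), 1e-12)
  # full-turn rotation is the identity on the interior
  rot <- apply_rigid(img, list(rotation = 360, shift_x = 0, shift_y = 0))
  expect_lt(max(abs(rot[5:28, 5:28] - img[5:28, 5:28])), 1e-6)
  expect_error(apply_rigid(img, idm, spacing = 0), class = "rsmoco_config_error")
})

test_that("slab draws cover exactly the requested lines, disjointly", {
  rng <- rsmoco:::rng_stream(1, "test-slabs")
  expect_identical(draw_slabs(0, c(3, 7), 64, rng), list())
  for (n_lines in c(7L, 10L, 15L)) {
    sl <- draw_slabs(n_lines, c(3, 7), 64, rng)
    expect_identical(sum(vapply(sl, function(s) s$width, 1L)), n_lines)
  }
  # property run: 1000 seeded draws at n_lines = 10
  ok <- vapply(1:1000, function(i) {
    sl <- draw_slabs(10, c(3, 7), 48, rng)
    widths <- vapply(sl, function(s) s$width, 1L)
    starts <- vapply(sl, function(s) s$start, 1L)
    lines <- unlist(Map(function(s, w) s:(s + w - 1), starts, widths))
    sum(widths) == 10L && all(widths <= 7) &&
      anyDuplicated(lines) == 0L && all(lines >= 1 & lines <= 48)
  }, TRUE)
  expect_true(all(ok))
  expect_error(draw_slabs(100, c(3, 7), 64, rng), class = "rsmoco_contract_error")
})

test_that("named presets carry the stated line counts and bounds", {
  expect_identical(severity_preset("heavy")$n_lines, 15L)
  expect_identical(severity_preset("moderate")$n_lines, 10L)
  expect_identical(severity_preset("minor")$n_lines, 7L)
  p <- severity_preset("heavy")
  expect_identical(p$slab_width_range, c(3L, 7L))
  expect_identical(p$rot_bound, 7)
  expect_identical(p$trans_bound, 5)
})

test_that("corruption perturbs exactly the logged lines and nothing else", {
  img <- make_phantom(64, seed = 6)
  pr <- corrupt_slice(img, severity_preset("heavy"), rng_seed = 3, return_kspace = TRUE)
  expect_identical(sum(pr$motion_log$slab_width), 15L)
  expect_true(all(abs(pr$motion_log$rotation) <= 7))
  expect_true(all(abs(pr$motion_log$shift_x) <= 5))
  expect_true(all(abs(pr$motion_log$shift_y) <= 5))
  touched <- unlist(Map(function(s, w) s:(s + w - 1),
                        pr$motion_log$slab_start, pr$motion_log$slab_width))
  untouched <- setdiff(seq_len(64), touched)
  expect_identical(pr$k_mixed[untouched, ], pr$k_original[untouched, ])
  expect_false(identical(pr$k_mixed[touched, ], pr$k_original[touched, ]))
  expect_lt(max(abs(pr$r - (pr$y - pr$x))), 1e-12)
})

test_that("null motion reproduces the input and seeds give determinism", {
  img <- make_phantom(32, seed = 7)
  null_preset <- severity_preset("heavy", rot_bound = 0, trans_bound = 0)
  pr <- corrupt_slice(img, null_preset, rng_seed = 1)
  expect_lt(max(abs(pr$y - img)), 1e-6)
  a <- corrupt_slice(img, severity_preset("moderate"), rng_seed = 5)
  b <- corrupt_slice(img, severity_preset("moderate"), rng_seed = 5)
  expect_identical(a$y, b$y)
  expect_identical(a$motion_log, b$motion_log)
  c2 <- corrupt_slice(img, severity_preset("moderate"), rng_seed = 6)
  expect_false(identical(a$y, c2$y))
  expect_error(corrupt_slice(img * 3, severity_preset("minor")),
               class = "rsmoco_contract_error")
})

test_that("severity ordering degrades image quality monotonically", {
  n <- 12
  mets <- sapply(c("minor", "moderate", "heavy"), function(sev) {
    ps <- numeric(n); ss <- numeric(n)
    for (i in seq_len(n)) {
      img <- make_phantom(64, seed = 100 + i)
      pr <- corrupt_slice(img, severity_preset(sev), rng_seed = 200 + i)
      ps[i] <- psnr(pr$x, pr$y); ss[i] <- ssim(pr$x, pr$y)
    }
    c(psnr = mean(ps), ssim = mean(ss))
  })
  expect_gt(mets["psnr", "minor"], mets["psnr", "moderate"])
  expect_gt(mets["psnr", "moderate"], mets["psnr", "heavy"])
  expect_gt(mets["ssim", "minor"], mets["ssim", "moderate"])
  expect_gt(mets["ssim", "moderate"], mets["ssim", "heavy"])
})

test_that("acquisition noise and central-line exclusion options work", {
  img <- make_phantom(32, seed = 9)
  pr <- corrupt_slice(img, severity_preset("minor"), rng_seed = 2, noise_sigma = 0.05)
  pr0 <- corrupt_slice(img, severity_preset("minor"), rng_seed = 2)
  expect_gt(sd(pr$y - pr0$y), 0.03)
  pe <- severity_preset("minor", exclusion_radius = 4L)
  prx <- corrupt_slice(img, pe, rng_seed = 3, return_kspace = TRUE)
  ctr <- 17
  expect_identical(prx$k_mixed[(ctr - 4):(ctr + 4), ], prx$k_original[(ctr - 4):(ctr + 4), ])
})
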