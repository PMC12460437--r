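# Direct closed-form oracles for the reference-free metrics.
ag_oracle <- function(img) {
  acc <- 0; n <- 0
  for (i in seq_len(nrow(img) - 1)) for (j in seq_len(ncol(img) - 1)) {
    dx <- img[i, j + 1] - img[i, j]
    dy <- img[i + 1, j] - img[i, j]
    acc <- acc + sqrt((dx^2 + dy^2) / 2); n <- n + 1
  }
  acc / n
}

sf_oracle <- function(img) {
  rf <- 0; cf <- 0
  for (i in seq_len(nrow(img))) for (j in 2:ncol(img))
    rf <- rf + (img[i, j] - img[i, j - 1])^2
  for (i in 2:nrow(img)) for (j in seq_len(ncol(img)))
    cf <- cf + (img[i, j] - img[i - 1, j])^2
  sqrt(rf / (nrow(img) * (ncol(img) - 1)) + cf / ((nrow(img) - 1) * ncol(img)))
}

test_that("entropy has its information-theoretic fixed points", {
  expect_equal(metric_en(matrix(0.5, 16, 16)), 0)
  u <- matrix(rep(0:255 / 255, 4), 32, 32)        # exactly uniform histogram
  expect_equal(metric_en(u), 8)
  half <- matrix(rep(c(0, 1), each = 128), 16, 16) # fair coin
  expect_equal(metric_en(half), 1)
  expect_error(metric_en(matrix(numeric(0), 0, 0)), "empty")
})

test_that("gradient metrics match closed forms and loop oracles", {
  expect_equal(metric_ag(matrix(0.3, 8, 8)), 0)
  expect_equal(metric_sf(matrix(0.3, 8, 8)), 0)
  cb <- outer(1:16, 1:16, function(i, j) (i + j) %% 2)
  expect_equal(metric_sf(cb), sqrt(2), tolerance = 1e-12)
  h <- 0.07
  ramp <- matrix(rep(seq_len(12) * h, each = 12), 12, 12, byrow = TRUE)
  expect_equal(metric_ag(ramp), h / sqrt(2), tolerance = 1e-12)
  set.seed(1)
  for (rep in 1:5) {
    x <- matrix(runif(15 * 13), 15, 13)
    expect_equal(metric_ag(x), ag_oracle(x), tolerance = 1e-12)
    expect_equal(metric_sf(x), sf_oracle(x), tolerance = 1e-12)
  }
  expect_error(metric_ag(matrix(1, 1, 1)), "2x2")
})

test_that("SSIM identities and symmetry hold", {
  set.seed(2)
  x <- matrix(runif(32 * 32), 32, 32)
  expect_equal(metric_ssim(x, x), 1, tolerance = 1e-12)
  y <- matrix(runif(32 * 32), 32, 32)
  expect_equal(metric_ssim(x, y), metric_ssim(y, x), tolerance = 1e-12)
  # inverted structured image: structural term flips sign
  expect_lt(metric_ssim(x, 1 - x), 0)
  # two-source convention is the mean of the pairwise values
  z <- matrix(runif(32 * 32), 32, 32)
  expect_equal(metric_ssim(x, y, z),
               (metric_ssim(x, y) + metric_ssim(x, z)) / 2, tolerance = 1e-12)
  expect_error(metric_ssim(x, matrix(0, 4, 4)), "mismatch")
})

test_that("SSIM agrees with an independently computed reference value", {
  # frozen from scikit-image structural_similarity (gaussian_weights = TRUE,
  # sigma = 1.5, use_sample_covariance = FALSE, data_range = 1) on the same
  # deterministic inputs
  set.seed(9)
  x <- matrix(runif(64 * 64), 64, 64)
  y <- matrix(runif(64 * 64), 64, 64)
  expect_equal(metric_ssim(x, y), 0.004831586288514, tolerance = 1e-9)
})

test_that("SCD follows the correlation-of-differences definition", {
  set.seed(3)
  for (rep in 1:10) {
    f <- matrix(runif(64), 8); a <- matrix(runif(64), 8); b <- matrix(runif(64), 8)
    r <- function(x, y) if (sd(x) == 0 || sd(y) == 0) 0 else
      cor(as.vector(x), as.vector(y))
    expect_equal(metric_scd(f, a, b), r(f - b, a) + r(f - a, b),
                 tolerance = 1e-12)
  }
  # independent zero-mean fields: fused = a + b approaches the limit 2
  a <- matrix(rnorm(128 * 128), 128); b <- matrix(rnorm(128 * 128), 128)
  expect_gt(metric_scd(a + b, a, b), 1.9)
  # degenerate variance convention
  x <- matrix(runif(64), 8)
  expect_equal(metric_scd(x, x, x), 0)
})

test_that("edge-transfer metric rewards perfect and punishes absent edges", {
  set.seed(4)
  x <- matrix(runif(32 * 32), 32, 32)
  y <- matrix(runif(32 * 32), 32, 32)
  expect_equal(metric_qabf(x, x, x), 1, tolerance = 1e-6)
  expect_lt(metric_qabf(matrix(0.5, 32, 32), x, y), 0.01)
  # symmetric in the two sources
  f <- (x + y) / 2
  expect_equal(metric_qabf(f, x, y), metric_qabf(f, y, x), tolerance = 1e-12)
  # bounded on fuzzed inputs
  for (rep in 1:10) {
    q <- metric_qabf(matrix(runif(256), 16), matrix(runif(256), 16),
                     matrix(runif(256), 16))
    expect_gte(q, 0); expect_lte(q, 1)
  }
})

test_that("visual information fidelity behaves as an information ratio", {
  set.seed(5)
  x <- matrix(runif(64 * 64), 64, 64)
  y <- matrix(runif(64 * 64), 64, 64)
  expect_equal(metric_vif(x, x, x), 1, tolerance = 1e-6)
  # strong noise strictly reduces fidelity
  noisy <- pmin(pmax(x + matrix(rnorm(64 * 64, 0, 0.25), 64), 0), 1)
  expect_lt(metric_vif(noisy, x, x), metric_vif(x, x, x))
  expect_gte(metric_vif(y, x, x), 0)
})

test_that("metric report bounds hold on fuzzed images", {
  set.seed(6)
  for (rep in 1:3) {
    f <- matrix(runif(48 * 48), 48); a <- matrix(runif(48 * 48), 48)
    b <- matrix(runif(48 * 48), 48)
    rep_ <- evaluate_all(f, a, b)
    expect_true(rep_$en >= 0 && rep_$en <= 8)
    expect_true(rep_$ssim >= -1 && rep_$ssim <= 1)
    expect_true(rep_$qabf >= 0 && rep_$qabf <= 1)
    expect_true(rep_$ag >= 0 && rep_$sf >= 0 && rep_$vif >= 0)
  }
})

test_that("directory evaluation matches per-pair reports and their mean", {
  dirs <- file.path(withr::local_tempdir(), c("f", "a", "b"))
  for (d in dirs) dir.create(d, recursive = TRUE)
  set.seed(7)
  imgs <- lapply(1:2, function(i)
    list(f = matrix(runif(48 * 48), 48), a = matrix(runif(48 * 48), 48),
         b = matrix(runif(48 * 48), 48)))
  for (i in 1:2) {
    nm <- sprintf("p%d.png", i)
    write_image(file.path(dirs[1], nm), imgs[[i]]$f)
    write_image(file.path(dirs[2], nm), imgs[[i]]$a)
    write_image(file.path(dirs[3], nm), imgs[[i]]$b)
  }
  csv <- withr::local_tempfile(fileext = ".csv")
  tab <- evaluate_dir(dirs[1], dirs[2], dirs[3], csv = csv)
  expect_equal(nrow(tab), 3)
  expect_equal(tab$image[3], "mean")
  # aggregate row is the arithmetic mean of the per-pair rows
  for (m in c("vif", "ag", "scd", "qabf", "sf", "en", "ssim"))
    expect_equal(tab[[m]][3], mean(tab[[m]][1:2]), tolerance = 1e-12)
  expect_true(file.exists(csv))
  # unmatched filenames are reported
  file.remove(file.path(dirs[2], "p2.png"))
  expect_error(evaluate_dir(dirs[1], dirs[2], dirs[3]), "p2.png")
})
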