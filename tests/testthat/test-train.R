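tiny_pairs <- function(n = 3, seed = 1, size = 32)
  lapply(seq_len(n), function(i)
    generate_phantom_pair(phantom_config(height = size, width = size,
                                         seed = seed + i - 1)))

test_that("a zero learning rate leaves the parameters unchanged", {
  cfg <- fusion_config(profile = "desk", lr = 0, seed = 1, batch_size = 1)
  p0 <- init_params(cfg)
  st <- train(cfg, tiny_pairs(2), steps = 2, params = p0)
  expect_equal(st$params, p0, tolerance = 0)
})

test_that("training is deterministic in the seed", {
  cfg <- fusion_config(profile = "desk", seed = 7, batch_size = 1)
  pairs <- tiny_pairs(2)
  a <- train(cfg, pairs, steps = 3)
  b <- train(cfg, pairs, steps = 3)
  expect_identical(a$history$l_total, b$history$l_total)
  expect_identical(a$params, b$params)
  cfg2 <- fusion_config(profile = "desk", seed = 8, batch_size = 1)
  c <- train(cfg2, pairs, steps = 3)
  expect_false(identical(a$history$l_total, c$history$l_total))
})

test_that("the mask loss variant demands salient labels", {
  cfg <- fusion_config(profile = "desk", seed = 1, batch_size = 1)
  p <- tiny_pairs(1)[[1]]
  p$salient_label <- NULL
  expect_error(train(cfg, list(p), steps = 1), "salient labels")
  # the pixel variant runs without labels
  cfg2 <- fusion_config(profile = "desk", seed = 1, batch_size = 1,
                        loss_variant = "pixel")
  st <- train(cfg2, list(p), steps = 1)
  expect_s3_class(st, "train_state")
})

test_that("training logs per-step losses and writes the CSV log", {
  cfg <- fusion_config(profile = "desk", seed = 2, batch_size = 1)
  log <- withr::local_tempfile(fileext = ".csv")
  st <- train(cfg, tiny_pairs(2), steps = 4, log_csv = log)
  expect_equal(nrow(st$history), 4)
  expect_true(all(c("l_total", "l_int", "l_text", "lr") %in%
                  names(st$history)))
  expect_true(all(st$history$l_total >= 0))
  expect_equal(nrow(utils::read.csv(log)), 4)
})

test_that("grayscale fusion preserves size and RGB chroma passes through", {
  cfg <- fusion_config(profile = "desk", seed = 3, batch_size = 1)
  st <- train(cfg, tiny_pairs(2), steps = 1)
  p <- tiny_pairs(1, seed = 50)[[1]]
  # grayscale pair
  g <- fuse_images(p$img1, rgb_to_ycbcr(p$img2)$y, st)
  expect_equal(dim(g), dim(p$img1))
  expect_true(all(g >= 0 & g <= 1))
  # RGB second modality: output chroma equals input chroma exactly
  out <- fuse_images(p$img1, p$img2, st)
  expect_equal(dim(out), dim(p$img2))
  yin <- rgb_to_ycbcr(p$img2)
  yout <- rgb_to_ycbcr(out)
  expect_lt(max(abs(yout$cb - yin$cb)), 1e-10)
  expect_lt(max(abs(yout$cr - yin$cr)), 1e-10)
  # repeated runs are bit-identical
  expect_identical(out, fuse_images(p$img1, p$img2, st))
  expect_error(fuse_images(p$img1, matrix(0, 8, 8), st), "differ|sizes")
})

test_that("non-stride-divisible inputs are padded and cropped back", {
  cfg <- fusion_config(profile = "desk", seed = 3, batch_size = 1)
  st <- list(params = init_params(cfg), cfg = cfg)
  i1 <- matrix(runif(35 * 37), 35, 37)
  i2 <- matrix(runif(35 * 37), 35, 37)
  out <- fuse_images(i1, i2, st)
  expect_equal(dim(out), c(35L, 37L))
})

test_that("a directory of synthesized phantoms feeds training", {
  d <- withr::local_tempdir()
  synthesize_phantom_set(d, n = 2, seed = 5, height = 32, width = 32)
  cfg <- fusion_config(profile = "desk", seed = 4, batch_size = 1)
  st <- train(cfg, d, steps = 2)
  expect_equal(st$step, 2)
})

test_that("the CLI subcommands run end to end with correct exit codes", {
  root <- withr::local_tempdir()
  synth_dir <- file.path(root, "set")
  # synth twice with the same seed: identical bytes
  expect_equal(suppressMessages(
    mmfuse_cli(c("synth", "--out", synth_dir, "--n", "2",
                 "--seed", "1", "--height", "48", "--width", "48"))), 0L)
  h1 <- tools::md5sum(list.files(synth_dir, full.names = TRUE))
  synth2 <- file.path(root, "set2")
  suppressMessages(mmfuse_cli(c("synth", "--out", synth2, "--n", "2",
                                "--seed", "1", "--height", "48",
                                "--width", "48")))
  h2 <- tools::md5sum(list.files(synth2, full.names = TRUE))
  expect_identical(unname(h1), unname(h2))
  # train one step and reload the checkpoint
  ckpt <- file.path(root, "model.rds")
  ycfg <- file.path(root, "cfg.yaml")
  yaml::write_yaml(list(profile = "desk", batch_size = 1, epochs = 1,
                        steps_per_epoch = 1, patch = 32), ycfg)
  expect_equal(suppressMessages(
    mmfuse_cli(c("train", "--data", synth_dir, "--out", ckpt,
                 "--config", ycfg, "--seed", "1"))), 0L)
  expect_s3_class(load_checkpoint(ckpt), "train_state")
  # fuse one pair from files
  fused_dir <- file.path(root, "fused"); dir.create(fused_dir)
  expect_equal(suppressMessages(mmfuse_cli(c(
    "fuse", "--img1", file.path(synth_dir, "phantom_001_m1.png"),
    "--img2", file.path(synth_dir, "phantom_001_m2.png"),
    "--ckpt", ckpt, "--out", file.path(fused_dir, "phantom_001_m1.png")))), 0L)
  expect_true(file.exists(file.path(fused_dir, "phantom_001_m1.png")))
  # eval with fused = src1 = src2 gives SSIM exactly 1
  m1_dir <- file.path(root, "m1only"); dir.create(m1_dir)
  file.copy(file.path(synth_dir, "phantom_001_m1.png"), m1_dir)
  file.remove(file.path(fused_dir, "phantom_001_m1.png"))
  file.copy(file.path(m1_dir, "phantom_001_m1.png"), fused_dir)
  csv <- file.path(root, "report.csv")
  invisible(utils::capture.output(ret <- mmfuse_cli(c(
    "eval", "--fused", fused_dir, "--src1", m1_dir, "--src2", m1_dir,
    "--csv", csv))))
  expect_equal(ret, 0L)
  tab <- utils::read.csv(csv)
  expect_true(all(abs(tab$ssim - 1) < 1e-9))
  # usage errors exit 2
  expect_equal(suppressMessages(mmfuse_cli(c("bogus"))), 2L)
  expect_equal(suppressMessages(mmfuse_cli(c("train"))), 2L)
  expect_equal(mmfuse_cli(character(0)), 2L)
})
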