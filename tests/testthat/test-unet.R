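test_that("the network maps inputs to probabilities of the same shape", {
  m <- build_unet(unet_spec(input_size = 32, levels = 3, base_channels = 2),
                  seed = 1)
  img <- array(stats::rnorm(32^3), c(32, 32, 32))
  pred <- predict_mask(m, img)
  expect_equal(dim(pred), c(32, 32, 32))
  expect_true(all(pred %in% c(0L, 1L)))

  m2 <- build_unet(unet_spec(input_size = 16, levels = 2,
                             base_channels = 2), seed = 1)
  img2 <- array(stats::rnorm(16^3), c(16, 16, 16))
  expect_equal(dim(predict_mask(m2, img2)), c(16, 16, 16))

  # probabilities are strictly inside (0, 1)
  fwd <- vcbct:::unet_forward(m2, list(img2), training = FALSE)
  expect_true(all(fwd$probs[[1]] > 0 & fwd$probs[[1]] < 1))
})

test_that("input sizes not divisible by 2^levels are rejected", {
  expect_error(unet_spec(input_size = 100, levels = 4), "divisible")
  m <- build_unet(unet_spec(input_size = 32, levels = 2,
                            base_channels = 2))
  expect_error(predict_mask(m, array(0, c(16, 16, 16))), "input size")
})

test_that("analytic gradients match finite differences", {
  set.seed(42)
  m <- build_unet(unet_spec(input_size = 8, levels = 2, base_channels = 2),
                  seed = 3)
  imgs <- lapply(1:2, function(i) array(stats::rnorm(512), c(8, 8, 8)))
  msks <- lapply(1:2, function(i) {
    array(stats::rbinom(512, 1, 0.3), c(8, 8, 8))
  })
  loss_at <- function(model) {
    fwd <- vcbct:::unet_forward(model, imgs, training = TRUE)
    vcbct:::soft_dice_loss(fwd$probs, msks)$loss
  }
  fwd <- vcbct:::unet_forward(m, imgs, training = TRUE)
  l0 <- vcbct:::soft_dice_loss(fwd$probs, msks)
  grads <- vcbct:::unet_backward(m, fwd, l0$dprobs)
  eps <- 1e-5
  for (layer in c("enc0", "down1", "enc1", "dec0", "head")) {
    for (par in c("W", "gamma")) {
      if (par == "gamma" && layer == "head") next
      idx <- 1L
      up <- m; up$layers[[layer]][[par]][idx] <-
        up$layers[[layer]][[par]][idx] + eps
      dn <- m; dn$layers[[layer]][[par]][idx] <-
        dn$layers[[layer]][[par]][idx] - eps
      num <- (loss_at(up) - loss_at(dn)) / (2 * eps)
      ana <- grads[[layer]][[par]][idx]
      expect_equal(ana, num, tolerance = 1e-4)
    }
  }
})

test_that("dice follows its definition", {
  a <- array(0L, c(10, 10, 10))
  a[1:5, , ] <- 1L
  expect_equal(dice(a, a), 1)

  b <- array(0L, c(10, 10, 10))
  b[6:10, , ] <- 1L
  expect_equal(dice(a, b), 0)

  # |A| = |B| = 100, |A intersect B| = 80 -> 0.8
  a2 <- array(0L, c(10, 10, 10))
  b2 <- array(0L, c(10, 10, 10))
  a2[1:100] <- 1L
  b2[21:120] <- 1L
  expect_equal(dice(a2, b2), 0.8)

  # symmetry on random masks
  set.seed(2)
  for (i in 1:5) {
    x <- array(stats::rbinom(1000, 1, 0.3), c(10, 10, 10))
    y <- array(stats::rbinom(1000, 1, 0.3), c(10, 10, 10))
    expect_equal(dice(x, y), dice(y, x))
  }

  # both empty -> 1 by convention
  z <- array(0L, c(4, 4, 4))
  expect_equal(dice(z, z), 1)
  expect_error(dice(a, z), "shape")
})

test_that("evaluation aggregates per-sample DSC with population spread", {
  m <- build_unet(unet_spec(input_size = 16, levels = 2,
                            base_channels = 2), seed = 1)
  s1 <- ellipsoid_sample(1, size = 16)
  rep1 <- evaluate(m, list(s1))
  expect_equal(attr(rep1, "sd"), 0)
  expect_equal(attr(rep1, "mean"), rep1$dsc[1])
  expect_true(attr(rep1, "mean") >= min(rep1$dsc) &&
                attr(rep1, "mean") <= max(rep1$dsc))

  # mean of hand-made DSC values: 0.8 and 1.0 average to 0.9
  expect_equal(mean(c(0.8, 1)), 0.9)
  rep2 <- evaluate(m, list(s1, ellipsoid_sample(2, size = 16)))
  expect_equal(attr(rep2, "mean"), mean(rep2$dsc))
})

test_that("short training reduces the loss and is seed-deterministic", {
  s <- ellipsoid_sample(7)
  m <- build_unet(unet_spec(input_size = 32, levels = 3,
                            base_channels = 2), seed = 2)
  pr <- train_protocol(round_size = 1, split = 0.8, epochs_per_round = 8,
                       total_epochs = 8, lr = 1e-2, batch_size = 1,
                       seed = 5, val_every = 4)
  t1 <- train(m, list(s), pr)
  h <- t1$history
  expect_lt(h$train_loss[nrow(h)], h$train_loss[1])

  t2 <- train(m, list(s), pr)
  expect_identical(t1$history, t2$history)
  expect_equal(t1$layers$enc0$W, t2$layers$enc0$W)
})

test_that("the network can overfit a single fixture sample", {
  s <- ellipsoid_sample(7)
  m <- build_unet(unet_spec(input_size = 32, levels = 3,
                            base_channels = 4), seed = 2)
  pr <- train_protocol(round_size = 1, split = 0.8, epochs_per_round = 60,
                       total_epochs = 60, lr = 1e-2, batch_size = 1,
                       seed = 5, val_every = 10)
  m2 <- train(m, list(s), pr)
  expect_gt(dice(predict_mask(m2, s$image), s$mask), 0.95)
})

test_that("models round-trip through disk", {
  m <- build_unet(unet_spec(input_size = 16, levels = 2,
                            base_channels = 2), seed = 1)
  path <- file.path(withr::local_tempdir(), "model.rds")
  write_unet(m, path)
  back <- read_unet(path)
  img <- array(stats::rnorm(16^3), c(16, 16, 16))
  expect_identical(predict_mask(back, img), predict_mask(m, img))
})
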