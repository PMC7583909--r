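# tensors with a planted cross-tower rule: positive iff BOTH towers carry
# their blob in the "high" corner; negatives have exactly one high blob, so
# neither tower alone separates the classes
and_rule_data <- function(n, seed) {
  withr::with_seed(seed, {
    y <- rbinom(n, 1, 0.5)
    zl <- ifelse(y == 1, 1, rbinom(n, 1, 0.5))
    zm <- ifelse(y == 1, 1, 1 - zl)
    xl <- array(0, c(20, 20, 4, n)); xm <- array(0, c(20, 20, 4, n))
    for (i in seq_len(n)) {
      cl <- if (zl[i] == 1) c(15, 15) else c(5, 5)
      cm <- if (zm[i] == 1) c(15, 15) else c(5, 5)
      for (ch in 1:4) {
        xl[cl[1] + sample(-2:2, 1), cl[2] + sample(-2:2, 1), ch, i] <- 50
        xm[cm[1] + sample(-2:2, 1), cm[2] + sample(-2:2, 1), ch, i] <- 50
      }
    }
    list(xl = xl, xm = xm, y = y)
  })
}

test_that("analytic gradients match numerical differentiation", {
  cfg <- cnn_config(conv_filters = c(2L, 3L), dense_units = 4L,
                    dropout_conv = 0, dropout_dense = 0, batch_size = 4,
                    epochs = 1, seed = 7, val_frac = 0)
  m <- build_cnn(c(8L, 8L, 2L), cfg)
  dat <- withr::with_seed(42, list(
    xl = array(rnorm(8 * 8 * 2 * 4), c(8, 8, 2, 4)),
    xm = array(rnorm(8 * 8 * 2 * 4), c(8, 8, 2, 4)),
    y = c(1, 0, 1, 0)))
  Xl <- lncmir:::flatten_batch(dat$xl)
  Xm <- lncmir:::flatten_batch(dat$xm)
  fwd <- lncmir:::cnn_forward(m, Xl, Xm, training = TRUE)
  gr <- lncmir:::cnn_backward(m, fwd, dat$y)
  loss_at <- function(mm)
    lncmir:::bce_loss(lncmir:::cnn_forward(mm, Xl, Xm, training = TRUE)$prob,
                      dat$y)
  eps <- 1e-5
  set.seed(1)
  for (nm in names(gr)) {
    p <- m$par[[nm]]
    for (ii in sample(length(p), min(4, length(p)))) {
      m2 <- m
      m2$par[[nm]][ii] <- p[ii] + eps; lp <- loss_at(m2)
      m2$par[[nm]][ii] <- p[ii] - eps; lm <- loss_at(m2)
      num <- (lp - lm) / (2 * eps)
      expect_equal(gr[[nm]][ii], num, tolerance = 1e-4,
                   label = sprintf("grad %s[%d]", nm, ii))
    }
  }
})

test_that("model construction is deterministic and outputs stay in (0, 1)", {
  m1 <- build_cnn(config = fast_cnn())
  m2 <- build_cnn(config = fast_cnn())
  expect_identical(m1$par, m2$par)
  expect_gt(lncmir:::n_parameters(m1), 0L)

  dat <- and_rule_data(8, seed = 3)
  m1$trained <- TRUE  # inference-mode forward with initial weights
  p <- predict(m1, dat$xl, dat$xm)
  expect_true(all(p$probability > 0 & p$probability < 1))
})

test_that("training reduces the loss, is seed-reproducible, and rejects bad input", {
  dat <- and_rule_data(96, seed = 5)
  m <- build_cnn(config = fast_cnn(seed = 2, epochs = 6))
  m <- train_cnn(m, dat$xl, dat$xm, dat$y)
  expect_lt(tail(m$history$train_loss, 1), m$history$train_loss[1])

  m2 <- train_cnn(build_cnn(config = fast_cnn(seed = 2, epochs = 6)),
                  dat$xl, dat$xm, dat$y)
  expect_equal(tail(m$history$train_loss, 1), tail(m2$history$train_loss, 1),
               tolerance = 1e-12)

  expect_error(train_cnn(build_cnn(config = fast_cnn()), dat$xl, dat$xm,
                         rep(1, 96)), "single class")
  expect_error(train_cnn(build_cnn(config = fast_cnn()), dat$xl,
                         dat$xm[, , , 1:10], dat$y), "does not match")
})

test_that("the network learns a cross-tower interaction rule", {
  tr <- and_rule_data(160, seed = 6)
  te <- and_rule_data(80, seed = 7)
  cfg <- cnn_config(conv_filters = c(8L, 16L), dense_units = 32L,
                    batch_size = 32L, epochs = 15L, seed = 1)
  m <- train_cnn(build_cnn(config = cfg), tr$xl, tr$xm, tr$y)
  p <- predict(m, te$xl, te$xm)
  expect_gt(roc_auc(p$probability, te$y), 0.9)
})

test_that("prediction applies the strict 0.5 call threshold", {
  dat <- and_rule_data(16, seed = 8)
  m <- build_cnn(config = fast_cnn())
  m$trained <- TRUE
  p <- predict(m, dat$xl, dat$xm)
  expect_identical(p$call, p$probability > 0.5)
  # deterministic at inference (no dropout)
  p2 <- predict(m, dat$xl, dat$xm)
  expect_identical(p$probability, p2$probability)
  # empty input -> empty output
  p0 <- predict(m, dat$xl[, , , 0, drop = FALSE], dat$xm[, , , 0, drop = FALSE])
  expect_equal(nrow(p0), 0L)
  expect_error(predict(m, array(0, c(19, 20, 4, 2)), dat$xm[, , , 1:2]),
               "shape")
  expect_error(predict(build_cnn(config = fast_cnn()), dat$xl, dat$xm),
               "not been trained")
})
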