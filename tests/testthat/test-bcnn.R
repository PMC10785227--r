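test_that("composite loss: identity, pure offset, and brute-force oracle", {
  set.seed(1)
  y <- matrix(rnorm(16, 0, 100), 4, 4)
  expect_equal(composite_loss(y, y), 0)
  # constant offsets kill every derivative term
  expect_equal(composite_loss(y, y + 37), 37)
  expect_equal(composite_loss(y, y - 2.5, 0.5, 0.5), 2.5)
  # independent brute-force evaluation on a 4x4 pair
  yh <- matrix(rnorm(16, 0, 100), 4, 4)
  d <- y - yh
  l1 <- mean(abs(d))
  gdl <- 0
  gv <- matrix(0, 3, 4); gh <- matrix(0, 4, 3)
  for (i in 1:3) for (j in 1:4) gv[i, j] <- d[i + 1, j] - d[i, j]
  for (i in 1:4) for (j in 1:3) gh[i, j] <- d[i, j + 1] - d[i, j]
  gdl <- mean(gv^2) + mean(gh^2)
  lap <- matrix(0, 2, 2)
  for (i in 2:3) for (j in 2:3)
    lap[i - 1, j - 1] <- d[i + 1, j] + d[i - 1, j] + d[i, j + 1] + d[i, j - 1] - 4 * d[i, j]
  ldl <- mean(lap^2)
  expect_equal(composite_loss(y, yh, 0.01, 0.02), l1 + 0.01 * gdl + 0.02 * ldl,
               tolerance = 1e-12)
  # degenerate weights reduce to plain L1
  expect_equal(composite_loss(y, yh, 0, 0), l1)
  expect_error(composite_loss(y, matrix(0, 3, 3)), "shape")
})

test_that("training is seed-deterministic and reduces the loss on a tiny run", {
  ds <- make_dataset(3, phantom_spec(seed = 1), seed = 21)
  ncfg <- desk_net_config()
  m1 <- bcnn_train(ds$cases[1:2], ncfg, desk_train_config(25, seed = 5))
  m2 <- bcnn_train(ds$cases[1:2], ncfg, desk_train_config(25, seed = 5))
  expect_identical(m1$history, m2$history)
  expect_identical(m1$params, m2$params)
  m3 <- bcnn_train(ds$cases[1:2], ncfg, desk_train_config(25, seed = 6))
  expect_false(identical(m1$history, m3$history))
  expect_true(all(is.finite(m1$history)))
})

test_that("training refuses implant cases under the default policy", {
  icase <- implant_case()
  expect_error(bcnn_train(list(icase), desk_net_config(),
                          desk_train_config(5, seed = 1)),
               "implant-free")
})

test_that("MC dropout estimators match direct evaluation of the stored samples", {
  model <- tiny_trained_model()
  icase <- implant_case()
  mr <- icase$mr[1, 1:32, 1:32, ]   # small region keeps the oracle cheap
  mc <- mc_dropout_infer(model, mr, mc_config(n_samples = 8, seed = 3),
                         keep_samples = TRUE)
  mean_oracle <- apply(mc$samples, c(2, 3), mean)
  var_oracle <- apply(mc$samples, c(2, 3),
                      function(v) mean((v - mean(v))^2))
  expect_lt(max(abs(mc$pct - mean_oracle)), 1e-10)
  expect_lt(max(abs(mc$variance - var_oracle)), 1e-10)
  expect_true(all(mc$variance >= 0))
  # fixed MC seed: bit-reproducible
  mc2 <- mc_dropout_infer(model, mr, mc_config(n_samples = 8, seed = 3))
  expect_identical(mc$pct, mc2$pct)
  expect_identical(mc$variance, mc2$variance)
  expect_error(mc_dropout_infer(model, mr, mc_config(n_samples = 2, seed = 1)),
               NA)
  expect_error(mc_config(n_samples = 1), "n_samples")
})

test_that("dropout rate zero gives zero variance and the deterministic pass", {
  model <- tiny_trained_model()
  model0 <- model
  model0$net_cfg$dropout <- 0
  icase <- implant_case()
  mr <- icase$mr[1, 1:32, 1:32, ]
  mc <- mc_dropout_infer(model0, mr, mc_config(n_samples = 4, seed = 2))
  expect_true(all(mc$variance == 0))
  expect_equal(mc$pct, predict(model0, mr), tolerance = 1e-12)
})
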