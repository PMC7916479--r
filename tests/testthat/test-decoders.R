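test_that("noiseless epochs are decoded perfectly by CCA and FBCCA", {
  rec <- fix_clean_record()
  ep <- record_to_epochs(rec, "wet")
  layout <- fix_layout()
  for (m in c("cca", "fbcca")) {
    res <- loo_block_cv(ep, layout, m, data_length = 1)
    expect_equal(res$accuracy, 1.0)
  }
})

test_that("FBCCA with a single unit-weight sub-band ranks like plain CCA", {
  ep <- record_to_epochs(fix_clean_record(), "dry")
  seg <- classification_segment(ep, 1)
  layout <- fix_layout()
  refs <- make_references(layout, 5, 250, dim(seg$data)[2])
  cfg <- filter_bank_config(1, a = 0, b = 0)   # w = (1)
  for (i in c(1, 13, 24)) {
    fb <- fbcca_classify(seg$data[, , i], refs, cfg, 250)
    plain <- cca_classify(fb_decompose(seg$data[, , i], cfg, 250)[[1]], refs)
    expect_equal(order(fb$scores), order(plain$scores^2))
    expect_equal(fb$predicted, plain$predicted)
  }
})

test_that("FBCCA scores match an independent loop-based recomputation", {
  ep <- record_to_epochs(fix_noisy_record(), "wet")
  seg <- classification_segment(ep, 1)
  layout <- fix_layout()
  rate <- 250
  refs <- make_references(layout, 5, rate, dim(seg$data)[2])
  cfg <- filter_bank_config(3, a = 1.25, b = 0.25)
  got <- fbcca_classify(seg$data[, , 5], refs, cfg, rate)
  # oracle: direct filtering + QR-based CCA + explicit weighted sum
  expected <- numeric(12)
  for (n in 1:3) {
    flt <- signal::cheby1(4, 0.1, c(8 * n, 90) / (rate / 2), type = "pass")
    xf <- t(apply(seg$data[, , 5], 1, function(ch) signal::filtfilt(flt, ch)))
    w_n <- n^(-1.25) + 0.25
    for (k in 1:12) {
      rho <- stats::cancor(t(xf), t(refs$references[[k]]))$cor[1]
      expected[k] <- expected[k] + w_n * rho^2
    }
  }
  expect_equal(got$scores, expected, tolerance = 1e-5)
  expect_equal(got$predicted, which.max(expected))
})

test_that("TRCA recovers the generating topography from rank-1 trials", {
  set.seed(44)
  topo <- unname(default_topography())
  rate <- 250; n <- 250
  t <- (0:(n - 1)) / rate
  s <- sin(2 * pi * 11.25 * t) + 0.4 * sin(2 * pi * 22.5 * t)
  trials <- array(0, dim = c(8, n, 6))
  for (i in 1:6)
    trials[, , i] <- topo %*% t(s) + matrix(rnorm(8 * n, sd = 0.05), 8, n)
  w <- ssvepkit:::trca_filter(trials)
  cosine <- abs(sum(w * topo)) / (sqrt(sum(w^2)) * sqrt(sum(topo^2)))
  expect_gte(cosine, 0.95)
})

test_that("TRCA on identical trials projects the template onto each trial exactly", {
  set.seed(45)
  x <- matrix(rnorm(8 * 100), 8, 100)
  trials <- array(c(x, x), dim = c(8, 100, 2))
  model <- train_trca(trials, targets = c(1, 1), n_classes = 1)
  proj_trial <- as.vector(crossprod(model$filters[, 1], x))
  proj_templ <- as.vector(crossprod(model$filters[, 1], model$templates[, , 1]))
  expect_equal(stats::cor(proj_trial, proj_templ), 1.0, tolerance = 1e-9)
})

test_that("permuting channels permutes the TRCA filter identically", {
  set.seed(46)
  trials <- array(rnorm(6 * 120 * 4), dim = c(6, 120, 4))
  # add a reproducible component so the filter is well defined
  s <- sin(2 * pi * 10 * (0:119) / 250)
  topo <- c(1, 0.8, 0.1, 0.5, 0.3, 0.9)
  for (i in 1:4) trials[, , i] <- trials[, , i] * 0.2 + topo %*% t(s)
  w <- ssvepkit:::trca_filter(trials)
  perm <- c(3, 1, 6, 2, 5, 4)
  wp <- ssvepkit:::trca_filter(trials[perm, , , drop = FALSE])
  expect_equal(wp, w[perm], tolerance = 1e-8)
})

test_that("FBTRCA decodes noiseless epochs and matches a loop-based oracle", {
  ep <- record_to_epochs(fix_clean_record(), "wet")
  layout <- fix_layout()
  res <- loo_block_cv(ep, layout, "fbtrca", data_length = 1)
  expect_equal(res$accuracy, 1.0)
  # oracle on one fixed epoch: explicit per-sub-band ensemble correlations
  seg <- classification_segment(ep, 1)
  cfg <- filter_bank_config(2, a = 1, b = 0.5)
  idx_train <- which(seg$info$block != 3)
  idx_test <- which(seg$info$block == 3)[3]
  model <- fbtrca_train(seg$data[, , idx_train],
                        seg$info$target_index[idx_train], cfg, 250)
  got <- fbtrca_classify(seg$data[, , idx_test], model)
  rate <- 250
  expected <- numeric(12)
  for (n in 1:2) {
    flt <- signal::cheby1(4, 0.1, c(8 * n, 90) / (rate / 2), type = "pass")
    xf <- t(apply(seg$data[, , idx_test], 1,
                  function(ch) signal::filtfilt(flt, ch)))
    W <- model$models[[n]]$filters
    w_n <- n^(-1) + 0.5
    for (k in 1:12) {
      r <- stats::cor(as.vector(t(W) %*% xf),
                      as.vector(t(W) %*% model$models[[n]]$templates[, , k]))
      expected[k] <- expected[k] + w_n * sign(r) * r^2
    }
  }
  expect_equal(got$scores, expected, tolerance = 1e-8)
})

test_that("non-ensemble FBTRCA reduces to the per-class single filter", {
  ep <- record_to_epochs(fix_clean_record(), "dry")
  seg <- classification_segment(ep, 0.6)
  cfg <- filter_bank_config(1, a = 0, b = 0)
  train <- which(seg$info$block != 3)
  model <- fbtrca_train(seg$data[, , train],
                        seg$info$target_index[train], cfg, 250)
  x <- seg$data[, , which(seg$info$block == 3)[1]]
  got <- fbtrca_classify(x, model, ensemble = FALSE)
  xf <- ssvepkit::fb_decompose(x, cfg, 250)[[1]]
  for (k in c(1, 6, 12)) {
    wk <- model$models[[1]]$filters[, k]
    r <- stats::cor(as.vector(crossprod(wk, xf)),
                    as.vector(crossprod(wk, model$models[[1]]$templates[, , k])))
    expect_equal(got$features[1, k], r, tolerance = 1e-10)
  }
})

test_that("model/segment length mismatches raise explicit errors", {
  ep <- record_to_epochs(fix_clean_record(), "wet")
  seg <- classification_segment(ep, 1)
  cfg <- filter_bank_config(2)
  model <- fbtrca_train(seg$data, seg$info$target_index, cfg, 250)
  short <- classification_segment(ep, 0.5)
  expect_error(fbtrca_classify(short$data[, , 1], model), "same data length")
  one_block <- ssvep_epochs(ep$data[, , 1:12], 250,
                            info = ep$info[1:12, ])
  expect_error(loo_block_cv(one_block, fix_layout(), "fbtrca"), ">= 2 blocks")
})

test_that("cross-validation folds follow the block structure", {
  ep <- record_to_epochs(fix_clean_record(), "wet")
  res <- loo_block_cv(ep, fix_layout(), "fbcca", data_length = 0.8)
  expect_equal(nrow(res$per_block), 3)
  expect_true(all(res$per_block$n_trials == 12))
  expect_equal(res$accuracy, mean(res$predictions$predicted ==
                                    res$predictions$target_index))
})

test_that("pure-noise decoding sits at chance level", {
  ep <- fix_noise_only_epochs()          # 120 trials, no evoked response
  res <- loo_block_cv(ep, fix_layout(), "fbcca", data_length = 1)
  n <- nrow(res$predictions)
  expect_gte(n, 120)
  band <- stats::qbinom(c(0.005, 0.995), n, 1 / 12) / n
  expect_gte(res$accuracy, band[1])
  expect_lte(res$accuracy, band[2])
})
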