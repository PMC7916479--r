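test_that("AVG projection of identical channels reproduces the waveform", {
  rate <- 250; n <- 250
  t <- (0:(n - 1)) / rate
  s <- sin(2 * pi * 11.25 * t) + 0.3 * sin(2 * pi * 22.5 * t)
  trials <- array(rep(s, each = 8), dim = c(8, n, 2))   # all channels equal
  cfg <- filter_bank_config(1)
  model <- build_et_model(trials, targets = c(1, 1), projection = "avg",
                          config = cfg, sampling_rate = rate)
  # channel averaging of identical channels = any single channel, so the
  # template equals the (band-passed, mean-removed) waveform itself
  filtered <- fb_decompose(trials[, , 1], cfg, rate)[[1]][1, ]
  expect_equal(model$templates[[1]][, 1], filtered - mean(filtered),
               tolerance = 1e-10)
})

test_that("degenerate all-zero training epochs are rejected", {
  trials <- array(0, dim = c(4, 100, 2))
  expect_error(
    build_et_model(trials, c(1, 1), "avg", filter_bank_config(1),
                   sampling_rate = 250),
    "degenerate")
})

test_that("CCA projection yields templates spanned by the class reference", {
  ep <- record_to_epochs(fix_clean_record(), "wet")
  seg <- classification_segment(ep, 1)
  layout <- fix_layout()
  cfg <- filter_bank_config(1)
  model <- build_et_model(seg$data, seg$info$target_index, "cca", cfg,
                          layout, 250)
  refs <- make_references(layout, 5, 250, dim(seg$data)[2])
  for (k in c(1, 5, 12)) {
    rho <- cca_first_correlation(rbind(model$templates[[1]][, k]),
                                 refs$references[[k]])
    expect_gte(rho, 0.99)
  }
})

test_that("a test trial equal to the training mean matches with r1 = 1", {
  ep <- record_to_epochs(fix_clean_record(), "dry")
  seg <- classification_segment(ep, 1)
  layout <- fix_layout()
  cfg <- filter_bank_config(2)
  model <- build_et_model(seg$data, seg$info$target_index, "avg", cfg,
                          layout, 250)
  refs <- make_references(layout, 5, 250, dim(seg$data)[2])
  # noiseless trials are the class means themselves
  i <- which(seg$info$target_index == 4)[1]
  res <- et_classify(seg$data[, , i], model, refs)
  expect_equal(res$predicted, 4)
  r1_own <- res$features$r1[res$features$class == 4]
  expect_true(all(r1_own > 0.999))
})

test_that("a template orthogonal to the test segment gives r1 near 0", {
  rate <- 250; n <- 250
  t <- (0:(n - 1)) / rate
  X <- rbind(sin(2 * pi * 10 * t), sin(2 * pi * 10 * t + 1))
  tau <- cos(2 * pi * 15 * t)           # full cycles: orthogonal to X's span
  v <- ssvepkit:::ls_spatial_filter(X, tau - mean(tau))
  proj <- as.vector(crossprod(v, X - rowMeans(X)))
  expect_lt(abs(stats::cor(proj, tau)), 1e-6)
})

test_that("fused score p is bounded and r1 is scale invariant", {
  rec <- fix_noisy_record()
  ew <- record_to_epochs(rec, "wet")
  ed <- record_to_epochs(rec, "dry")
  layout <- fix_layout()
  cfg <- filter_bank_config(2)
  segw <- classification_segment(ew, 0.6)
  segd <- classification_segment(ed, 0.6)
  model <- build_et_model(segw$data, segw$info$target_index, "avg", cfg,
                          layout, 250)
  refs <- make_references(layout, 5, 250, dim(segd$data)[2])
  x <- segd$data[, , 7]
  res <- et_classify(x, model, refs)
  expect_true(all(res$features$p >= -2 & res$features$p <= 2))
  expect_true(all(abs(res$features$r1) <= 1 & abs(res$features$r2) <= 1))
  res_scaled <- et_classify(3.7 * x, model, refs)
  expect_equal(res_scaled$features$r1, res$features$r1, tolerance = 1e-9)
  expect_equal(res_scaled$scores, res$scores, tolerance = 1e-9)
})

test_that("wet-to-dry and dry-to-wet transfers are symmetric code paths", {
  # equal wet/dry response amplitudes + no noise: the two sessions carry
  # identical signals, so swapping train/test roles must give identical
  # results
  prof <- noiseless_profile(8, amplitudes_dry = c(2.597, 1.262, 0.746, 0.316))
  sess <- simulate_subject(fix_layout(), prof, n_blocks = 2,
                           electrodes = c("wet", "dry"), sampling_rate = 250)
  rec <- session_to_record(sess)
  ew <- record_to_epochs(rec, "wet")
  ed <- record_to_epochs(rec, "dry")
  w2d <- et_evaluate(ew, ed, fix_layout(), "avg", data_length = 0.6)
  d2w <- et_evaluate(ed, ew, fix_layout(), "avg", data_length = 0.6)
  expect_equal(w2d$accuracy, 1.0)
  expect_equal(w2d$predictions$predicted, d2w$predictions$predicted)
})

test_that("ET classification is deterministic and validates lengths", {
  ep <- record_to_epochs(fix_clean_record(), "wet")
  seg <- classification_segment(ep, 0.6)
  cfg <- filter_bank_config(1)
  model <- build_et_model(seg$data, seg$info$target_index, "avg", cfg,
                          fix_layout(), 250)
  refs <- make_references(fix_layout(), 5, 250, dim(seg$data)[2])
  a <- et_classify(seg$data[, , 3], model, refs)
  b <- et_classify(seg$data[, , 3], model, refs)
  expect_identical(a, b)
  expect_error(et_classify(seg$data[, 1:100, 3], model, refs),
               "does not match")
  expect_error(
    build_et_model(seg$data[, , 1:12], seg$info$target_index[1:12], "trca",
                   cfg, fix_layout(), 250),
    ">= 2 training epochs")
})
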