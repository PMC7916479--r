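test_that("ITR reproduces its closed forms and limiting cases", {
  expect_equal(itr(12, 1, 2), 30 * log2(12), tolerance = 1e-12)
  expect_equal(itr(12, 1 / 12, 2), 0, tolerance = 1e-12)
  expect_equal(itr(12, 1 / 12, 0.7), 0, tolerance = 1e-12)
  # independent scalar evaluation at the online wet-electrode accuracy
  p <- 0.83
  bits <- log2(12) + p * log2(p) + (1 - p) * log2((1 - p) / 11)
  expect_equal(itr(12, p, 2), bits * 60 / 2, tolerance = 1e-12)
  expect_equal(itr(12, 0, 1), (log2(12) + log2(1 / 11)) * 60)
})

test_that("ITR is increasing above chance and scales as 1/T", {
  ps <- seq(1 / 12, 1, length.out = 40)
  vals <- itr(12, ps, 2)
  expect_true(all(diff(vals) > 0))
  expect_equal(itr(12, 0.7, 4), itr(12, 0.7, 2) / 2, tolerance = 1e-12)
  expect_error(itr(1, 0.5, 2), ">= 2")
  expect_error(itr(12, 1.2, 2), "\\[0, 1\\]")
  expect_error(itr(12, 0.5, 0), "> 0")
})

test_that("amplitude spectrum maps a full-bin sinusoid to its amplitude", {
  rate <- 250
  t4 <- (0:999) / rate                      # 4 s: 0.25 Hz bins
  spec <- amplitude_spectrum(sin(2 * pi * 11.25 * t4), rate)
  expect_equal(spec$delta_f, 0.25)
  i <- which.min(abs(spec$frequency - 11.25))
  expect_equal(spec$frequency[i], 11.25)
  expect_equal(spec$amplitude[i], 1.0, tolerance = 1e-9)
  expect_lt(max(spec$amplitude[-i]), 1e-9)
  # 2 s window: 0.5 Hz bins, 11.5 Hz on-bin
  t2 <- (0:499) / rate
  spec2 <- amplitude_spectrum(2.5 * sin(2 * pi * 11.5 * t2), rate)
  expect_equal(spec2$delta_f, 0.5)
  expect_equal(spec2$amplitude[which.min(abs(spec2$frequency - 11.5))], 2.5,
               tolerance = 1e-9)
  expect_true(all(amplitude_spectrum(rep(0, 500), rate)$amplitude == 0))
  expect_error(amplitude_spectrum(numeric(0), rate), "empty")
})

test_that("off-bin amplitudes agree with a brute-force DFT oracle", {
  rate <- 250
  t <- (0:499) / rate
  x <- 1.3 * sin(2 * pi * 10.3 * t) + 0.2 * cos(2 * pi * 30 * t)
  spec <- amplitude_spectrum(x, rate)
  n <- length(x)
  for (i in c(10, 21, 42, 61, 121)) {
    f <- spec$frequency[i]
    oracle <- 2 * Mod(sum(x * exp(-2i * pi * f * t))) / n
    expect_equal(spec$amplitude[i], oracle, tolerance = 1e-9)
  }
})

test_that("narrowband SNR follows the printed neighbour-sum formula", {
  flat <- structure(list(frequency = seq(0, 50, by = 0.5),
                         amplitude = rep(2, 101), delta_f = 0.5),
                    class = "spectrum_estimate")
  expect_equal(snr_db(flat, 20), 20 * log10(1 / 10), tolerance = 1e-12)
  peaked <- flat
  peaked$amplitude[flat$frequency == 20] <- 20   # 10x the flat background
  expect_equal(snr_db(peaked, 20), 0, tolerance = 1e-12)
  # scale invariance
  scaled <- peaked
  scaled$amplitude <- scaled$amplitude * 37
  expect_equal(snr_db(scaled, 20), snr_db(peaked, 20), tolerance = 1e-12)
  # the mean-of-neighbours variant differs by the constant 20*log10(10)
  expect_equal(snr_db(peaked, 20, variant = "mean"),
               snr_db(peaked, 20) + 20 * log10(10), tolerance = 1e-12)
  expect_error(snr_db(flat, 1.5), "outside the spectrum")
  expect_error(snr_db(flat, 80), "outside the spectrum range")
})

test_that("epoch SNR matches a direct re-computation on simulated data", {
  prof <- subject_profile(subject_seed = 6, noise_scale = c(wet = 3, dry = 3),
                          alpha_scale = 0)
  f <- 11.25
  eps <- vapply(1:30, function(i)
    simulate_epoch(f, 0, prof, "wet", duration = 2.34, sampling_rate = 250,
                   seed = 3000 + i),
    matrix(0, 8, 585))
  e <- ssvep_epochs(eps, 250, window = c(pre = 0, post = 2.34))
  got <- epoch_snr(e, f)
  # loop-based oracle: average waveform, explicit DFT at f and neighbours
  avg <- rowMeans(eps[6, 36:535, ])               # Oz, [0.14, 2.14) s
  t <- (0:499) / 250
  amp <- function(g) 2 * Mod(sum(avg * exp(-2i * pi * g * t))) / 500
  denom <- sum(vapply(c(-(5:1), 1:5) * 0.5 + f, amp, numeric(1)))
  expect_equal(got, 20 * log10(amp(f) / denom), tolerance = 1e-9)
  expect_gt(got, 0)
})

test_that("grid search covers the full 240-cell grid with exact tie-breaks", {
  ep <- record_to_epochs(fix_clean_record(), "wet")
  gs <- grid_search(ep, fix_layout(), "fbcca")
  expect_equal(nrow(gs$surface), 8 * 5 * 6)
  expect_equal(nrow(dplyr::distinct(gs$surface[c("a", "b", "n_subbands")])),
               240)
  expect_equal(max(gs$surface$accuracy), gs$optimum$accuracy)
  # noiseless data: every cell decodes perfectly; ties resolve to the
  # smallest N, then a, then b
  expect_equal(gs$optimum$accuracy, 1.0)
  expect_equal(gs$optimum$n_subbands, 1)
  expect_equal(gs$optimum$a, 0.25)
  expect_equal(gs$optimum$b, 0)
  # dominance: the maximum is at least the accuracy of any named cell
  cell <- gs$surface[gs$surface$a == 1.25 & gs$surface$b == 0.25 &
                       gs$surface$n_subbands == 3, ]
  expect_gte(gs$optimum$accuracy, cell$accuracy)
  # the optimum reproduces when re-evaluated in isolation
  cfg <- filter_bank_config(gs$optimum$n_subbands, gs$optimum$a, gs$optimum$b)
  res <- loo_block_cv(ep, fix_layout(), "fbcca", config = cfg, data_length = 1)
  expect_equal(res$accuracy, gs$optimum$accuracy)
})

test_that("grid search supports electrode-transfer methods", {
  rec <- fix_clean_record()
  pair <- list(train = record_to_epochs(rec, "wet"),
               test = record_to_epochs(rec, "dry"))
  gs <- grid_search(list(pair), fix_layout(), "et-avg",
                    a_grid = c(0.5, 1), b_grid = 0, n_grid = 1:2,
                    data_length = 0.6)
  expect_equal(nrow(gs$surface), 4)
  expect_equal(gs$optimum$accuracy, 1.0)   # noiseless transfer is perfect
})

test_that("harmonic sweep returns one accuracy per harmonic count", {
  ep <- record_to_epochs(fix_clean_record(), "wet")
  one_block <- ssvep_epochs(ep$data[, , ep$info$block == 1], 250,
                            info = ep$info[ep$info$block == 1, ])
  hs <- harmonic_sweep(one_block, fix_layout(), nh_range = 1:6)
  expect_equal(nrow(hs), 6)
  expect_equal(hs$n_harmonics, 1:6)
  expect_equal(hs$accuracy[1], 1.0)   # noiseless: Nh = 1 already suffices
})

test_that("group statistics handle degenerate and linear relations", {
  perf <- tibble::tibble(
    subject = rep(1:6, 2),
    electrode = rep(c("wet", "dry"), each = 6),
    accuracy = c(0.9, 0.8, 0.7, 0.95, 0.85, 0.75,
                 0.9, 0.8, 0.7, 0.95, 0.85, 0.75))
  gs <- group_stats(perf)
  expect_equal(gs$paired_tests$t[gs$paired_tests$metric == "accuracy"], 0)
  expect_equal(
    gs$difference_groups$proportion[gs$difference_groups$group == "within_10pct"],
    1.0)
  # perfectly linear accuracy-impedance relation gives |r| = 1
  imp <- tibble::tibble(
    subject = rep(1:6, 2),
    electrode = rep(c("wet", "dry"), each = 6),
    impedance = 100 - 50 * perf$accuracy)
  gs2 <- group_stats(perf, imp)
  r_wet <- gs2$correlations$r[
    gs2$correlations$comparison == "accuracy_vs_impedance_wet"]
  expect_equal(r_wet, -1, tolerance = 1e-12)
  expect_error(group_stats(perf[-1, ]), "unpaired")
})

test_that("correlations match the textbook product-moment formula", {
  set.seed(61)
  wet <- runif(10, 0.5, 1)
  dry <- runif(10, 0.3, 0.9)
  perf <- tibble::tibble(subject = rep(1:10, 2),
                         electrode = rep(c("wet", "dry"), each = 10),
                         accuracy = c(wet, dry))
  gs <- group_stats(perf)
  oracle <- sum((wet - mean(wet)) * (dry - mean(dry))) /
    sqrt(sum((wet - mean(wet))^2) * sum((dry - mean(dry))^2))
  expect_equal(
    gs$correlations$r[gs$correlations$comparison == "accuracy_wet_vs_dry"],
    oracle, tolerance = 1e-12)
})

test_that("block trend recovers the least-squares slope", {
  const <- tibble::tibble(block = 1:10, accuracy = rep(0.8, 10))
  expect_equal(block_trend(const)$slope, 0, tolerance = 1e-12)
  rising <- tibble::tibble(block = 1:10, accuracy = seq(0.5, 0.95, 0.05))
  expect_gt(block_trend(rising)$slope, 0)
  # closed-form simple-regression oracle on a fixed table
  tab <- tibble::tibble(block = 1:5, accuracy = c(0.6, 0.7, 0.65, 0.8, 0.75))
  bt <- block_trend(tab)
  x <- tab$block; y <- tab$accuracy
  slope <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  expect_equal(bt$slope, slope, tolerance = 1e-12)
  expect_equal(bt$intercept, mean(y) - slope * mean(x), tolerance = 1e-12)
  expect_error(block_trend(tab[1, ]), ">= 2 blocks")
})

test_that("result objects expose tidy and glance views", {
  ep <- record_to_epochs(fix_clean_record(), "wet")
  res <- loo_block_cv(ep, fix_layout(), "fbcca", data_length = 0.6)
  expect_s3_class(tidy(res), "tbl_df")
  g <- glance(res)
  expect_equal(g$accuracy, res$accuracy)
  expect_equal(g$method, "fbcca")
  tab <- tibble::tibble(block = 1:4, accuracy = c(0.5, 0.6, 0.7, 0.6))
  expect_named(glance(block_trend(tab)),
               c("slope", "intercept", "slope_p_value", "n_blocks"))
  spec <- amplitude_spectrum(sin(2 * pi * 10 * (0:499) / 250), 250)
  td <- tidy(spec)
  expect_equal(names(td), c("frequency", "amplitude"))
  p <- autoplot(spec)
  expect_s3_class(p, "ggplot")
})
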