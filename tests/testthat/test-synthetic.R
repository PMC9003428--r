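noiseless_cfg <- function(seed = 1, ...) {
  sim_config(seed = seed,
             sinusoids = data.frame(freq_hz = numeric(0), sd = numeric(0)),
             drift_sd = 0, white_sd = 0, ...)
}

test_that("the canonical HRF has the expected double-gamma shape", {
  fs <- 10
  h <- canonical_hrf(fs)
  t <- seq(0, 32, by = 1 / fs)
  expect_equal(max(h), 1)
  peak_t <- t[which.max(h)]
  expect_gte(peak_t, 4); expect_lte(peak_t, 7)
  # near-zero at both ends relative to the unit peak
  expect_lt(abs(h[1]), 1e-3)
  expect_lt(abs(h[length(h)]), 1e-3)
  # without the undershoot the kernel is a gamma density: non-negative
  expect_true(all(canonical_hrf(fs, ratio = 0) >= -1e-15))
  expect_error(canonical_hrf(fs, peak_s = 10, undershoot_s = 8), "invalid")
})

test_that("simulated recordings are deterministic and correctly sized", {
  cfg <- sim_config(seed = 12)
  s1 <- simulate_hbo(cfg)
  s2 <- simulate_hbo(cfg)
  expect_identical(s1$rec$values, s2$rec$values)
  expect_equal(ncol(s1$rec$values), floor(360 * 1.81))   # 651 samples
  expect_equal(nrow(s1$rec$values), 12)
  s3 <- simulate_hbo(sim_config(seed = 13))
  expect_false(identical(s1$rec$values, s3$rec$values))
})

test_that("noiseless simulations isolate the evoked response", {
  sim <- simulate_hbo(noiseless_cfg())
  v <- sim$rec$values
  lab <- paradigm_labels(sim$paradigm, sim$rec$fs, ncol(v))
  t <- (0:(ncol(v) - 1)) / sim$rec$fs
  # rest samples before the first task block carry no response
  expect_lt(max(abs(v[2, t < 30])), 1e-12)
  # informative channels respond: task mean above rest mean, peak amplitude 1
  for (ch in c(2, 5, 9)) {
    expect_gt(mean(v[ch, lab == "task"]), mean(v[ch, lab == "rest"]))
    expect_equal(max(v[ch, ]), 1, tolerance = 1e-12)
  }
  # uninformative channels are exactly zero
  expect_true(all(v[-c(2, 5, 9), ] == 0))
})

test_that("response scale is linear in the configured amplitude", {
  r1 <- simulate_hbo(noiseless_cfg(amplitude_uM = 1))$rec$values[2, ]
  r2 <- simulate_hbo(noiseless_cfg(amplitude_uM = 2))$rec$values[2, ]
  expect_equal(r2, 2 * r1, tolerance = 1e-12)
  # with noise, the task-rest contrast still grows with amplitude
  contrasts <- sapply(c(0.5, 1, 2, 4), function(a) {
    mean(sapply(1:10, function(s) {
      sim <- simulate_hbo(sim_config(seed = s, amplitude_uM = a, snr = a))
      lab <- paradigm_labels(sim$paradigm, sim$rec$fs, ncol(sim$rec$values))
      mean(sim$rec$values[2, lab == "task"]) -
        mean(sim$rec$values[2, lab == "rest"])
    }))
  })
  expect_true(all(diff(contrasts) > 0))
  # ~linear growth: ratio of slope ends within 25% of proportionality
  expect_equal(contrasts[4] / contrasts[1], 8, tolerance = 0.25)
})

test_that("the configured SNR controls the noise floor", {
  for (snr in c(0.5, 2)) {
    sims <- sapply(1:10, function(s) {
      sd(simulate_hbo(sim_config(seed = s, snr = snr))$rec$values[1, ])
    })
    # channel 1 is noise-only: sd should track amplitude/snr
    expect_equal(mean(sims), 1 / snr, tolerance = 0.25)
  }
})

test_that("uninformative channels pass a label-permutation test", {
  n_pass <- 0
  n_seeds <- 25
  for (s in 1:n_seeds) {
    sim <- simulate_hbo(sim_config(seed = 200 + s))
    lab <- paradigm_labels(sim$paradigm, sim$rec$fs, ncol(sim$rec$values))
    keep <- lab != "baseline"
    x <- sim$rec$values[4, keep]           # an uninformative channel
    is_task <- lab[keep] == "task"
    obs <- abs(mean(x[is_task]) - mean(x[!is_task]))
    set.seed(s)
    null <- replicate(199, {
      p <- sample(is_task)
      abs(mean(x[p]) - mean(x[!p]))
    })
    if (mean(c(null, obs) >= obs) > 0.05) n_pass <- n_pass + 1
  }
  expect_gte(n_pass / n_seeds, 0.9)
})

test_that("raw optical density round-trips to the HbO ground truth", {
  prm <- mbll_params()
  sim <- simulate_raw_od(noiseless_cfg(), prm)
  rec <- mbll_inverse(sim$od, prm)$hbo
  expect_lt(max(abs(rec$values - sim$hbo_truth$values)), 1e-8)
  # zero amplitude leaves only (transformed) noise
  sim0 <- simulate_raw_od(noiseless_cfg(amplitude_uM = 0))
  expect_true(all(sim0$od$values == 0))
  # doubling amplitude doubles the recovered response
  sA <- simulate_raw_od(noiseless_cfg(amplitude_uM = 1), prm)
  sB <- simulate_raw_od(noiseless_cfg(amplitude_uM = 2), prm)
  hA <- mbll_inverse(sA$od, prm)$hbo$values
  hB <- mbll_inverse(sB$od, prm)$hbo$values
  expect_equal(hB, 2 * hA, tolerance = 1e-8)
})

test_that("cohorts are reproducible with subject-level variation", {
  c1 <- generate_cohort(9, sim_config(), seed = 5)
  c2 <- generate_cohort(9, sim_config(), seed = 5)
  expect_length(c1, 9)
  for (s in 1:9)
    expect_identical(c1[[s]]$rec$values, c2[[s]]$rec$values)
  # subjects differ from one another
  expect_false(identical(c1[[1]]$rec$values, c1[[2]]$rec$values))
  # jitter off: everyone shares the informative set
  expect_true(all(vapply(c1, function(s)
    identical(s$informative, c(2L, 5L, 9L)), logical(1))))
  # a different master seed changes at least one recording
  c3 <- generate_cohort(9, sim_config(), seed = 6)
  expect_false(identical(c1[[1]]$rec$values, c3[[1]]$rec$values))
  # jitter on: informative sets vary but keep size 3
  c4 <- generate_cohort(9, sim_config(), seed = 5, jitter_informative = TRUE)
  sets <- lapply(c4, `[[`, "informative")
  expect_true(all(lengths(sets) == 3))
  expect_gt(length(unique(sets)), 1)
})
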