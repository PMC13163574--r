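test_that("phantoms are bit-reproducible under a fixed seed", {
  a <- make_phantom(phantom_spec("active", n_cycles = 1, seed = 42))
  b <- make_phantom(phantom_spec("active", n_cycles = 1, seed = 42))
  expect_identical(a$seq$frames, b$seq$frames)
  expect_identical(a$seq$ecg$samples, b$seq$ecg$samples)
  c <- make_phantom(phantom_spec("active", n_cycles = 1, seed = 43))
  expect_false(identical(a$seq$frames, c$seq$frames))
})

test_that("an all-static noise-free phantom has identical frames and empty truth", {
  sp <- phantom_spec("custom", shape = c(40L, 40L), n_cycles = 1,
                     noise_sd = 0, seed = 3,
                     regimes = list(phantom_region(
                       geometry = list(type = "disc", cx = 20, cy = 20, r = 10),
                       motion = "static", grain = 2, contrast = 80)))
  ph <- make_phantom(sp)
  for (i in seq_along(ph$seq$frames)[-1]) {
    expect_identical(ph$seq$frames[[i]], ph$seq$frames[[1]])
  }
  expect_true(all(!vapply(ph$truth$moved, any, logical(1))))
})

test_that("a translating flat patch moves exactly its footprint symmetric difference", {
  H <- W <- 100
  sp <- phantom_spec("custom", shape = c(H, W), frame_rate = 85, n_cycles = 1,
                     cycle_period = 0.8, noise_sd = 0, seed = 5,
                     regimes = list(phantom_region(
                       geometry = list(type = "rect", x0 = 10, y0 = 35,
                                       w = 30, h = 30),
                       motion = "translate", v = c(1, 0), duty = 0.4,
                       grain = 0, mean = 100)))
  ph <- make_phantom(sp)
  fpc <- ph$truth$frames_per_cycle
  # geometry oracle: footprint at frame f is the rect shifted by its
  # accumulated integer displacement; moved mask = symmetric difference
  foot <- function(f) {
    steps <- min((f - 1) %% fpc, floor(0.4 * fpc))
    m <- matrix(FALSE, H, W)
    m[36:65, (11 + steps):(40 + steps)] <- TRUE
    m
  }
  for (i in c(1, 5, 10, 20)) {
    oracle <- xor(foot(i), foot(i + 1))
    expect_identical(ph$truth$moved[[i]], oracle)
    expect_equal(sum(ph$truth$moved[[i]]),
                 if (sum(oracle) > 0) 2 * 30 else 0)
  }
  # the pipeline's BMF(0) equals the truth moved fraction exactly (no noise)
  s <- index_series(ph$seq, cutoffs = 0)
  truth_frac <- vapply(ph$truth$moved, function(m) 100 * sum(m) / (H * W),
                       numeric(1))
  expect_equal(s$bmf_0, truth_frac)
})

test_that("the synthetic ECG carries truth peaks recoverable by detection", {
  g <- make_ecg(1, 3, sample_rate = 250)
  expect_length(g$peaks, 3)
  expect_equal(g$peaks, c(0, 1, 2))
  p <- detect_r_peaks(g$trace)
  expect_length(p, 3)
  expect_lt(max(abs(p - g$peaks)), 0.020)
  # determinism
  g2 <- make_ecg(1, 3, sample_rate = 250)
  expect_identical(g$trace$samples, g2$trace$samples)
})

test_that("phantom regions outside the frame are rejected", {
  expect_error(phantom_spec("custom", shape = c(40L, 40L),
                            regimes = list(phantom_region(
                              geometry = list(type = "disc", cx = 38, cy = 20,
                                              r = 10),
                              motion = "static"))),
               "outside")
})

test_that("active phantoms out-range stale phantoms at the 200-px cutoff", {
  a <- index_series(make_phantom(phantom_spec("active", n_cycles = 2,
                                              seed = 1))$seq, cutoffs = 200)
  s <- index_series(make_phantom(phantom_spec("stale", n_cycles = 2,
                                              seed = 1))$seq, cutoffs = 200)
  expect_gt(max(a$bmf_200), max(s$bmf_200))
  expect_gt(max(a$bmf_200) - min(a$bmf_200),
            max(s$bmf_200) - min(s$bmf_200))
})

test_that("respiratory modulation raises cycle-average SD but keeps the mean", {
  run <- function(resp) {
    sp <- phantom_spec("active", n_cycles = 4, noise_sd = 0, seed = 2,
                       respiration = resp)
    ph <- make_phantom(sp)
    s <- index_series(ph$seq, cutoffs = 200)
    # skip the first cycle: it lacks the position-reset frame at its onset
    # and so is not one of the identical steady-state cycles
    cyc <- segment_cycles(ph$truth$r_peaks[-1], s, n_cycles = 3)
    cycle_average(s, cyc, value = "bmf_200", n_bins = 25)
  }
  base <- run(NULL)
  resp <- run(list(period = 2.7, amplitude = 0.15))
  expect_lt(max(base$sd), 1e-9)                 # perfectly periodic
  expect_gt(max(resp$sd), max(base$sd))         # modulation adds variance
  # per-bin means stay close to the unmodulated profile
  expect_lt(max(abs(resp$mean - base$mean)),
            0.25 * max(base$mean) + 1e-9)
})
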