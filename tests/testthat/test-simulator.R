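test_that("empty scene renders a constant frame at background level", {
  cfg <- tiny_sim_config(background_level = 0.6)
  fr <- render_frame(cfg, empty_layout())
  expect_equal(dim(fr), c(32, 32))
  expect_true(all(fr == 0.6))
})

test_that("silhouettes darken the frame by about the configured contrast", {
  cfg <- tiny_sim_config(background_level = 0.7, silhouette_contrast = 0.4)
  fr <- render_frame(cfg, cell_layout(x = 16, y = 16, r = 4))
  # center pixel fully covered -> background minus contrast
  expect_equal(fr[16, 16], 0.3, tolerance = 1e-8)
  # far corner untouched
  expect_equal(fr[2, 2], 0.7)
  expect_true(all(fr >= 0 & fr <= 1))
})

test_that("degenerate dispersion yields identical cell radii", {
  cfg <- tiny_sim_config(cell_density = 0.02, cell_radius_mean = 3,
                         cell_radius_sd = 0, cell_eccentricity_sd = 0,
                         seed = 5)
  sim <- simulate_sequence(cfg, grade_profile("low"))
  cells <- sim$annotation$frames[[1]]$cells
  expect_gt(nrow(cells), 0)
  expect_true(all(cells$radius == 3))
})

test_that("per-frame silhouette counts are Poisson-calibrated", {
  lambda <- 0.004 * 64^2 # expected count per frame
  n_rep <- 200
  counts <- vapply(seq_len(n_rep), function(i) {
    cfg <- simulator_config(frame_size = 64, n_frames = 1,
                            cell_density = 0.004, background_noise_sd = 0,
                            motion_artifact_prob = 0, seed = 1000 + i)
    sim <- simulate_sequence(cfg, grade_profile("low"))
    nrow(sim$annotation$frames[[1]]$cells)
  }, numeric(1))
  se <- sqrt(lambda / n_rep)
  expect_lt(abs(mean(counts) - lambda), 3 * se)
})

test_that("a static noiseless scene renders identical frames", {
  cfg <- tiny_sim_config(cell_density = 0.01, rbc_density = 0.01,
                         rbc_flow_velocity = 0, seed = 11)
  sim <- simulate_sequence(cfg, grade_profile("low"))
  for (t in 2:4) {
    expect_identical(sim$sequence$frames[[t]], sim$sequence$frames[[1]])
  }
})

test_that("RBC field translation matches the annotated velocity (xcorr oracle)", {
  cfg <- simulator_config(frame_size = 48, n_frames = 2, cell_density = 0,
                          rbc_density = 0.01, rbc_flow_velocity = 3,
                          background_noise_sd = 0, motion_artifact_prob = 0,
                          seed = 23)
  sim <- simulate_sequence(cfg, grade_profile("low"))
  v <- sim$annotation$velocity
  f1 <- sim$sequence$frames[[1]]
  f2 <- sim$sequence$frames[[2]]
  # brute-force toroidal cross-correlation over candidate shifts
  best <- c(NA, NA); best_val <- -Inf
  shift_frame <- function(m, dr, dc) {
    n <- nrow(m)
    m[((seq_len(n) - 1 - dr) %% n) + 1, ((seq_len(n) - 1 - dc) %% n) + 1]
  }
  for (dr in -6:6) {
    for (dc in -6:6) {
      val <- sum(shift_frame(f1, dr, dc) * f2)
      if (val > best_val) { best_val <- val; best <- c(dr, dc) }
    }
  }
  # layout x = column, y = row; allow 1 px for anti-aliased subpixel motion
  expect_lt(abs(best[1] - v[2]), 1.01)
  expect_lt(abs(best[2] - v[1]), 1.01)
})

test_that("artifact flagging frequency matches its probability", {
  cfg <- simulator_config(frame_size = 32, n_frames = 400, cell_density = 0,
                          background_noise_sd = 0, motion_artifact_prob = 0.5,
                          seed = 31)
  sim <- simulate_sequence(cfg, grade_profile("low"))
  frac <- mean(sim$annotation$artifact)
  se <- sqrt(0.5 * 0.5 / 400)
  expect_lt(abs(frac - 0.5), 3 * se)
})

test_that("blurred frames differ from pristine renders and are flagged", {
  cfg <- tiny_sim_config(cell_density = 0.02, motion_artifact_prob = 1,
                         seed = 4)
  cfg0 <- tiny_sim_config(cell_density = 0.02, motion_artifact_prob = 0,
                          seed = 4)
  simb <- simulate_sequence(cfg, grade_profile("low"))
  sim0 <- simulate_sequence(cfg0, grade_profile("low"))
  expect_true(all(simb$annotation$artifact))
  expect_false(any(sim0$annotation$artifact))
})

test_that("simulation is bit-exactly deterministic in (config, seed)", {
  cfg <- tiny_sim_config(cell_density = 0.01, rbc_density = 0.005,
                         background_noise_sd = 0.02,
                         motion_artifact_prob = 0.5, seed = 77)
  a <- simulate_sequence(cfg, cle_profiles("separated")$high)
  b <- simulate_sequence(cfg, cle_profiles("separated")$high)
  expect_identical(a$sequence$frames, b$sequence$frames)
  expect_identical(a$annotation, b$annotation)
})

test_that("tumor-cell and RBC counts are conserved across frames", {
  cfg <- tiny_sim_config(cell_density = 0.015, rbc_density = 0.01,
                         rbc_flow_velocity = 5, seed = 13)
  sim <- simulate_sequence(cfg, grade_profile("low"))
  cell_counts <- vapply(sim$annotation$frames,
                        function(fr) nrow(fr$cells), numeric(1))
  rbc_counts <- vapply(sim$annotation$frames,
                       function(fr) nrow(fr$rbc), numeric(1))
  expect_true(all(cell_counts == cell_counts[1]))
  expect_true(all(rbc_counts == rbc_counts[1])) # toroidal wrap conserves
})

test_that("grade profiles may not override bookkeeping fields", {
  expect_error(grade_profile("high", list(seed = 3)), "may not touch")
  expect_error(grade_profile("high", list(n_frames = 3)), "may not touch")
  expect_error(grade_profile("high", list(nonsense = 1)), "unknown")
})

test_that("generate_dataset respects case counts, balance and grouping", {
  ds <- generate_dataset(16, 2, class_balance = 0.5,
                         config = tiny_sim_config(), seed = 3)
  cases <- ds$manifest[!duplicated(ds$manifest$case_id), ]
  expect_equal(sum(cases$label == "high"), 8)
  expect_equal(sum(cases$label == "low"), 8)
  expect_equal(nrow(ds$manifest), 32)
  # a case is wholly one grade
  per_case <- tapply(ds$manifest$label, ds$manifest$case_id,
                     function(l) length(unique(l)))
  expect_true(all(per_case == 1))

  minimal <- generate_dataset(2, 1, config = tiny_sim_config(), seed = 1)
  expect_equal(nrow(minimal$manifest), 2)
  expect_equal(length(unique(minimal$manifest$case_id)), 2)

  expect_error(generate_dataset(3, 1, class_balance = 0.01,
                                config = tiny_sim_config()),
               "zero cases")
})

test_that("dataset generation is reproducible and seed-sensitive", {
  a <- generate_dataset(2, 2, config = tiny_sim_config(), seed = 5)
  b <- generate_dataset(2, 2, config = tiny_sim_config(), seed = 5)
  c <- generate_dataset(2, 2, config = tiny_sim_config(), seed = 6)
  expect_identical(a$sequences, b$sequences)
  expect_identical(a$manifest, b$manifest)
  expect_false(identical(a$sequences, c$sequences))
})

test_that("written datasets are byte-identical across writes and round-trip", {
  ds <- generate_dataset(2, 1, config = tiny_sim_config(background_noise_sd = 0.02),
                         seed = 9)
  d1 <- file.path(tempdir(), "cleds1"); d2 <- file.path(tempdir(), "cleds2")
  unlink(c(d1, d2), recursive = TRUE)
  write_cle_dataset(ds, d1)
  write_cle_dataset(ds, d2)
  f1 <- list.files(d1, recursive = TRUE)
  expect_identical(f1, list.files(d2, recursive = TRUE))
  for (f in f1) {
    expect_identical(readBin(file.path(d1, f), "raw", file.size(file.path(d1, f))),
                     readBin(file.path(d2, f), "raw", file.size(file.path(d2, f))))
  }
  back <- read_cle_dataset(d1)
  expect_equal(back$manifest$sequence_id, ds$manifest$sequence_id)
  expect_equal(back$manifest$label, ds$manifest$label)
  # 8-bit quantization round-trip: within half a quantization step
  orig <- ds$sequences[[1]]$frames[[1]]
  expect_lt(max(abs(back$sequences[[1]]$frames[[1]] - orig)), 0.5 / 255 + 1e-9)
})

test_that("matched profiles leave a mean-intensity probe at chance", {
  ds <- generate_dataset(200, 2, class_balance = 0.5,
                         config = simulator_config(frame_size = 32, n_frames = 1,
                                                   cell_density = 0.008,
                                                   background_noise_sd = 0.02),
                         profiles = cle_profiles("matched"), seed = 1)
  mi <- vapply(ds$sequences, function(sq) mean(sq$frames[[1]]), numeric(1))
  lab <- ds$manifest$label
  cen_high <- mean(mi[lab == "high"]); cen_low <- mean(mi[lab == "low"])
  pred <- ifelse(abs(mi - cen_high) < abs(mi - cen_low), "high", "low")
  acc <- 100 * mean(pred == lab)
  expect_lt(abs(acc - 50), 5)
})

test_that("RBC-confound preset hides the class from per-frame density", {
  ds <- generate_dataset(50, 2, class_balance = 0.5,
                         config = simulator_config(frame_size = 64, n_frames = 6),
                         profiles = cle_profiles("rbc_confound"), seed = 2)
  # per-sequence mean silhouette count (tumor cells + RBCs together)
  counts <- vapply(names(ds$sequences), function(sid) {
    mean(vapply(ds$annotations[[sid]]$frames,
                function(fr) nrow(fr$cells) + nrow(fr$rbc), numeric(1)))
  }, numeric(1))
  lab <- factor(ds$manifest$label)
  fit <- suppressWarnings(stats::glm(lab ~ counts, family = stats::binomial()))
  pred <- ifelse(stats::predict(fit, type = "response") > 0.5,
                 levels(lab)[2], levels(lab)[1])
  acc <- 100 * mean(pred == as.character(lab))
  expect_lte(acc, 60)
})
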