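test_that("signal generator is deterministic for a fixed seed and leaves the RNG alone", {
  p <- signal_params(seed = 99)
  set.seed(1); before <- rnorm(1)
  r1 <- simulate_tremor_signal(p)
  r2 <- simulate_tremor_signal(p)
  expect_identical(r1$samples, r2$samples)
  set.seed(1)
  expect_identical(rnorm(1), before)  # generator restored global RNG state

  r3 <- simulate_tremor_signal(signal_params(seed = 100))
  expect_false(identical(r1$samples, r3$samples))
})

test_that("generator rejects bands outside the Nyquist range", {
  expect_error(signal_params(bands = tibble::tibble(center_hz = 150, bandwidth_hz = 1,
                                                    log_gain = 1)),
               "Nyquist|inside")
  expect_error(signal_params(bands = tibble::tibble(center_hz = 10, bandwidth_hz = -1,
                                                    log_gain = 1)),
               "positive")
})

test_that("zero band gains give a white floor whose variance matches the target", {
  p0 <- signal_params(bands = tibble::tibble(center_hz = numeric(), bandwidth_hz = numeric(),
                                             log_gain = numeric()),
                      floor_log_level = 0, seed = 5)
  # integral of flat density exp(0) over (0, 100] Hz -> variance 100
  vars <- vapply(1:30, function(s) {
    p <- signal_params(bands = p0$bands, floor_log_level = 0, seed = s)
    var(simulate_tremor_signal(p)$samples)
  }, 1)
  expect_equal(mean(vars), 100, tolerance = 0.05)
})

test_that("a narrow band centered at 11.5 Hz is recovered by the pipeline centroid", {
  f_hat <- vapply(1:50, function(s) {
    p <- signal_params(
      bands = tibble::tibble(center_hz = 11.5, bandwidth_hz = 0.8, log_gain = 6),
      floor_log_level = -2, seed = s
    )
    rec <- simulate_tremor_signal(p)
    compute_indices(rec)$F[2]
  }, 1)
  expect_equal(mean(f_hat), 11.5, tolerance = 0.2)
})

test_that("generator ground truth matches the analytic spectrum's discrete indices", {
  p <- signal_params(seed = 3)
  rec <- simulate_tremor_signal(p)
  truth <- attr(rec, "truth")
  grid <- (0:512) * 200 / 1024
  idx <- setdiff(which(grid >= 2 - 1e-9 & grid <= 5 + 1e-9), 1L)
  s <- target_psd(p, grid[idx])
  expect_equal(truth$L_true[truth$band == "2_5"], mean(log(s)), tolerance = 1e-12)
  expect_equal(truth$F_true[truth$band == "2_5"], sum(grid[idx] * s) / sum(s),
               tolerance = 1e-12)
  expect_true(all(truth$F_true >= c(2, 9) & truth$F_true <= c(5, 14)))
})

test_that("cohort generator is seeded, balanced, and degenerate at correlation 1", {
  d <- cohort_design(seed = 8)
  t1 <- simulate_cohort(d)
  t2 <- simulate_cohort(d)
  expect_identical(as.data.frame(t1), as.data.frame(t2))
  counts <- dplyr::count(t1, condition, limb, band)
  expect_true(all(counts$n == 19L))
  expect_equal(nrow(t1), 19 * 3 * 2 * 2)

  perfect <- simulate_cohort(cohort_design(interlimb_correlation = 1, seed = 9))
  wide <- tidyr::pivot_wider(perfect, names_from = limb, values_from = c(L, F))
  expect_equal(wide$L_left, wide$L_right, tolerance = 1e-12)
  expect_equal(wide$F_left, wide$F_right, tolerance = 1e-12)
})

test_that("large cohorts reproduce the design cell means", {
  big <- simulate_cohort(cohort_design(n_subjects = 2000L, seed = 10))
  eff <- default_cohort_effects()
  means <- big |>
    dplyr::group_by(band, condition) |>
    dplyr::summarise(L = mean(L), F = mean(F), .groups = "drop")
  for (r in seq_len(nrow(eff))) {
    e <- eff[r, ]
    for (cond in c("rest", "endurance", "sprint")) {
      want <- e$rest_mean + switch(cond, rest = 0,
                                   endurance = e$effect_endurance,
                                   sprint = e$effect_sprint)
      got <- means[[e$dv]][means$band == e$band & means$condition == cond]
      expect_equal(got, want, tolerance = 0.05)
    }
  }
})

test_that("subject random effects are exported and actually used", {
  tab <- simulate_cohort(cohort_design(seed = 11))
  se <- attr(tab, "subject_effects")
  expect_identical(sort(unique(se$subject_id)), sort(unique(tab$subject_id)))
  # subject means of L(2_5) over all six cells should track the drawn effects
  obs <- tab |>
    dplyr::filter(band == "2_5") |>
    dplyr::group_by(subject_id) |>
    dplyr::summarise(m = mean(L), .groups = "drop")
  drawn <- dplyr::filter(se, band == "2_5", dv == "L")
  expect_gt(stats::cor(obs$m, drawn$subject_effect[match(obs$subject_id, drawn$subject_id)]),
            0.8)
})

test_that("fixture sets regenerate byte-identically and agree with the pipeline", {
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  m1 <- make_fixture_set(dir1, seeds = c(7L, 8L), n_samples = 6144L)
  m2 <- make_fixture_set(dir2, seeds = c(7L, 8L), n_samples = 6144L)
  files <- list.files(dir1)
  expect_identical(sort(files), sort(list.files(dir2)))
  for (f in files) {
    expect_identical(readLines(file.path(dir1, f)), readLines(file.path(dir2, f)))
  }
  expect_identical(m1$filename, c("fixture_01.acc.tsv", "fixture_02.acc.tsv"))

  # expected indices in the manifest match recomputation from the files
  rec <- read_recording(file.path(dir1, "fixture_01.acc.tsv"), strict = TRUE)
  idx <- compute_indices(rec)
  expect_equal(idx$L[idx$band == "2_5"], m1$expected_L_2_5[1], tolerance = 1e-9)
  expect_equal(idx$F[idx$band == "9_14"], m1$expected_F_9_14[1], tolerance = 1e-9)
})
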