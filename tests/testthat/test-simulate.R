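test_that("config validation rejects degenerate designs", {
  expect_error(sim_config(n_subjects = 1), "counts")
  expect_error(sim_config(ar1_coef = 1), "ar1_coef")
  expect_error(sim_config(sigma_between = -0.1), ">= 0")
})

test_that("same seed and config give bit-identical output", {
  cfg <- sim_config(3, 2, 50, 6, seed = 42)
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  expect_identical(s1, s2)
  s3 <- simulate_study(sim_config(3, 2, 50, 6, seed = 43))
  expect_false(identical(s1$ts[[1]], s3$ts[[1]]))
})

test_that("output has the configured shape and no missing values", {
  cfg <- sim_config(4, 3, 40, 7, seed = 5)
  st <- simulate_study(cfg)
  expect_equal(nrow(st), 12)
  expect_true(all(vapply(st$ts, function(x) all(is.finite(x)), logical(1))))
  expect_true(all(vapply(st$ts, ncol, integer(1)) == 7))
  expect_true(all(vapply(st$ts, nrow, integer(1)) == 40))
})

test_that("nearest-correlation repair returns symmetric PSD unit-diagonal matrices", {
  set.seed(1)
  for (i in 1:20) {
    s <- matrix(rnorm(36), 6, 6)
    s <- (s + t(s)) / 2
    diag(s) <- 1
    r <- nearest_correlation(s)
    expect_equal(r, t(r))
    expect_equal(unname(diag(r)), rep(1, 6))
    expect_gte(min(eigen(r, symmetric = TRUE, only.values = TRUE)$values), -1e-10)
  }
})

test_that("without variance components all sessions converge to one population matrix", {
  cfg <- sim_config(3, 2, 4000, 6,
    sigma_between = 0, sigma_within = 0, global_amplitude = 0, seed = 11
  )
  st <- simulate_study(cfg)
  cors <- purrr::map(st$ts, cor)
  ref <- cors[[1]]
  for (m in cors[-1]) {
    expect_lt(max(abs(m - ref)), 0.12) # sampling error only at T = 4000
  }
})

test_that("edgewise reliability of generated z-values matches the variance-component prediction", {
  cfg <- sim_config(12, 3, 2000, 6,
    base_connectivity = 0, sigma_edge = 0, anticorr_strength = 0,
    sigma_between = 0.3, sigma_within = 0.05,
    global_amplitude = 0, ar1_coef = 0, seed = 21
  )
  st <- simulate_study(cfg)
  z <- purrr::map(st$ts, function(x) atanh(cor(x)[upper.tri(cor(x))]))
  # empirical sampling variance from within-session split halves
  half_var <- purrr::map_dbl(st$ts, function(x) {
    t_half <- nrow(x) %/% 2
    z1 <- atanh(cor(x[seq_len(t_half), ])[upper.tri(diag(ncol(x)))])
    z2 <- atanh(cor(x[(t_half + 1):nrow(x), ])[upper.tri(diag(ncol(x)))])
    mean(((z1 - z2) / 2)^2)
  })
  # var((z1 - z2)/2) = 1/(T - 6), matching the full-series z variance 1/(T - 3)
  v_samp <- mean(half_var)
  pred <- cfg$sigma_between^2 /
    (cfg$sigma_between^2 + cfg$sigma_within^2 + v_samp)
  zmat <- do.call(rbind, z) # (subject x session) rows, edges as columns
  iccs <- vapply(seq_len(ncol(zmat)), function(e) {
    icc_a1(matrix(zmat[, e], nrow = cfg$n_subjects, byrow = TRUE))$icc_raw
  }, numeric(1))
  expect_lt(abs(mean(iccs) - pred), 0.1)
  expect_gt(pred, 0.85) # regime check: trait variance dominates
})

test_that("mean edgewise reliability increases with between-subject variance", {
  mean_icc <- function(sb) {
    cfg <- sim_config(10, 3, 600, 6,
      base_connectivity = 0, sigma_edge = 0, anticorr_strength = 0,
      sigma_between = sb, sigma_within = 0.1,
      global_amplitude = 0, ar1_coef = 0, seed = 31
    )
    st <- simulate_study(cfg)
    z <- do.call(rbind, purrr::map(st$ts, function(x) atanh(cor(x)[upper.tri(cor(x))])))
    mean(vapply(seq_len(ncol(z)), function(e) {
      icc_a1(matrix(z[, e], nrow = 10, byrow = TRUE))$icc_raw
    }, numeric(1)))
  }
  iccs <- vapply(c(0.05, 0.15, 0.4), mean_icc, numeric(1))
  expect_true(all(diff(iccs) > 0))
})

test_that("a shared global signal inflates the first principal component", {
  base <- sim_config(2, 2, 300, 10, global_amplitude = 0, seed = 8)
  with_g <- sim_config(2, 2, 300, 10, global_amplitude = 0.8, seed = 8)
  pc1_frac <- function(x) {
    ev <- eigen(cov(x), symmetric = TRUE, only.values = TRUE)$values
    ev[1] / sum(ev)
  }
  f0 <- purrr::map_dbl(simulate_study(base)$ts, pc1_frac)
  f1 <- purrr::map_dbl(simulate_study(with_g)$ts, pc1_frac)
  expect_true(all(f1 > f0))
})

test_that("study round-trips through the TSV writer", {
  cfg <- sim_config(3, 2, 30, 5, seed = 2)
  st <- simulate_study(cfg)
  dir <- withr::local_tempdir()
  manifest <- write_study(st, dir, config = cfg)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  expect_true(file.exists(file.path(dir, "config.yaml")))
  expect_setequal(basename(manifest$path), c(
    outer(sprintf("sub-sub%02d", 1:3), sprintf("ses-ses%d", 1:2),
      function(a, b) paste0(a, "_", b, "_roits.tsv")
    )
  ))
  back <- read_study(dir)
  expect_equal(back$subject, st$subject)
  for (i in seq_len(nrow(st))) {
    expect_equal(unname(back$ts[[i]]), unname(st$ts[[i]]), tolerance = 1e-10)
  }
})
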