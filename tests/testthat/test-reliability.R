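sim_table <- function(n, k, sb, sr, se, seed) {
  set.seed(seed)
  outer(rnorm(n, sd = sb), rep(1, k)) +
    outer(rep(1, n), rnorm(k, sd = sr)) +
    matrix(rnorm(n * k, sd = se), n, k) + 10
}

test_that("threshold averaging is the plain mean of clamped ICCs", {
  expect_equal(threshold_averaged_icc(rep(0.42, 5)), 0.42)
  expect_equal(threshold_averaged_icc(seq(0.1, 0.5, 0.1)), 0.3)
  fits <- purrr::map(1:3, function(i) icc_a1(sim_table(8, 3, 1, 0.2, 0.5, i)))
  expect_equal(
    threshold_averaged_icc(fits),
    mean(purrr::map_dbl(fits, "icc"))
  )
})

test_that("pairwise-visit ICC restricts the table to two sessions", {
  m <- sim_table(6, 3, 1, 0.1, 0.4, 5)
  colnames(m) <- paste0("ses", 1:3)
  fit <- pairwise_visit_icc(m, c("ses1", "ses3"))
  expect_equal(fit$k, 2)
  expect_equal(fit$icc_raw, icc_a1(m[, c(1, 3)])$icc_raw)
  expect_error(pairwise_visit_icc(m, c("ses1", "ses9")), "present")
  identical_two <- cbind(1:5, 1:5)
  expect_equal(pairwise_visit_icc(identical_two, c(1, 2))$icc, 1)
})

test_that("k = 2 ICC equals the general sums-of-squares formula", {
  m <- matrix(c(1, 2, 2, 4, 3, 3, 5, 4), 4, 2, byrow = TRUE)
  expect_equal(icc_a1(m)$icc_raw, oracle_icc_a1(m), tolerance = 1e-12)
})

test_that("under exchangeable sessions all three visit pairs converge", {
  m <- sim_table(400, 3, 1, 0, 0.8, 6) # no session effect, large n
  iccs <- c(
    pairwise_visit_icc(m, c(1, 2))$icc_raw,
    pairwise_visit_icc(m, c(1, 3))$icc_raw,
    pairwise_visit_icc(m, c(2, 3))$icc_raw
  )
  expect_lt(max(iccs) - min(iccs), 0.08)
  expect_lt(abs(mean(iccs) - 1 / (1 + 0.8^2)), 0.06)
})

test_that("one all-inclusive group reproduces the full-sample ICC", {
  m <- sim_table(8, 3, 1, 0.1, 0.5, 7)
  rownames(m) <- paste0("s", 1:8)
  grouping <- setNames(rep("all", 8), rownames(m))
  out <- subgroup_reliability(m, grouping)
  expect_equal(nrow(out), 1)
  expect_equal(out$icc_raw, icc_a1(m)$icc_raw)
})

test_that("identical half-samples give identical subgroup ICCs", {
  half <- sim_table(4, 3, 1, 0.1, 0.5, 8)
  m <- rbind(half, half)
  rownames(m) <- paste0("s", 1:8)
  grouping <- setNames(rep(c("g1", "g2"), each = 4), rownames(m))
  out <- subgroup_reliability(m, grouping)
  expect_equal(out$icc_raw[1], out$icc_raw[2])
  expect_error(
    subgroup_reliability(m, setNames(c("solo", rep("rest", 7)), rownames(m))),
    "fewer than 2"
  )
})

test_that("a median split of 16 subjects yields two groups of 8", {
  set.seed(9)
  ages <- setNames(runif(16, 22, 50), sprintf("sub%02d", 1:16))
  split <- median_split(ages)
  expect_equal(unname(table(split)["low"]), 8L)
  expect_equal(unname(table(split)["high"]), 8L)
  expect_true(max(ages[split == "low"]) <= min(ages[split == "high"]))
})

test_that("global reliability table covers every cell with a mean row", {
  set.seed(11)
  tbl <- tidyr::expand_grid(
    method = c("BG90", "WG90"),
    metric = c("Cp", "Lp"),
    density = c(0.15, 0.20),
    subject = sprintf("s%d", 1:6),
    session = sprintf("v%d", 1:3)
  )
  tbl$value <- rnorm(nrow(tbl), mean = 5)
  rel <- reliability_global(tbl)
  expect_equal(nrow(rel), 2 * 2 * (2 + 1))
  mean_row <- dplyr::filter(rel, method == "BG90", metric == "Cp", density == "mean")
  per_density <- dplyr::filter(rel, method == "BG90", metric == "Cp", density != "mean")
  expect_equal(mean_row$icc, mean(per_density$icc))
  expect_equal(mean_row$icc_raw, mean(per_density$icc_raw))
})

test_that("nodal reliability works per node on AUC values", {
  set.seed(12)
  tbl <- tidyr::expand_grid(
    method = "WNG90",
    subject = sprintf("s%d", 1:5),
    session = sprintf("v%d", 1:3),
    node = c("roi001", "roi002"),
    metric = c("Dc", "Ne"),
    density = seq(0.05, 0.50, 0.05)
  )
  tbl$value <- rnorm(nrow(tbl), mean = 3)
  auc <- nodal_auc_table(tbl)
  expect_equal(nrow(auc), 5 * 3 * 2 * 2)
  one <- dplyr::filter(tbl, subject == "s1", session == "v1", node == "roi001", metric == "Dc")
  expect_equal(
    dplyr::filter(auc, subject == "s1", session == "v1", node == "roi001", metric == "Dc")$value,
    auc_over_densities(one$value[order(one$density)], sort(one$density))
  )
  rel <- reliability_nodal(auc)
  expect_equal(nrow(rel), 2 * 2)
  expect_true(all(c("icc", "icc_raw", "cv", "category") %in% names(rel)))
})

test_that("ICC recovery matches the variance-ratio ground truth", {
  rho_hat <- function(sb, sr, se, reps, seed) {
    set.seed(seed)
    mean(replicate(reps, {
      m <- outer(rnorm(16, sd = sb), rep(1, 3)) +
        outer(rep(1, 16), rnorm(3, sd = sr)) +
        matrix(rnorm(48, sd = se), 16, 3)
      icc_a1(m + 5)$icc_raw
    }))
  }
  # rho = sb^2 / (sb^2 + sr^2 + se^2)
  expect_lt(abs(rho_hat(1, 0.3, 0.954, 400, 1) - 0.5), 0.05)
  expect_lt(abs(rho_hat(1, 0.2, 0.458, 400, 2) - 0.8), 0.04)
})
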