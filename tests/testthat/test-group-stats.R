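test_that("Bonferroni arithmetic is exact", {
  expect_identical(bonferroni(0.05, 32), 0.05 / 32)
  expect_identical(bonferroni(0.05, 32), 0.0015625)
  expect_identical(bonferroni(0.05, 1), 0.05)
  expect_identical(bonferroni(0.01, 5), 0.002)
  expect_equal(bonferroni(0.05, 7) * 7, 0.05)
  expect_error(bonferroni(0.05, 0), "positive")
  expect_error(bonferroni(1.5, 4), "alpha")
})

test_that("t_critical matches independent quantile implementations", {
  # published threshold: one-sided, df = 14
  expect_equal(t_critical(0.00156, 14), 3.563, tolerance = 0.01 / 3.563)
  # scipy as an independent oracle
  out <- system2("python", c("-c", shQuote(
    "from scipy import stats; print(stats.t.ppf(1-0.00156, 14))")),
    stdout = TRUE)
  expect_equal(t_critical(0.00156, 14), as.numeric(out), tolerance = 1e-9)
  expect_equal(t_critical(0.5, 7), 0)
  expect_equal(t_critical(0.025, 1e6), 1.959966, tolerance = 1e-3)
  # monotone decreasing in alpha and df
  expect_true(t_critical(0.001, 14) > t_critical(0.01, 14))
  expect_true(t_critical(0.01, 5) > t_critical(0.01, 50))
})

test_that("connection t-test matches hand computation", {
  tt <- connection_ttest(c(0.2, 0.3, 0.4), null_mean = 0,
                         alpha = 0.0015625)
  expect_equal(tt$t_stat, 0.3 / (0.1 / sqrt(3)), tolerance = 1e-12)
  expect_equal(tt$group_sem, 0.1 / sqrt(3), tolerance = 1e-12)
  # values centered on the null mean: t = 0, not significant
  t0 <- connection_ttest(c(0.1, 0.2, 0.3), null_mean = 0.2, alpha = 0.05)
  expect_equal(t0$t_stat, 0)
  expect_false(t0$significant)
  # p-rule and threshold-rule agree
  for (v in list(c(0.2, 0.25, 0.3, 0.22), c(1, 2, 3, 4, 5))) {
    r <- connection_ttest(v, 0, alpha = 0.01)
    expect_identical(r$significant, r$p_value < 0.01)
  }
  expect_error(connection_ttest(c(0.1, 0.1, 0.1), 0), "degenerate")
  expect_error(connection_ttest(c(0.1, 0.2), 0), "3 participants")
})

test_that("regression on covariates behaves like OLS", {
  x <- c(10, 20, 30, 40, 50)
  r <- suppressWarnings(regress_db(x, 0.01 * x + 0.2))
  expect_equal(r$r, 1, tolerance = 1e-12)
  expect_equal(r$slope, 0.01, tolerance = 1e-12)
  expect_lt(r$p_value, 1e-8)
  expect_error(regress_db(rep(1, 5), rnorm(5)), "constant")
  # null calibration: p-values uniform under independence (KS)
  set.seed(42)
  ps <- replicate(500, regress_db(rnorm(20), rnorm(20))$p_value)
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("ANCOVA partial F tests detect interactions and are invariant", {
  set.seed(5)
  n <- 15
  x <- rnorm(2 * n, 30, 10)
  g <- rep(c("FM", "HC"), each = n)
  # identical groups: duplicate data under both labels
  y <- rnorm(2 * n)
  same <- ancova(rep(c("A", "B"), each = 2 * n), rep(x, 2), rep(y, 2))
  expect_gt(same$p_value[same$effect == "interaction"], 0.99)
  # constructed opposite slopes +/- 0.5, low noise
  y2 <- ifelse(g == "FM", 0.5, -0.5) * (x - 30) + rnorm(2 * n, 0, 1)
  a2 <- ancova(g, x, y2)
  expect_lt(a2$p_value[a2$effect == "interaction"], 0.001)
  # invariance to group coding
  a3 <- ancova(factor(g, levels = c("HC", "FM")), x, y2)
  expect_equal(a2$p_value, a3$p_value, tolerance = 1e-10)
  expect_true(all(c("effect", "F", "p_value", "mean_FM", "sem_FM",
                    "mean_HC", "sem_HC", "connection") %in%
                  c(names(a2), "connection")))
  expect_error(ancova(rep("A", 10), rnorm(10), rnorm(10)), "two groups")
})

test_that("group table applies the 32-test correction consistently", {
  net <- default_network()
  set.seed(6)
  labs <- connection_labels(net, TRUE)
  fake_fit <- function() {
    db <- setNames(rnorm(length(labs), 0, 0.1), labs)
    db["PBN->Thalamus"] <- rnorm(1, 0.9, 0.05)   # one strong connection
    structure(list(db = db), class = "sapm_fit")
  }
  cells <- list(FM_Pain = replicate(15, fake_fit(), simplify = FALSE),
                HC_Pain = replicate(15, fake_fit(), simplify = FALSE))
  gs <- summarize_table(cells, NULL, alpha_family = 0.05)
  expect_identical(gs$m_tests, 32L)
  expect_identical(gs$alpha_corrected, 0.0015625)
  expect_equal(gs$t_threshold, 3.563, tolerance = 0.01 / 3.563)
  # SEM column equals sd/sqrt(n) (direct recomputation)
  mat <- db_matrix(cells$FM_Pain)
  row <- gs$rows[gs$rows$cell == "FM_Pain" &
                 gs$rows$connection == "PBN->Thalamus", ]
  expect_equal(row$group_sem, sd(mat[, "PBN->Thalamus"]) / sqrt(15),
               tolerance = 1e-12)
  expect_true(row$significant)
  # flag consistency across all rows
  expect_identical(gs$rows$significant,
                   abs(gs$rows$t_stat) >= gs$t_threshold)
  # latent links are excluded from testing
  expect_false(any(grepl("^int", gs$rows$connection)))
})
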