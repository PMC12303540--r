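test_that("Mann-Whitney U matches enumeration on canonical examples", {
  r <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$U, 0)
  expect_equal(r$p, 0.1)       # 2 of C(6,3)=20 arrangements are this extreme
  expect_identical(r$method, "exact")

  r2 <- mann_whitney_u(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(r2$U, 8)        # n^2 / 2
  expect_equal(r2$p, 1)
})

test_that("exact p-values agree with the independent enumeration oracle", {
  set.seed(13)
  for (i in 1:20) {
    n1 <- sample(2:5, 1); n2 <- sample(2:5, 1)
    x <- rnorm(n1); y <- rnorm(n2)
    ours <- mann_whitney_u(x, y)
    oracle <- wilcox.test(x, y, exact = TRUE, correct = FALSE)
    expect_identical(ours$method, "exact")
    expect_equal(ours$p, oracle$p.value, tolerance = 1e-10)
  }
})

test_that("the normal approximation tracks a permutation Monte Carlo", {
  set.seed(14)
  x <- rnorm(30); y <- rnorm(30, 0.3)
  ours <- mann_whitney_u(x, y)
  pooled <- c(x, y)
  stat <- function(idx) {
    r <- rank(pooled)
    u <- 30 * 30 + 30 * 31 / 2 - sum(r[idx])
    min(u, 900 - u)
  }
  obs <- stat(seq_len(30))
  mc <- replicate(20000, stat(sample(60, 30)))
  p_mc <- mean(mc <= obs)
  expect_lt(abs(ours$p - p_mc), 0.01)
})

test_that("U statistics are label-symmetric and complementary", {
  set.seed(15)
  for (i in 1:10) {
    x <- rnorm(7); y <- rnorm(9)
    a <- mann_whitney_u(x, y); b <- mann_whitney_u(y, x)
    expect_equal(a$U, b$U)
    expect_equal(a$p, b$p, tolerance = 1e-12)
  }
})

test_that("group comparison reduces to the underlying test", {
  tab <- data.frame(
    participant = rep(sprintf("p%02d", 1:8), each = 2),
    group = rep(c("control", "csvd"), each = 8),
    task = "normal",
    repetition = rep(1:2, 8),
    metric = c(10, 10, 12, 12, 11, 11, 14, 14, 5, 5, 6, 6, 7, 7, 4, 4))
  cmp <- compare_groups(tab, parameters = "metric")
  direct <- mann_whitney_u(c(10, 12, 11, 14), c(5, 6, 7, 4))
  expect_equal(cmp$U, direct$U)
  expect_equal(cmp$p, direct$p)
  expect_equal(nrow(cmp), 1L)
  expect_error(compare_groups(tab[tab$group == "control", ],
                              parameters = "metric"), "both groups")
})

test_that("repetitions are averaged within participant before testing", {
  tab <- data.frame(
    participant = rep(c("a", "b", "c", "d"), each = 2),
    group = rep(c("control", "csvd"), each = 4),
    task = "normal", repetition = rep(1:2, 4),
    metric = c(0, 20, 9, 9, 1, 1, 2, 2))  # participant a averages to 10
  cmp <- compare_groups(tab, parameters = "metric")
  direct <- mann_whitney_u(c(10, 9), c(1, 2))
  expect_equal(cmp$p, direct$p)
})

test_that("demographics table flags real shifts and not null ones", {
  set.seed(16)
  base <- data.frame(
    participant = sprintf("p%02d", 1:29),
    group = rep(c("control", "csvd"), c(10, 19)),
    sex = rep(c("male", "female"), length.out = 29))
  vals <- rnorm(29, 65, 5)
  null_tab <- cbind(base, age = vals, height = 165 + vals * 0,
                    weight = rnorm(29, 65, 8))
  null_tab$height <- rnorm(29, 165, 8)
  d0 <- demographics_table(null_tab)
  expect_true(all(d0$p[d0$variable == "age"] > 0.001, na.rm = TRUE))

  shifted <- null_tab
  shifted$age[shifted$group == "csvd"] <- shifted$age[shifted$group == "csvd"] + 25
  d1 <- demographics_table(shifted)
  expect_lt(d1$p[d1$variable == "age"], 0.001)
})

test_that("Welch t matches the closed form on a hand-sized fixture", {
  x <- c(1, 2, 3); y <- c(7, 9, 14)
  d <- demographics_table(data.frame(
    participant = sprintf("p%d", 1:6),
    group = rep(c("control", "csvd"), each = 3), age = c(x, y)))
  mx <- mean(x); my <- mean(y); vx <- var(x) / 3; vy <- var(y) / 3
  tstat <- (mx - my) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / 2 + vy^2 / 2)
  p_hand <- 2 * pt(-abs(tstat), df)
  expect_equal(d$p[d$variable == "age"], p_hand, tolerance = 1e-12)
})

test_that("headline effects compute relative deficits and angle gaps", {
  cmp <- data.frame(
    task = rep("normal", 3),
    parameter = c("step_regularity", "head_to_body_mean", "head_to_ground_mean"),
    control_mean = c(1.0, 133, 134), control_sd = 1,
    csvd_mean = c(0.8, 128, 129), csvd_sd = 1, U = 1, p = 0.5,
    method = "exact")
  h <- headline_effects(cmp)
  expect_equal(h$regularity_rel_diff, 0.2)
  expect_equal(h$head_to_body_gap_deg, 5)

  cmp$csvd_mean <- cmp$control_mean
  h0 <- headline_effects(cmp)
  expect_equal(h0$regularity_rel_diff, 0)
  expect_equal(h0$head_to_ground_gap_deg, 0)

  # published group means as direct numeric input: the normal-walking
  # regularity deficit works out to about 19.7%
  cmp2 <- cmp[1, ]
  cmp2$control_mean <- 0.76; cmp2$csvd_mean <- 0.61
  expect_equal(headline_effects(cmp2)$regularity_rel_diff, (0.76 - 0.61) / 0.76,
               tolerance = 1e-12)
})

test_that("the calibrated cohort separates groups on regularity more than cadence", {
  hits <- vapply(1:5, function(s) {
    d <- calibrated_design(repetitions = 1L, seed = 4400 + s)
    d$tasks <- "normal"
    feat <- extract_features_table(simulate_cohort(d, channels = "sensor"))
    cmp <- compare_groups(feat, parameters = c("step_regularity",
                                               "step_frequency"))
    c(reg = cmp$p[cmp$parameter == "step_regularity"],
      freq = cmp$p[cmp$parameter == "step_frequency"])
  }, numeric(2))
  # regularity should separate the groups more strongly than step frequency
  expect_gt(mean(hits["freq", ] > hits["reg", ]), 0.5)
})
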