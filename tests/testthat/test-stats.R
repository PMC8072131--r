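test_that("rank-sum exact p matches exhaustive enumeration", {
  # disjoint samples: W minimal, p = 2/20
  rs <- rank_sum_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(rs$statistic, 6)
  expect_equal(rs$p_value, 0.1)
  expect_equal(rs$method, "exact enumeration")

  # independent enumeration oracle on a random tied sample
  set.seed(20)
  a <- sample(1:5, 6, replace = TRUE)
  b <- sample(2:6, 5, replace = TRUE)
  r <- rank(c(a, b))
  w_obs <- sum(r[1:6])
  ws <- apply(utils::combn(11, 6), 2, function(ix) sum(r[ix]))
  p_oracle <- min(1, 2 * min(mean(ws <= w_obs), mean(ws >= w_obs)))
  expect_equal(rank_sum_test(a, b)$p_value, p_oracle)

  # identical samples: two-sided p is 1
  expect_equal(rank_sum_test(c(2, 2, 5), c(2, 2, 5))$p_value, 1)
})

test_that("rank-sum agrees with wilcox.test where both are exact", {
  set.seed(21)
  for (rep in 1:5) {
    a <- rnorm(7)
    b <- rnorm(6) # continuous: no ties
    p_ref <- stats::wilcox.test(a, b, exact = TRUE)$p.value
    expect_equal(rank_sum_test(a, b)$p_value, p_ref, tolerance = 1e-12)
  }
})

test_that("rank-sum is symmetric under label swap and rejects empty samples", {
  set.seed(22)
  a <- rnorm(12)
  b <- rnorm(15) + 0.8
  expect_equal(rank_sum_test(a, b)$p_value, rank_sum_test(b, a)$p_value)
  expect_error(rank_sum_test(numeric(0), b), "non-empty")
})

test_that("rank-sum holds its nominal type-I error under the null", {
  # 10,000 null pairs of n = 20: rejection rate at alpha = 0.05 is 0.05 +- 0.01
  set.seed(23)
  n_rep <- 10000L
  x <- matrix(rnorm(n_rep * 40), ncol = 40)
  rej <- vapply(seq_len(n_rep), function(i) {
    rank_sum_test(x[i, 1:20], x[i, 21:40])$p_value < 0.05
  }, TRUE)
  expect_lt(abs(mean(rej) - 0.05), 0.01)
})

test_that("KS statistic is the brute-force maximal ECDF gap", {
  expect_equal(ks_two_sample(1:10, 1:10)$statistic, 0)
  expect_equal(ks_two_sample(1:5, 6:10)$statistic, 1)

  set.seed(24)
  a <- rnorm(30)
  b <- rnorm(30, 0.7)
  d_brute <- max(vapply(c(a, b), function(p) {
    abs(mean(a <= p) - mean(b <= p))
  }, 0))
  ks <- ks_two_sample(a, b)
  expect_equal(ks$statistic, d_brute, tolerance = 1e-12)
  # and matches the reference implementation
  ref <- suppressWarnings(stats::ks.test(a, b))
  expect_equal(ks$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(ks$p_value, ref$p.value, tolerance = 0.01)
})

test_that("two-way ANOVA matches a closed-form sums-of-squares oracle", {
  set.seed(25)
  d <- expand.grid(age = c("2", "18", "22"), sex = c("m", "f"), rep = 1:4)
  d$y <- rnorm(nrow(d))
  out <- two_way_anova(d, "y")

  # balanced design: SS from group means (type I = type II when balanced)
  gm <- mean(d$y)
  mA <- tapply(d$y, d$age, mean)
  mB <- tapply(d$y, d$sex, mean)
  mAB <- tapply(d$y, interaction(d$age, d$sex), mean)
  nA <- 8; nB <- 12; nAB <- 4
  ss_a <- nA * sum((mA - gm)^2)
  ss_b <- nB * sum((mB - gm)^2)
  ss_cells <- nAB * sum((mAB - gm)^2)
  ss_ab <- ss_cells - ss_a - ss_b
  expect_equal(out$sum_sq, c(ss_a, ss_b, ss_ab), tolerance = 1e-8)

  ss_res <- sum((d$y - mAB[interaction(d$age, d$sex)])^2)
  f_oracle <- c(ss_a / 2, ss_b / 1, ss_ab / 2) / (ss_res / (24 - 6))
  expect_equal(out$f_value, f_oracle, tolerance = 1e-8)
})

test_that("two-way ANOVA agrees with the car type-II reference", {
  skip_if_not_installed("car")
  set.seed(26)
  # mildly unbalanced: drop two rows
  d <- expand.grid(age = c("2", "22"), sex = c("m", "f"), rep = 1:5)[-c(3, 17), ]
  d$y <- rnorm(nrow(d)) + as.numeric(d$age == "22")
  out <- two_way_anova(d, "y")
  fit <- stats::lm(y ~ A * B,
                   data = data.frame(y = d$y, A = factor(d$age),
                                     B = factor(d$sex)),
                   contrasts = list(A = "contr.sum", B = "contr.sum"))
  ref <- car::Anova(fit, type = 2)
  expect_equal(out$sum_sq, ref$`Sum Sq`[1:3], tolerance = 1e-10)
  expect_equal(out$f_value, ref$`F value`[1:3], tolerance = 1e-10)
})

test_that("degenerate designs follow the documented conventions", {
  d <- expand.grid(age = c("2", "22"), sex = c("m", "f"), rep = 1:3)
  d$y <- 5
  out <- two_way_anova(d, "y")
  expect_equal(out$f_value, c(0, 0, 0))
  expect_equal(out$p_value, c(1, 1, 1))

  # additive effects, zero noise: main effects unbounded, interaction 0
  d$y <- 2 * (d$age == "22") + 1 * (d$sex == "f")
  out <- two_way_anova(d, "y")
  expect_true(all(is.infinite(out$f_value[1:2])))
  expect_equal(out$p_value[1:2], c(0, 0))
  expect_equal(out$f_value[3], 0)

  # empty cell is named in the error
  d2 <- d[!(d$age == "22" & d$sex == "f"), ]
  expect_error(two_way_anova(d2, "y"), "empty design cell")
})

test_that("balanced designs make type-II equal type-I sums of squares", {
  set.seed(27)
  d <- expand.grid(age = c("2", "22"), sex = c("m", "f"), rep = 1:6)
  d$y <- rnorm(nrow(d))
  out <- two_way_anova(d, "y")
  a1 <- stats::anova(stats::lm(y ~ factor(age) * factor(sex), data = d))
  expect_equal(out$sum_sq, a1$`Sum Sq`[1:3], tolerance = 1e-10)
})

test_that("Sidak adjustment follows the formula and its monotonicity", {
  expect_equal(posthoc_adjust(0.05, m = 1), 0.05)
  expect_equal(posthoc_adjust(0.05, m = 3), 0.142625)
  p <- seq(0, 1, by = 0.05)
  adj <- posthoc_adjust(p, m = 4)
  expect_true(all(diff(adj) >= 0))  # monotone in raw p
  expect_true(all(adj >= p))        # never below raw
  expect_error(posthoc_adjust(1.2), "\\[0, 1\\]")
})

test_that("Tukey post hoc draws on the studentized range of the group fit", {
  set.seed(28)
  d <- data.frame(g = rep(c("a", "b", "c"), each = 8),
                  y = rnorm(24) + rep(c(0, 1, 0), each = 8))
  tk <- tukey_posthoc(d, "y", "g")
  expect_equal(nrow(tk), 3L)
  ref <- stats::TukeyHSD(stats::aov(y ~ g, data = d))$g
  expect_equal(tk$p_adj, unname(ref[, "p adj"]), tolerance = 1e-12)
  expect_true(all(tk$p_adj >= 0 & tk$p_adj <= 1))
})

test_that("the group-comparison battery emits labelled tidy results", {
  set.seed(29)
  d <- expand.grid(age = c("2", "22"), sex = c("m", "f"), rep = 1:4)
  d$tort <- rnorm(nrow(d), 1.2, 0.05) + 0.1 * (d$age == "22" & d$sex == "m")
  out <- compare_groups(d, "tort", posthoc = "sidak")
  expect_true(all(c("test", "statistic", "p_value", "comparison") %in%
                    names(out)))
  expect_true(any(out$test == "two_way_anova"))
  expect_true(any(out$test == "wilcoxon_rank_sum"))
  pr <- out[out$test == "wilcoxon_rank_sum", ]
  expect_true(all(pr$p_adjusted >= pr$p_value))
})
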