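test_that("mean bias t-test handles regular and degenerate samples", {
  z <- mean_bias(c(0, 0, 0, 0))
  expect_equal(z$bias, 0)
  expect_equal(z$ci, c(0, 0))
  expect_equal(z$p, 1)
  # symmetric +/-1 sample: t = 0, p = 1, SE = sd/sqrt(n) = sqrt(4/3)/2
  s <- mean_bias(c(1, -1, 1, -1))
  expect_equal(s$bias, 0)
  expect_equal(s$t, 0)
  expect_equal(s$p, 1)
  expect_equal(s$ci[2], qt(0.975, 3) * sqrt(4 / 3) / 2)
  # sampling-theory oracle: strong signal detected, CI covers truth
  set.seed(101)
  d <- rnorm(10000, mean = 1, sd = 1)
  g <- mean_bias(d)
  expect_true(g$ci[1] <= 1 && 1 <= g$ci[2])
  expect_lt(g$p, 0.001)
  expect_equal(g$df, 9999)
  # zero variance, nonzero mean
  w <- NULL
  expect_warning(w <- mean_bias(c(2, 2, 2)), "degenerate")
  expect_equal(w$t, Inf)
  expect_equal(w$p, 0)
})

test_that("mean-bias CI has nominal coverage", {
  set.seed(7)
  hits <- vapply(1:1000, function(i) {
    b <- mean_bias(rnorm(30, mean = 0.5))
    b$ci[1] <= 0.5 && 0.5 <= b$ci[2]
  }, logical(1))
  expect_gt(mean(hits), 0.93)
  expect_lt(mean(hits), 0.97)
})

test_that("limits of agreement match the 1.96 SD construction", {
  cst <- limits_of_agreement(rep(1.5, 10))
  expect_equal(c(cst$loa_lower, cst$loa_upper), c(1.5, 1.5))
  two <- limits_of_agreement(c(-1, 1))
  expect_equal(two$bias, 0)
  expect_equal(two$loa_upper, 1.96 * sqrt(2), tolerance = 1e-12)  # 2.7719
  expect_equal(two$loa_lower, -1.96 * sqrt(2), tolerance = 1e-12)
  # coverage property: ~95% of standard-normal diffs inside the LoA
  set.seed(11)
  d <- rnorm(1e5)
  l <- limits_of_agreement(d)
  inside <- mean(d >= l$loa_lower & d <= l$loa_upper)
  expect_equal(inside, 0.95, tolerance = 0.005)
  expect_true(l$loa_lower <= l$bias && l$bias <= l$loa_upper)
})

test_that("pearson_r recovers exact and null correlations", {
  a <- c(1, 2, 4, 6, 9)
  expect_equal(pearson_r(a, 2 * a + 3)$r, 1)
  expect_equal(pearson_r(a, -a)$r, -1)
  set.seed(5)
  x <- rnorm(5000); y <- rnorm(5000)
  expect_lt(abs(pearson_r(x, y)$r), 0.05)
  expect_error(pearson_r(a, rep(1, 5)), "constant")
  expect_error(pearson_r(a[1:2], a[1:2]), "at least 3")
})

test_that("ICC(A,1) matches a brute-force variance-components oracle", {
  # small constructed 5x2 table; oracle computed from explicit mean squares
  x <- cbind(a = c(9, 6, 8, 7, 10), b = c(9.5, 6.5, 9, 8, 10.5))
  oracle <- local({
    n <- nrow(x); k <- ncol(x)
    y <- as.vector(x)
    subj <- factor(rep(seq_len(n), k)); meth <- factor(rep(seq_len(k), each = n))
    fit <- stats::aov(y ~ subj + meth)
    ms <- summary(fit)[[1]][["Mean Sq"]]
    msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
    (msr - mse) / (msr + (k - 1) * mse + k / n * (msc - mse))
  })
  expect_equal(icc_absolute(x)$icc, oracle, tolerance = 1e-12)
  # identical methods with between-subject variance -> 1
  y <- cbind(c(1, 5, 9, 2, 7), c(1, 5, 9, 2, 7))
  expect_equal(icc_absolute(y)$icc, 1)
  # independent noise, no subject effect -> ~0
  set.seed(21)
  z <- cbind(rnorm(2000), rnorm(2000))
  expect_lt(abs(icc_absolute(z)$icc), 0.05)
  expect_error(icc_absolute(cbind(c(1, NA, 3), c(1, 2, 3))), "missing cells")
  expect_error(icc_absolute(cbind(1:2, 3:4)), "at least 3 subjects")
})

test_that("ICC equals Pearson r when methods share mean and variance", {
  set.seed(31)
  u <- rnorm(50); e1 <- rnorm(50, sd = 0.3); e2 <- rnorm(50, sd = 0.3)
  a <- u + e1
  # force exactly equal first and second moments via standardization
  b <- (u + e2 - mean(u + e2)) / sd(u + e2) * sd(a) + mean(a)
  expect_equal(icc_absolute(cbind(a, b))$icc, cor(a, b), tolerance = 0.02)
  expect_true(abs(icc_absolute(cbind(a, b))$icc) <= 1)
})

test_that("bias-by-level ANOVA separates real level effects from noise", {
  # power oracle: two well-separated levels
  set.seed(41)
  d <- c(rnorm(50, 0), rnorm(50, 5))
  lv <- rep(c("light", "hard"), each = 50)
  a <- bias_anova_by_level(d, lv)
  expect_lt(a$p, 0.001)
  expect_equal(a$df[1], 1)
  expect_equal(a$df[2], 98)
  # type-I error property: same distribution across levels
  set.seed(43)
  rejections <- vapply(1:100, function(i) {
    d0 <- rnorm(120)
    bias_anova_by_level(d0, rep(letters[1:4], each = 30))$p < 0.05
  }, logical(1))
  expect_gte(mean(!rejections), 0.90)
})

test_that("Bonferroni pairwise correction multiplies by N(N-1)/2 and caps", {
  set.seed(47)
  d <- rnorm(250)
  lv <- rep(paste0("L", 1:5), each = 50)
  a <- bias_anova_by_level(d, lv)
  expect_equal(nrow(a$pairwise), 10)  # 5 levels -> 10 comparisons
  expect_equal(a$pairwise$p_adj, pmin(1, a$pairwise$p_raw * 10))
  # order-preserving, never lowers a p-value
  expect_true(all(a$pairwise$p_adj >= a$pairwise$p_raw))
  o <- order(a$pairwise$p_raw)
  expect_true(all(diff(a$pairwise$p_adj[o]) >= 0))
  expect_true(all(a$pairwise$p_adj >= 0 & a$pairwise$p_adj <= 1))
  # sparse level exclusion
  expect_warning(bias_anova_by_level(c(rnorm(20), 1), c(rep("a", 10),
                                                        rep("b", 10), "c")),
                 "excluding")
})

test_that("per-individual biases expose masking of group-level agreement", {
  one <- per_individual_biases(c(1, 1), c("p1", "p1"))
  expect_equal(nrow(one), 1)
  expect_equal(one$bias, 1)
  # offsetting individual biases with zero group bias
  d <- c(2, 2, -2, -2)
  ids <- c("a", "a", "b", "b")
  tab <- per_individual_biases(d, ids)
  expect_equal(mean(d), 0)
  expect_true(all(abs(tab$bias) == 2))
  # simulation: per-participant biases ~ N(0.36, 1)
  set.seed(53)
  pb <- rnorm(200, 0.36)
  tab2 <- per_individual_biases(rep(pb, each = 5) + rnorm(1000, sd = 0.1),
                                rep(seq_len(200), each = 5))
  mc_se <- sd(tab2$bias) / sqrt(nrow(tab2))
  expect_lt(abs(mean(tab2$bias) - 0.36), 3 * mc_se)
})

test_that("time-synchronized group pattern averages per minute and method", {
  x <- expand.grid(participant = 1:3, minute = 1:4,
                   method = c("m1", "m2"), stringsAsFactors = FALSE)
  x$value <- ifelse(x$method == "m1", x$minute, 10 + x$minute)
  p <- time_synchronized_group_pattern(x)
  expect_equal(p$mean[p$method == "m1"], 1:4)
  expect_equal(p$mean[p$method == "m2"], 11:14)
  expect_true(all(p$n == 3))
  # identical series: group mean equals any individual
  x1 <- x[x$participant == 1, ]
  p1 <- time_synchronized_group_pattern(rbind(x1, x1, x1))
  expect_equal(p1$mean, p$mean)
  pf <- time_synchronized_group_pattern(x, min_participants = 5)
  expect_true(all(pf$flagged))
})

test_that("the combined agreement report wires all statistics together", {
  set.seed(61)
  n <- 200
  b <- rnorm(n, 5, 2)
  a <- b + rnorm(n, 0.36, 0.5)
  lv <- sample(c("light", "moderate", "hard"), n, replace = TRUE)
  ids <- rep(1:20, each = 10)
  rep_ <- agreement_report(a, b, level = lv, participant = ids)
  expect_s3_class(rep_, "agreement_report")
  expect_equal(rep_$bias$bias, mean(a - b))
  expect_equal(rep_$loa$bias, rep_$bias$bias)
  expect_true(rep_$loa$loa_lower <= rep_$bias$bias &&
                rep_$bias$bias <= rep_$loa$loa_upper)
  expect_equal(nrow(rep_$individual), 20)
  expect_true(rep_$icc$icc <= 1 && rep_$icc$icc >= -1)
  expect_output(print(rep_), "bias = ")
})
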