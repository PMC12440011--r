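test_that("mean/SEM summaries use the n-1 sample SD", {
  s <- mean_sem(c(2, 4, 6))
  expect_equal(s$mean, 4)
  expect_equal(s$sd, 2)
  expect_equal(s$sem, 2 / sqrt(3))
  s1 <- mean_sem(5)
  expect_equal(s1$mean, 5)
  expect_false(s1$sem_defined)
  expect_equal(mean_sem(rep(3, 4))$sem, 0)
  expect_error(mean_sem(numeric(0)), "empty")
  x <- rnorm(20)
  expect_equal(mean_sem(x)[c("mean", "sem")], mean_sem(rev(x))[c("mean", "sem")])
})

test_that("the worked three-group ANOVA gives F = 21 on (2, 6) df", {
  groups <- list(a = c(1, 2, 3), b = c(2, 3, 4), c = c(6, 7, 8))
  an <- one_way_anova(groups)
  expect_equal(an$F, 21, tolerance = 1e-12)
  expect_equal(an$df_between, 2)
  expect_equal(an$df_within, 6)
  expect_equal(an$p, pf(21, 2, 6, lower.tail = FALSE))
})

test_that("degenerate and two-group ANOVAs behave classically", {
  an0 <- one_way_anova(list(a = c(1, 2, 3), b = c(3, 2, 1)))
  expect_equal(an0$F, 0)
  expect_equal(an0$p, 1)

  set.seed(6)
  g <- list(a = rnorm(8), b = rnorm(9, 1))
  an <- one_way_anova(g)
  tt <- t.test(g$a, g$b, var.equal = TRUE)
  expect_equal(an$F, unname(tt$statistic)^2, tolerance = 1e-12)
  expect_error(one_way_anova(list(a = 1, b = c(1, 2))), "n >= 2")
})

test_that("ANOVA F matches the sums-of-squares oracle on random data", {
  set.seed(31)
  for (i in 1:30) {
    k <- sample(2:5, 1)
    groups <- lapply(seq_len(k), function(j) rnorm(sample(2:8, 1), mean = j / 2))
    names(groups) <- paste0("g", seq_len(k))
    an <- one_way_anova(groups)
    or <- anova_F_oracle(groups)
    expect_equal(an$F, or$F, tolerance = 1e-9)
    expect_equal(an$mse, or$mse, tolerance = 1e-9)
    expect_equal(an$df_within, or$df_within)
  }
})

test_that("Fisher's LSD reproduces the pooled-error closed form", {
  groups <- list(a = c(1, 2, 3), b = c(2, 3, 4), c = c(6, 7, 8))
  an <- one_way_anova(groups)
  p <- fisher_lsd(groups, an)
  for (pair in list(c("a", "b"), c("a", "c"), c("b", "c"))) {
    i <- pair[1]; j <- pair[2]
    tij <- (mean(groups[[i]]) - mean(groups[[j]])) /
      sqrt(an$mse * (1 / 3 + 1 / 3))
    expect_equal(p[i, j], 2 * pt(-abs(tij), 6))
  }
  expect_equal(p["a", "b"], p["b", "a"])

  # equal pair means -> p = 1
  g2 <- list(a = c(1, 3), b = c(2, 2), c = c(5, 6))
  p2 <- fisher_lsd(g2, one_way_anova(g2))
  expect_equal(p2["a", "b"], 1)
  expect_error(fisher_lsd(list(x = 1:3, y = 4:6), an), "do not match")
})

test_that("with two groups LSD equals the pooled two-sample t-test exactly", {
  set.seed(14)
  for (i in 1:10) {
    g <- list(ctrl = rnorm(6), high = rnorm(7, 0.8))
    an <- one_way_anova(g)
    p <- fisher_lsd(g, an)
    tt <- t.test(g$ctrl, g$high, var.equal = TRUE)
    expect_equal(p["ctrl", "high"], tt$p.value, tolerance = 1e-12)
    expect_equal(p["ctrl", "high"], an$p, tolerance = 1e-12)
  }
})

test_that("ddCt fold change follows the 2^-ddCt closed form", {
  ct <- data.frame(condition = rep(c("ctrl", "high"), each = 2),
                   gene = rep(c("TNF", "ACTB"), 2),
                   ct = c(25, 20, 25, 20))
  expect_equal(ddct_fold_change(ct, "TNF", "ACTB", "ctrl", "high")$fold_change, 1)

  ct$ct <- c(25, 20, 24, 20)   # ddCt = -1
  expect_equal(ddct_fold_change(ct, "TNF", "ACTB", "ctrl", "high")$fold_change, 2)

  ct$ct <- c(25, 20, 25 - 2.322, 20)
  fc <- ddct_fold_change(ct, "TNF", "ACTB", "ctrl", "high")$fold_change
  expect_equal(fc, 2^2.322, tolerance = 1e-12)
  expect_equal(fc, 5, tolerance = 0.002)

  expect_error(ddct_fold_change(ct, "TNF", "ACTB", "ctrl", "missing"), "missing")
})

test_that("ddCt is invariant to a constant shift of one gene", {
  set.seed(8)
  ct <- data.frame(condition = rep(c("ctrl", "high"), each = 4),
                   gene = rep(rep(c("TNF", "ACTB"), each = 2), 2),
                   ct = runif(8, 18, 30))
  f0 <- ddct_fold_change(ct, "TNF", "ACTB", "ctrl", "high")$fold_change
  ct2 <- ct
  ct2$ct[ct2$gene == "ACTB"] <- ct2$ct[ct2$gene == "ACTB"] + 3.7
  f1 <- ddct_fold_change(ct2, "TNF", "ACTB", "ctrl", "high")$fold_change
  expect_equal(f0, f1)
})

test_that("fold changes are ratios of group means", {
  g <- list("11mM" = c(300, 300), "33mM" = c(100, 100))
  fc <- fold_change(g, "11mM")
  expect_equal(unname(fc["33mM"]), 1 / 3)
  expect_equal(unname(fc["11mM"]), 1)
  expect_error(fold_change(list(a = c(0, 0), b = 1:2), "a"), "zero")
  expect_error(fold_change(g, "nope"), "not found")
})
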