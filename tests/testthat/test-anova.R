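# Independent oracle: hand-computed sums of squares on a balanced 2x2 design.

test_that("factorial ANOVA matches a hand sums-of-squares decomposition", {
  d <- expand.grid(a = c("x", "y"), b = c("u", "v"),
                   rep = 1:2, KEEP.OUT.ATTRS = FALSE)
  d$y <- c(3.1, 5.2, 4.0, 6.8, 2.9, 5.5, 4.4, 7.0)
  grand <- mean(d$y)
  ma <- tapply(d$y, d$a, mean)
  mb <- tapply(d$y, d$b, mean)
  mab <- tapply(d$y, paste(d$a, d$b), mean)
  ss_a <- 4 * sum((ma - grand)^2)
  ss_b <- 4 * sum((mb - grand)^2)
  ss_ab <- 2 * sum((mab - ma[substr(names(mab), 1, 1)] -
                      mb[substr(names(mab), 3, 3)] + grand)^2)
  ss_res <- sum((d$y - mab[paste(d$a, d$b)])^2)
  res <- factorial_anova(d, "y", c("a", "b"), interactions = "a:b",
                         transform = "none")
  expect_equal(res$sumsq, unname(c(ss_a, ss_b, ss_ab, ss_res)))
  expect_equal(res$df, c(1, 1, 1, 4))
  expect_equal(res$statistic[1], (ss_a / 1) / (ss_res / 4))
  f <- res$statistic[1:3]
  expect_equal(res$p.value[1:3], pf(f, 1, 4, lower.tail = FALSE))
})

test_that("equal cell means give F near 0 and p near 1", {
  d <- expand.grid(a = c("x", "y"), b = c("u", "v"), rep = 1:3)
  d$y <- 10 + c(-0.01, 0, 0.01)[d$rep]  # same mean in every cell
  res <- factorial_anova(d, "y", c("a", "b"), transform = "none")
  expect_lt(max(res$statistic[1:2]), 1e-10)
  expect_gt(min(res$p.value[1:2]), 0.999)
})

test_that("a 10-fold species effect is detected in the design's regime", {
  set.seed(21)
  d <- expand.grid(species = c("coral", "sponge"),
                   food = c("algae", "bacteria"), rep = 1:3)
  d$rate <- ifelse(d$species == "sponge", 1.0, 0.1) * 10^rnorm(12, 0, 0.15)
  res <- factorial_anova(d, "rate", c("species", "food"))
  sp <- res[res$term == "species", ]
  expect_equal(sp$df, 1)
  expect_equal(sp$df_den, 9)
  expect_lt(sp$p.value, 0.001)
})

test_that("design bookkeeping: labels, residual df, empty cells, zeros", {
  set.seed(22)
  d <- expand.grid(a = c("x", "y"), b = c("u", "v"), rep = 1:3)
  d$y <- 10^rnorm(12)
  r1 <- factorial_anova(d, "y", c("a", "b"))
  # permuting factor labels leaves the residual df unchanged
  d2 <- d; d2$a <- ifelse(d$a == "x", "y", "x")
  r2 <- factorial_anova(d2, "y", c("a", "b"))
  expect_equal(r1$df_den, r2$df_den)
  expect_equal(r1$df, r2$df)
  # empty cell is an error naming the missing combination
  expect_error(factorial_anova(d[!(d$a == "x" & d$b == "v"), ], "y",
                               c("a", "b"), interactions = "a:b"),
               "empty design cell: a = x, b = v")
  # single-level factor
  expect_error(factorial_anova(d[d$a == "x", ], "y", c("a", "b")),
               "fewer than 2")
  # non-positive responses are excluded with a warning before log10
  d$y[1] <- 0; d$y[2] <- -1
  expect_warning(r3 <- factorial_anova(d, "y", c("a", "b")),
                 "non-positive")
  expect_equal(sum(r3$df) + 1, 10)  # 10 usable observations
})
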