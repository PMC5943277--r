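# Ecological indices and the regression battery.

test_that("yield response is measured against matched control means", {
  md <- data.frame(
    sample_id = paste0("p", 1:6),
    trial = "T1", p_level = 0,
    inoculated = c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE),
    yield = c(3000, 3100, 3050, 2950, 3025, 3500))
  yr <- yield_response(md)
  expect_equal(yr$response[1], 0, tolerance = 1e-12)  # equals control mean
  expect_equal(yr$response[2], (3500 - 3025) / 3025, tolerance = 1e-12)
  # zero control mean is an error
  md0 <- md; md0$yield[1:4] <- 0
  expect_error(yield_response(md0), "zero")
  # an inoculated plot with no matching controls is an error
  md2 <- md; md2$p_level[5:6] <- 100
  expect_error(yield_response(md2), "without matching control")
})

test_that("commonness reproduces the niche-breadth arithmetic", {
  expect_equal(commonness_index(c(100, 100, 100)), 3.0, tolerance = 1e-9)
  expect_equal(commonness_index(c(100, 0, 0)), 1.0, tolerance = 1e-9)
  expect_equal(commonness_index(c(60, 30, 10)), 1 / 0.46, tolerance = 1e-9)
  # scale invariance
  expect_equal(commonness_index(c(6, 3, 1) * 17),
               commonness_index(c(60, 30, 10)), tolerance = 1e-12)
})

test_that("table-level commonness applies filters and the trial-share matrix", {
  counts <- rbind(
    c1 = c(A = 600L, B = 1000L, RHZ = 100L, rare = 1L),
    c2 = c(A = 600L, B = 0L,    RHZ = 100L, rare = 0L),
    c3 = c(A = 300L, B = 0L,    RHZ = 100L, rare = 1L),
    c4 = c(A = 300L, B = 0L,    RHZ = 100L, rare = 0L),
    c5 = c(A = 100L, B = 0L,    RHZ = 100L, rare = 0L),
    c6 = c(A = 100L, B = 0L,    RHZ = 100L, rare = 0L))
  trials <- rep(c("T1", "T2", "T3"), each = 2)
  cm <- commonness(counts, trials, inoculum_set = "RHZ",
                   rare_filter = 0.002)
  # OTU A: trial means (600, 300, 100) -> shares (.6,.3,.1)
  expect_equal(unname(cm$commonness["A"]), 1 / 0.46, tolerance = 1e-9)
  # specialist B appears only in trial 1
  expect_equal(unname(cm$commonness["B"]), 1.0, tolerance = 1e-9)
  # P columns sum to one over trials
  expect_equal(unname(colSums(cm$P)), rep(1, ncol(cm$P)), tolerance = 1e-12)
  expect_true(all(cm$commonness >= 1 & cm$commonness <= 3))
  # exclusions are reported with reasons
  expect_setequal(cm$excluded$otu_id, c("RHZ", "rare"))
  expect_error(commonness(counts, rep("T1", 6)), ">= 2 trials")
})

test_that("robustness is the inoculated/control mean ratio with explicit gaps", {
  counts <- rbind(
    i1 = c(A = 20L, B = 10L), i2 = c(A = 30L, B = 0L),
    u1 = c(A = 50L, B = 0L),  u2 = c(A = 50L, B = 0L))
  md <- data.frame(sample_id = c("i1", "i2", "u1", "u2"), trial = "T1",
                   inoculated = c(TRUE, TRUE, FALSE, FALSE))
  rb <- robustness(counts, md, rare_filter = 0)
  expect_equal(rb$robustness[rb$otu_id == "A"], 0.5)
  expect_true(rb$undefined[rb$otu_id == "B"])
  expect_true(is.na(rb$robustness[rb$otu_id == "B"]))
  md_bad <- md; md_bad$inoculated <- TRUE
  expect_error(robustness(counts, md_bad, rare_filter = 0), "lacks")
})

test_that("Bray-Curtis similarity matches its formula and vegan", {
  expect_equal(bray_curtis(c(5, 5, 0), c(5, 5, 0)), 1.0)
  expect_equal(bray_curtis(c(5, 0), c(0, 7)), 0.0)
  expect_equal(bray_curtis(c(6, 4), c(4, 6)), 0.8)
  expect_error(bray_curtis(c(0, 0), c(0, 0)), "all-zero")
  set.seed(8)
  m <- matrix(rpois(40, 20), 4, 10,
              dimnames = list(paste0("s", 1:4), NULL))
  D <- bray_curtis_dist(m)
  for (i in 1:3) for (j in (i + 1):4)
    expect_equal(1 - as.matrix(D)[i, j], bray_curtis(m[i, ], m[j, ]),
                 tolerance = 1e-12)
})

test_that("permanova pseudo-F agrees with vegan::adonis2", {
  set.seed(14)
  m <- matrix(rpois(12 * 8, 30), 12, 8,
              dimnames = list(paste0("s", 1:12), NULL))
  md <- data.frame(trial = rep(c("a", "b", "c"), each = 4),
                   inoculated = rep(c(TRUE, FALSE), 6))
  D <- vegan::vegdist(m, method = "bray")
  ours <- permanova(D, md, ~ trial * inoculated, permutations = 99,
                    seed = 2)
  ref <- vegan::adonis2(D ~ trial * inoculated, data = md,
                        permutations = 99, by = "terms")
  expect_equal(ours$F[1:3], ref$F[1:3], tolerance = 1e-8)
  expect_equal(ours$SS[1:3], ref$SumOfSqs[1:3], tolerance = 1e-8)
  expect_equal(ours$df[1:3], ref$Df[1:3])
  expect_error(permanova(D, data.frame(trial = rep("a", 12),
                                       inoculated = md$inoculated),
                         ~ trial * inoculated), "single level")
})

test_that("exact permanova p equals complete enumeration by the oracle", {
  set.seed(15)
  m <- matrix(rpois(6 * 5, 25), 6, 5,
              dimnames = list(paste0("s", 1:6), NULL))
  md <- data.frame(trial = rep(c("a", "b", "c"), each = 2),
                   inoculated = rep(c(TRUE, FALSE), 3))
  D <- vegan::vegdist(m, method = "bray")
  ours <- permanova(D, md, ~ trial + inoculated, permutations = "exact")
  p_oracle <- {
    n <- 6
    perms <- amfniche:::all_permutations(n)
    Fo <- permanova_f_additive_oracle(D, md$trial, md$inoculated)
    ge <- rep(0, 2)
    for (r in seq_len(nrow(perms))) {
      p <- perms[r, ]
      ge <- ge + (permanova_f_additive_oracle(as.matrix(D)[p, p],
                                              md$trial, md$inoculated) >=
                    Fo - 1e-12)
    }
    ge / nrow(perms)
  }
  expect_equal(ours$p[1:2], p_oracle, tolerance = 1e-12)
})

test_that("all_permutations enumerates the symmetric group", {
  p3 <- amfniche:::all_permutations(3)
  expect_equal(nrow(p3), 6)
  expect_equal(nrow(unique(p3)), 6)
  expect_true(all(apply(p3, 1, sort) == 1:3))
})

test_that("correlation handles log transforms and degenerate input", {
  x <- 1:10
  expect_equal(correlate(x, 2 * x)$r, 1.0, tolerance = 1e-12)
  expect_equal(correlate(x, exp(x), log_y = TRUE)$r, 1.0,
               tolerance = 1e-12)
  # zeros survive the log transform via the pseudo-count
  r <- correlate(c(0, 1, 10, 100), c(1, 2, 3, 4), log_x = TRUE)
  expect_true(is.finite(r$r))
  expect_error(correlate(1:2, 1:2), ">= 3")
  expect_error(correlate(rep(1, 5), 1:5), "zero variance")
})

test_that("odds ratios exponentiate coefficients", {
  expect_equal(odds_ratio(0), 1.0)
  expect_equal(odds_ratio(log(2)), 2.0)
  expect_equal(signif(odds_ratio(-8.68), 2), 0.00017)
})

test_that("stepwise OLS recovers a strong predictor and standardizes it", {
  set.seed(21)
  n <- 48
  d <- data.frame(x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n))
  d$y <- 2 * d$x1 + rnorm(n, 0, 0.5)
  fit <- stepwise_lm(d, "y", c("x1", "x2", "x3"))
  expect_true("x1" %in% fit$selected)
  cf <- fit$coefficients
  expect_gt(cf$estimate[cf$term == "x1"], 0)
  # noiseless y = x gives standardized slope exactly 1
  d2 <- data.frame(x = rnorm(20)); d2$y <- d2$x
  fit2 <- suppressWarnings(stepwise_lm(d2, "y", "x"))  # perfect fit
  expect_equal(cf2 <- fit2$coefficients$std_coef[
    fit2$coefficients$term == "x"], 1.0, tolerance = 1e-9)
  # selected model never beats full or null on AIC
  expect_lte(fit$aic, stats::AIC(stats::lm(y ~ x1 + x2 + x3, d)))
  expect_lte(fit$aic, stats::AIC(stats::lm(y ~ 1, d)))
  expect_error(stepwise_lm(d[1:3, ], "y", c("x1", "x2", "x3")), "n >")
})

test_that("the zero-variance GLMM path matches an independent IRLS oracle", {
  set.seed(22)
  n <- 24
  d <- data.frame(block = factor(rep(1:4, 6)), x = rnorm(n))
  eta <- -1 + 0.8 * d$x
  d$depth <- 500L
  d$succ <- rbinom(n, d$depth, plogis(eta))
  fit <- logistic_glmm(d, "succ", "depth", "x", "block",
                       re_variance = "zero")
  X <- cbind(1, d$x)
  beta <- irls_binomial_oracle(X, d$succ, d$depth)
  expect_equal(unname(fit$coefficients$estimate), unname(beta),
               tolerance = 1e-6)
  expect_equal(fit$re_sd, 0)
  expect_equal(fit$coefficients$odds_ratio,
               exp(fit$coefficients$estimate), tolerance = 1e-12)
  expect_error(logistic_glmm(transform(d, succ = depth + 1), "succ",
                             "depth", "x", "block"), "exceed")
})

test_that("the GLMM estimates a real random-block effect and AIC selection works", {
  set.seed(23)
  n <- 32
  d <- data.frame(block = factor(rep(1:8, 4)), x = rnorm(n),
                  z = rnorm(n))
  b <- rnorm(8, 0, 1)
  eta <- -0.5 + 1.2 * d$x + b[as.integer(d$block)]
  d$depth <- 400L
  d$succ <- rbinom(n, d$depth, plogis(eta))
  fit <- logistic_glmm(d, "succ", "depth", c("x", "z"), "block",
                       select = "aic", nagq = 5)
  expect_true("x" %in% fit$selected)
  expect_gt(fit$re_sd, 0.3)
  cf <- fit$coefficients
  expect_gt(cf$estimate[cf$term == "x"], 0)
})
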