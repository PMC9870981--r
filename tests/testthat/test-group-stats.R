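test_that("summary-statistics ANOVA matches closed-form arithmetic", {
  s <- group_summary(c("a", "b"), n = c(3, 3), mean = c(0, 2), sd = c(1, 1))
  av <- anova_from_summary(s)
  expect_equal(av$ss_between, 6)
  expect_equal(av$ss_within, 4)
  expect_equal(av$F, 6)
  expect_equal(av$p, pf(6, 1, 4, lower.tail = FALSE), tolerance = 1e-12)
  expect_equal(round(av$p, 4), 0.0705)
  eq <- group_summary(c("a", "b", "c"), n = c(4, 4, 4), mean = c(1, 1, 1),
                      sd = c(1, 2, 1))
  expect_equal(anova_from_summary(eq)$F, 0)
  expect_error(anova_from_summary(
    group_summary(c("a", "b"), c(3, 3), c(1, 1), c(0, 0))),
    class = "gcxi_degenerate_anova")
})

test_that("summary ANOVA is identical to raw-data aov on random data", {
  set.seed(31)
  for (i in 1:20) {
    k <- sample(2:5, 1)
    data <- do.call(rbind, lapply(seq_len(k), function(g) {
      data.frame(group = paste0("g", g),
                 value = rnorm(sample(3:9, 1), rnorm(1, 0, 2),
                               runif(1, 0.5, 2)))
    }))
    av <- anova_from_summary(summarize_groups(data))
    ref <- summary(aov(value ~ group, data))[[1]]
    expect_equal(av$F, ref[["F value"]][1], tolerance = 1e-10)
    expect_equal(av$p, ref[["Pr(>F)"]][1], tolerance = 1e-10)
  }
})

test_that("with a single treatment group Dunnett reduces to the pooled t-test", {
  s <- group_summary(c("C", "T"), n = c(5, 10), mean = c(0, 1.2),
                     sd = c(1, 1.1))
  dn <- dunnett_vs_control(s, "C")
  expect_lt(abs(dn$p_adjusted - dn$p_unadjusted), 1e-4)
  expect_equal(dn$p_unadjusted, 2 * pt(abs(dn$t), 13, lower.tail = FALSE),
               tolerance = 1e-12)
})

test_that("Dunnett adjusted p agrees with a Monte-Carlo max-|T| oracle", {
  configs <- list(
    list(n = c(9, 7, 5, 6, 6, 8), q = 2.5),
    list(n = c(5, 5, 5), q = 2.0),
    list(n = c(20, 8, 12, 10), q = 3.0))
  for (cf in configs) {
    n0 <- cf$n[1]; ni <- cf$n[-1]
    lambda <- sqrt(ni / (ni + n0))
    df <- sum(cf$n) - length(cf$n)
    p_quad <- gcxi:::dunnett_tail_p(cf$q, lambda, df)
    p_mc <- mc_dunnett_tail(cf$q, lambda, df, n = 2e5, seed = 17)
    expect_lt(abs(p_quad - p_mc), 0.005)
    if (requireNamespace("mvtnorm", quietly = TRUE)) {
      corr <- outer(lambda, lambda); diag(corr) <- 1
      p_ref <- 1 - mvtnorm::pmvt(
        lower = -rep(cf$q, length(lambda)), upper = rep(cf$q, length(lambda)),
        df = df, corr = corr,
        algorithm = mvtnorm::GenzBretz(abseps = 1e-5, maxpts = 1e6))[1]
      expect_lt(abs(p_quad - p_ref), 1e-4)
    }
  }
})

test_that("Dunnett p is monotone in |t| and never below the unadjusted p", {
  s <- group_summary(c("C", "A", "B", "D"), n = c(8, 6, 7, 9),
                     mean = c(0, 0.5, 1.5, 2.5), sd = c(1, 1.2, 0.9, 1.1))
  dn <- dunnett_vs_control(s, "C")
  expect_true(all(dn$p_adjusted >= dn$p_unadjusted - 1e-6))
  ord <- order(abs(dn$t))
  expect_true(all(diff(dn$p_adjusted[ord]) <= 1e-9))
})

test_that("the printed syndecan-1 summaries reproduce the published control contrast", {
  syn <- study_endpoint_summaries("syndecan-1")
  dn <- dunnett_vs_control(syn, "C")
  nsns <- dn[dn$group == "NS-NS", ]
  expect_equal(nsns$t, 3.7396, tolerance = 1e-3)
  expect_lte(nsns$p_adjusted, 0.01)
  expect_equal(nsns$flag, "**")
  # all other groups are not significantly different from control
  expect_true(all(dn$p_adjusted[dn$group != "NS-NS"] > 0.05))
})

test_that("Kaplan-Meier curves match hand-computed product limits", {
  no_ev <- data.frame(group = "g", time = c(7, 7, 7), event = 0)
  km <- km_curve(no_ev)
  expect_true(all(km$surv == 1))
  two <- data.frame(group = "g", time = c(1, 2), event = 1)
  km <- km_curve(two)
  expect_equal(km_surv_at(km, c(0, 1, 2)), c(1, 0.5, 0))
  mix <- data.frame(group = "g", time = c(1, 2, 3, 7),
                    event = c(1, 0, 1, 0))
  km <- km_curve(mix)
  # hand product limit: (1 - 1/4) at day 1, censor at 2, (1 - 1/2) at day 3
  expect_equal(km_surv_at(km, c(1, 2.5, 3)), c(3 / 4, 3 / 4, 3 / 8))
  expect_true(all(diff(km$surv) <= 0))
  expect_equal(km$surv[km$time == 0], 1)
  expect_error(km_curve(mix, group = "absent"), class = "gcxi_empty_group")
})

test_that("log-rank test matches hand tallies and is null for identical groups", {
  same <- data.frame(group = rep(c("a", "b"), each = 3),
                     time = rep(c(1, 2, 3), 2), event = 1)
  lr <- logrank_test(same)
  expect_equal(lr$chisq, 0, tolerance = 1e-12)
  expect_equal(lr$p, 1, tolerance = 1e-9)
  hand <- data.frame(group = c("A", "A", "B", "B"),
                     time = c(1, 2, 7, 7), event = c(1, 1, 0, 0))
  lr <- logrank_test(hand)
  expect_equal(lr$chisq, 49 / 17, tolerance = 1e-9)  # hypergeometric tally
  none <- data.frame(group = c("a", "b"), time = c(7, 7), event = 0)
  expect_error(logrank_test(none), class = "gcxi_no_events")
})

test_that("log-rank asymptotic p agrees with a permutation reference", {
  set.seed(12)
  d <- data.frame(group = rep(c("a", "b"), each = 20),
                  time = c(rexp(20, 0.25), rexp(20, 0.45)))
  d$event <- as.integer(d$time <= 7)
  d$time <- pmin(d$time, 7)
  obs <- logrank_test(d)
  perm <- vapply(1:1000, function(i) {
    dd <- d; dd$group <- sample(dd$group)
    logrank_test(dd)$chisq
  }, 0)
  p_perm <- mean(perm >= obs$chisq)
  expect_lt(abs(p_perm - obs$p), 0.05)
})
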