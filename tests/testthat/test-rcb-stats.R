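test_that("EMS ANOVA matches the brute-force balanced decomposition", {
  d <- simulate_movement_dataset(cultivars = 2, planting_dates = 2, reps = 2,
                                 cultivar_effects = c(0, 0.2),
                                 planting_date_effects = c(0, -0.1),
                                 position_effects = c(0.05, -0.05),
                                 sigma = 0.08, seed = 17)
  an <- anova_ems(d, "response")
  oracle <- ems_anova_oracle(d)
  expect_equal(an$table$ss, oracle$ss, tolerance = 1e-8)
  expect_equal(an$table$df, oracle$df)
  expect_equal(an$table$f[1:5], oracle$f, tolerance = 1e-8)
  # p values come from the F distribution at the ratio's df
  expect_equal(an$table$p[1],
               pf(oracle$f[1], oracle$df[1], oracle$df[5], lower.tail = FALSE))
  expect_equal(an$table$p[2],
               pf(oracle$f[2], oracle$df[2], oracle$df[3], lower.tail = FALSE))
  # components + residual = total
  y <- d$response
  expect_equal(sum(an$table$ss), sum((y - mean(y))^2), tolerance = 1e-10)
  expect_equal(sum(an$table$df), nrow(d) - 1)
})

test_that("a constant response yields zero SS and NA F ratios", {
  d <- simulate_movement_dataset(cultivars = 2, planting_dates = 2, reps = 2,
                                 sigma = 0, seed = 1)
  d$response <- 1.37
  an <- anova_ems(d, "response")
  expect_equal(an$table$ss, rep(0, 6), tolerance = 1e-20)
  expect_true(all(is.na(an$table$f)))
})

test_that("tidy and glance expose the fit in broom shape", {
  d <- simulate_movement_dataset(seed = 2)
  an <- anova_ems(d, "response")
  td <- tidy(an)
  expect_named(td, c("term", "df", "sumsq", "meansq", "statistic", "p.value"))
  expect_equal(nrow(td), 6)
  g <- glance(an)
  expect_equal(g$nobs, nrow(d))
})

test_that("rejection rates rise with the simulated cultivar effect", {
  sizes <- c(0, 0.1, 0.3, 0.5)
  rates <- vapply(sizes, function(es) {
    rej <- vapply(1:40, function(s) {
      d <- simulate_movement_dataset(cultivars = 4, planting_dates = 2,
                                     reps = 2,
                                     cultivar_effects = c(0, 0, 0, es),
                                     sigma = 0.15, seed = 1000 + s * 7 + es * 131)
      anova_ems(d, "response")$table$p[1] < 0.05
    }, TRUE)
    mean(rej)
  }, 0)
  expect_true(all(diff(rates) >= 0))
  expect_lt(rates[1], 0.2)
  expect_gt(rates[4], 0.8)
})

test_that("cultivar means are recovered within the LSD at trial replication", {
  # 16 cultivars x 4 planting dates x 2 positions x 2 reps, as in the trial
  truth <- seq(-0.15, 0.15, length.out = 16)
  hits <- 0; total <- 0
  for (s in 1:10) {
    d <- simulate_movement_dataset(cultivars = 16, planting_dates = 4,
                                   reps = 2, cultivar_effects = truth,
                                   sigma = 0.12, seed = 300 + s)
    an <- anova_ems(d, "response")
    ms <- lsd_mean_separation(an, "cultivar")
    den <- ms$denominator
    est <- ms$means
    n_per <- est$n[1]
    lsd <- qt(0.975, den$df) * sqrt(2 * den$ms / n_per)
    truth_means <- 1.37 + truth[as.integer(sub("C", "", est$level))]
    hits <- hits + sum(abs(est$mean - truth_means) <= lsd)
    total <- total + nrow(est)
  }
  expect_gte(hits / total, 0.95)
})

test_that("LSD letters separate only true differences", {
  # identical means, tiny noise -> one shared letter
  d0 <- simulate_movement_dataset(cultivars = 2, planting_dates = 2, reps = 2,
                                  sigma = 0.01, seed = 5)
  m0 <- lsd_mean_separation(anova_ems(d0, "response"), "cultivar")
  expect_equal(m0$means$letters, c("a", "a"))
  # a 10-sigma separation -> distinct letters
  d1 <- simulate_movement_dataset(cultivars = 2, planting_dates = 2, reps = 2,
                                  cultivar_effects = c(0, 1), sigma = 0.05,
                                  seed = 6)
  m1 <- lsd_mean_separation(anova_ems(d1, "response"), "cultivar")
  expect_equal(sort(m1$means$letters), c("a", "b"))
  # mu, mu, mu + Delta: the two equal levels share, the third stands alone
  d2 <- simulate_movement_dataset(cultivars = 3, planting_dates = 2, reps = 4,
                                  cultivar_effects = c(0, 0, 2), sigma = 0.05,
                                  seed = 7)
  m2 <- lsd_mean_separation(anova_ems(d2, "response"), "cultivar")
  top <- m2$means[m2$means$mean > 3, ]
  rest <- m2$means[m2$means$mean < 3, ]
  expect_equal(top$letters, "a")
  expect_equal(rest$letters, c("b", "b"))
})

test_that("correction choices change adjusted p values monotonically", {
  d <- simulate_movement_dataset(cultivars = 4, planting_dates = 2, reps = 2,
                                 cultivar_effects = c(0, 0.05, 0.1, 0.15),
                                 sigma = 0.1, seed = 11)
  an <- anova_ems(d, "response")
  p_none <- lsd_mean_separation(an, "cultivar", correction = "none")$pairwise$p.adj
  p_fdr <- lsd_mean_separation(an, "cultivar", correction = "fdr")$pairwise$p.adj
  p_bon <- lsd_mean_separation(an, "cultivar", correction = "bonferroni")$pairwise$p.adj
  expect_true(all(p_none <= p_fdr + 1e-12))
  expect_true(all(p_fdr <= p_bon + 1e-12))
  expect_error(lsd_mean_separation(an, "nope"), "unknown factor")
})

test_that("demarcation agreement reports per-plot correlations and position test", {
  set.seed(33)
  n <- 600
  base <- lapply(1:6, function(i) 0.6 + 0.05 * sin(2 * pi * 1.5 * (1:n) / 24 + i))
  mk <- function(values) {
    tibble::tibble(frame = rep(1:n, 6),
                   plot = rep(sprintf("Cv%d_oat_1A", 1:6), each = n),
                   value = unlist(values))
  }
  manual <- mk(base)
  positions <- tibble::tibble(plot = sprintf("Cv%d_oat_1A", 1:6),
                              position = rep(c("inner", "outer"), each = 3))
  # identical sets: r = 1 everywhere
  agr <- demarcation_agreement(manual, manual, positions)
  expect_equal(agr$per_plot$r, rep(1, 6), tolerance = 1e-12)
  # sign flip: r = -1
  neg <- mk(lapply(base, function(b) -b))
  agr_neg <- demarcation_agreement(manual, neg, positions)
  expect_equal(agr_neg$per_plot$r, rep(-1, 6), tolerance = 1e-12)
  # noisy copy at SNR 10: expected attenuation 1/sqrt(1 + 1/SNR^2)
  snr <- 10
  noisy <- mk(lapply(base, function(b) {
    b + rnorm(n, 0, sd(b) / snr)
  }))
  agr_n <- demarcation_agreement(manual, noisy, positions)
  expect_equal(mean(agr_n$per_plot$r), 1 / sqrt(1 + 1 / snr^2),
               tolerance = 0.01)
  expect_error(demarcation_agreement(manual, mk(base)[1:n, ], positions),
               "different plots")
})

test_that("agreement separates degraded outer positions", {
  set.seed(44)
  n <- 400
  plots <- sprintf("Cv%d_oat_1A", 1:12)
  positions <- tibble::tibble(plot = plots,
                              position = rep(c("inner", "outer"), each = 6))
  base <- lapply(1:12, function(i) sin(2 * pi * 1.5 * (1:n) / 24 + i))
  noise_sd <- ifelse(positions$position == "inner", 0.1, 1.2)
  auto <- lapply(1:12, function(i) base[[i]] + rnorm(n, 0, noise_sd[i]))
  mk <- function(v) tibble::tibble(frame = rep(1:n, 12),
                                   plot = rep(plots, each = n),
                                   value = unlist(v))
  agr <- demarcation_agreement(mk(base), mk(auto), positions)
  expect_lt(agr$p.value, 0.05)
  gm <- agr$group_means
  expect_gt(gm$mean[gm$level == "inner"], gm$mean[gm$level == "outer"])
  expect_false(gm$letters[1] == gm$letters[2])
})
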