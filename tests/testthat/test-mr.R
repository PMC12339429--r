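hand_h <- function() {
  # 3-SNP worked table: exact IVW slope 0.5
  harmonized_set(beta_exp = c(0.1, 0.2, 0.3), se_exp = rep(0.01, 3),
                 beta_out = c(0.05, 0.10, 0.15), se_out = rep(0.01, 3))
}

test_that("F statistic is the squared Wald ratio", {
  expect_equal(f_statistic(0.2367, 0.0497), (0.2367 / 0.0497)^2)
  expect_equal(f_statistic(0.2367, 0.0497), 22.68, tolerance = 2e-3)
  expect_equal(f_statistic(0, 1), 0)
  expect_error(f_statistic(1, 0))
})

test_that("published instrument panel reproduces its F column from beta/SE", {
  tab <- read_gwas(system.file("extdata", "gh_exposure_instruments.tsv",
                               package = "pvmr"))
  f <- f_statistic(tab$beta, tab$se)
  expect_true(all(abs(f - tab$f_published) / tab$f_published < 0.005))
  expect_true(all(f > 10))
  expect_equal(range(tab$f_published), c(20.85, 25.33))
})

test_that("greedy clumping follows the p-order, window and r2 rules", {
  two <- as_gwas_sumstats(data.frame(
    snp_id = c("s1", "s2"), chrom = "1", pos = c(1e6, 1.005e6),
    effect_allele = "A", other_allele = "G", eaf = 0.3,
    beta = c(0.3, 0.25), se = 0.05, p = c(1e-8, 1e-7), n = 1000))
  ld <- data.frame(snp_i = "s1", snp_j = "s2", r2 = 0.9)
  kept <- select_instruments(two, ld = ld)
  expect_equal(kept$snp_id, "s1")
  excl <- attr(kept, "exclusions")
  expect_equal(excl$reason[excl$snp_id == "s2"], "clumped_with:s1")

  # different chromosomes: no clumping regardless of LD entries
  two$chrom <- c("1", "2")
  expect_equal(nrow(select_instruments(two, ld = NULL)), 2L)

  # weak instruments dropped after clumping
  weak <- two
  weak$beta <- c(0.3, 0.01)
  kept2 <- select_instruments(weak)
  expect_equal(kept2$snp_id, "s1")
  excl2 <- attr(kept2, "exclusions")
  expect_equal(excl2$reason[excl2$snp_id == "s2"], "weak_instrument")

  # p-value screen exclusions are logged
  two$p <- c(1e-8, 1e-3)
  kept3 <- select_instruments(two)
  excl3 <- attr(kept3, "exclusions")
  expect_equal(excl3$reason[excl3$snp_id == "s2"], "p_above_threshold")

  expect_error(select_instruments(two, p_thresh = 1e-20),
               "no instruments")
})

test_that("clumping a block-structured panel matches the exhaustive oracle", {
  cfg <- gwas_sim_config(seed = 31,
                         ld_blocks = list(sizes = c(5, 3, 1, 4), r2 = 0.9,
                                          spacing_kb = 5, gap_kb = 20000))
  panel <- simulate_ld_panel(cfg)
  kept <- select_instruments(panel$snps, ld = panel$ld, f_min = 0)
  expect_equal(sort(kept$snp_id),
               clump_oracle(panel$snps, panel$ld, 0.001, 10000))
  # one survivor per block when blocks are unlinked and far apart
  expect_equal(nrow(kept), 4L)

  # single block of 5 at r2 = 0.9 retains exactly one SNP
  cfg1 <- gwas_sim_config(seed = 32, ld_blocks = list(sizes = 5, r2 = 0.9))
  p1 <- simulate_ld_panel(cfg1)
  expect_equal(nrow(select_instruments(p1$snps, ld = p1$ld, f_min = 0)), 1L)

  # randomized layouts against the oracle
  for (seed in 33:36) {
    cfgr <- gwas_sim_config(seed = seed,
                            ld_blocks = list(
                              sizes = sample(1:4, 3, replace = TRUE),
                              r2 = sample(c(0.0005, 0.5, 0.95), 1),
                              gap_kb = sample(c(5, 20000), 1)))
    pr <- simulate_ld_panel(cfgr)
    keptr <- select_instruments(pr$snps, ld = pr$ld, f_min = 0)
    expect_equal(sort(keptr$snp_id),
                 clump_oracle(pr$snps, pr$ld, 0.001, 10000))
  }
})

test_that("harmonization aligns, flips and drops alleles correctly", {
  exp <- as_gwas_sumstats(data.frame(
    snp_id = c("a", "b", "c", "d"),
    effect_allele = c("T", "A", "A", "C"),
    other_allele = c("G", "T", "G", "T"),
    eaf = c(0.3, 0.50, 0.2, 0.4), beta = c(0.2, 0.1, 0.3, 0.15),
    se = 0.05, n = 1000))
  out <- as_gwas_sumstats(data.frame(
    snp_id = c("a", "b", "c", "d"),
    effect_allele = c("G", "A", "A", "C"),
    other_allele = c("T", "T", "C", "T"),
    eaf = c(0.6, 0.5, 0.2, 0.4), beta = c(0.2, 0.1, 0.3, 0.25),
    se = 0.04, n = 5000))
  h <- harmonize(exp, out)
  excl <- attr(h, "exclusions")
  # a: swapped alleles -> beta flipped, eaf complemented
  expect_equal(h$beta_out[h$snp_id == "a"], -0.2)
  expect_equal(h$eaf_out[h$snp_id == "a"], 0.4)
  # b: palindromic A/T at eaf 0.50 -> dropped
  expect_false("b" %in% h$snp_id)
  expect_true(any(excl$snp_id == "b" & excl$reason == "palindromic_ambiguous"))
  # c: allele pair irreconcilable -> dropped
  expect_true(any(excl$snp_id == "c" & excl$reason == "allele_mismatch"))
  # d: direct match -> untouched
  expect_equal(h$beta_out[h$snp_id == "d"], 0.25)
  expect_equal(nrow(h), 2L)

  expect_error(harmonize(exp, out[0, ]), "no overlapping")
})

test_that("harmonization intersects a larger exposure panel down to k", {
  sim <- simulate_gwas_pair(gwas_sim_config(k_snps = 16, seed = 9))
  out9 <- sim$outcome[1:9, ]
  h <- harmonize(sim$exposure, out9)
  expect_equal(nrow(h), 9L)
  excl <- attr(h, "exclusions")
  expect_equal(sum(excl$reason == "absent_from_outcome"), 7L)
})

test_that("IVW matches its closed form and degenerate cases", {
  h <- hand_h()
  fit <- mr_ivw(h)
  expect_equal(fit$beta, 0.5, tolerance = 1e-12)
  expect_equal(fit$extras$Q, 0, tolerance = 1e-18)

  # identical ratios: estimate is the common ratio, Q = 0
  h2 <- harmonized_set(c(0.2, 0.4, 0.25), rep(0.02, 3),
                       c(0.2, 0.4, 0.25) * 0.7, c(0.1, 0.2, 0.15))
  fit2 <- mr_ivw(h2)
  expect_equal(fit2$beta, 0.7, tolerance = 1e-12)
  expect_equal(fit2$extras$Q, 0, tolerance = 1e-12)

  # k = 1 reduces to the Wald ratio only when explicitly requested
  h1 <- harmonized_set(0.2, 0.02, 0.1, 0.05)
  expect_error(mr_ivw(h1), "at least 2")
  expect_equal(mr_ivw(h1, allow_single = TRUE)$beta, 0.5)

  # random-effects SE never narrower than fixed-effect
  set.seed(4)
  h3 <- harmonized_set(runif(8, 0.1, 0.4), rep(0.03, 8),
                       rnorm(8, 0.1, 0.2), runif(8, 0.08, 0.2))
  expect_gte(mr_ivw(h3, random_effects = TRUE)$se,
             mr_ivw(h3, random_effects = FALSE)$se)
})

test_that("Egger regression estimates slope and intercept with t inference", {
  # constrained-intercept equivalence: with zero intercept data the slope
  # approaches the fixed-effect IVW slope
  set.seed(12)
  bx <- runif(10, 0.1, 0.5)
  h <- harmonized_set(bx, rep(0.02, 10), 0.4 * bx + rnorm(10, 0, 0.05),
                      rep(0.12, 10))
  eg <- mr_egger(h)
  expect_equal(length(eg$extras$intercept), 1L)
  expect_true(is.finite(eg$extras$intercept_p))

  # exact collinear exposure effects: flagged error, never a silent number
  hc <- harmonized_set(rep(0.3, 5), rep(0.02, 5), rnorm(5, 0.1, 0.1),
                       rep(0.1, 5))
  expect_error(mr_egger(hc), "identifiable")

  expect_error(mr_egger(hand_h()[1:2, ]), "at least 3")

  # weighted-least-squares oracle via stats::lm
  lmfit <- lm(beta_out ~ beta_exp, data = h, weights = 1 / h$se_out^2)
  expect_equal(eg$beta, unname(coef(lmfit)[2]), tolerance = 1e-10)
  expect_equal(eg$extras$intercept, unname(coef(lmfit)[1]), tolerance = 1e-10)
  sm <- summary(lmfit)
  expect_equal(eg$se, unname(sm$coefficients[2, 2]) / min(1, sm$sigma),
               tolerance = 1e-9)
})

test_that("Egger with intercept constrained to zero equals fixed-effect IVW", {
  set.seed(13)
  bx <- runif(7, 0.1, 0.5)
  h <- harmonized_set(bx, rep(0.02, 7), 0.3 * bx + rnorm(7, 0, 0.08),
                      runif(7, 0.08, 0.2))
  # constraining the Egger intercept to zero is exactly the weighted
  # through-origin regression, i.e. the fixed-effect IVW slope
  w <- 1 / h$se_out^2
  slope0 <- sum(w * h$beta_exp * h$beta_out) / sum(w * h$beta_exp^2)
  expect_equal(mr_ivw(h, random_effects = FALSE)$beta, slope0,
               tolerance = 1e-9)
  lm0 <- lm(beta_out ~ 0 + beta_exp, data = h, weights = w)
  expect_equal(slope0, unname(coef(lm0)[1]), tolerance = 1e-9)
})

test_that("weighted median interpolates the weighted ratio distribution", {
  # equal weights on ratios 1, 2, 3 -> plain median 2
  h <- harmonized_set(c(1, 1, 1), rep(0.02, 3), c(1, 2, 3), rep(0.1, 3))
  fit <- mr_weighted_median(h, n_boot = 200, seed = 1)
  expect_equal(fit$beta, 2)

  # weight concentrated on one SNP pulls the estimate to its ratio
  h2 <- harmonized_set(c(1, 1, 1), rep(0.02, 3), c(1, 2, 3),
                       c(1e-4, 10, 10))
  expect_equal(mr_weighted_median(h2, n_boot = 200, seed = 1)$beta, 1,
               tolerance = 1e-3)

  # 5-SNP fixture vs an independently-coded interpolation oracle
  h5 <- harmonized_set(c(0.2, 0.25, 0.4, 0.1, 0.3), rep(0.02, 5),
                       c(0.12, 0.05, 0.24, 0.01, 0.33),
                       c(0.05, 0.04, 0.1, 0.02, 0.06))
  r <- h5$beta_out / h5$beta_exp
  w <- (abs(h5$beta_exp) / h5$se_out)^2
  ord <- order(r); rs <- r[ord]; ws <- w[ord] / sum(w)
  cum <- cumsum(ws) - ws / 2
  i <- findInterval(0.5, cum)
  oracle <- rs[i] + (rs[i + 1] - rs[i]) * (0.5 - cum[i]) / (cum[i + 1] - cum[i])
  expect_equal(mr_weighted_median(h5, n_boot = 200, seed = 2)$beta, oracle)

  expect_error(mr_weighted_median(hand_h()[1:2, ], n_boot = 200), "at least 3")
})

test_that("mode estimators find the kernel-density argmax", {
  # bimodal ratios {1,1,1,5,5}: simple mode at the majority cluster
  h <- harmonized_set(rep(1, 5), rep(0.02, 5), c(1, 1, 1, 5, 5),
                      rep(0.2, 5))
  sm <- mr_mode(h, "simple", n_boot = 200, seed = 3)
  # the kernel is wide here (bandwidth ~1.4), so the argmax sits near but
  # not exactly on the majority cluster
  expect_equal(sm$beta, 1, tolerance = 0.1)

  # explicit grid evaluation oracle (mad is 0 here, so the scale is the sd)
  r <- c(1, 1, 1, 5, 5)
  s <- 0.9 * sd(r) * 5^(-1 / 5)
  grid <- seq(min(r) - 3 * s, max(r) + 3 * s, length.out = 512)
  dens <- vapply(grid, function(g) sum(dnorm(g - r, sd = s) / 5), numeric(1))
  expect_equal(sm$beta, grid[which.max(dens)])

  # weights favoring the {5,5} cluster shift the weighted mode there
  h2 <- harmonized_set(rep(1, 5), rep(0.02, 5), c(1, 1, 1, 5, 5),
                       c(10, 10, 10, 0.05, 0.05))
  wm <- mr_mode(h2, "weighted", n_boot = 200, seed = 4)
  expect_equal(wm$beta, 5, tolerance = 0.05)

  # unimodal symmetric ratios: mode close to median
  set.seed(5)
  rr <- rnorm(15, 2, 0.1)
  h3 <- harmonized_set(rep(1, 15), rep(0.02, 15), rr, rep(0.1, 15))
  expect_equal(mr_mode(h3, "simple", n_boot = 200, seed = 6)$beta,
               median(rr), tolerance = 0.1)
})

test_that("Cochran's Q matches the ratio-form oracle and its chi-square tail", {
  set.seed(14)
  bx <- runif(9, 0.1, 0.5)
  h <- harmonized_set(bx, rep(0.02, 9), 0.3 * bx + rnorm(9, 0, 0.1),
                      runif(9, 0.08, 0.2))
  q <- cochran_q(h, "ivw")
  expect_equal(q$df, 8L)
  expect_equal(q$p, pchisq(q$Q, 8, lower.tail = FALSE))
  # independent ratio-form oracle with first-order weights
  wr <- (h$se_out / h$beta_exp)^-2
  beta_fixed <- sum(wr * (h$beta_out / h$beta_exp)) / sum(wr)
  q_oracle <- sum(wr * (h$beta_out / h$beta_exp - beta_fixed)^2)
  expect_equal(q$Q, q_oracle, tolerance = 1e-6)

  qe <- cochran_q(h, "egger")
  expect_equal(qe$df, 7L)
  expect_lte(qe$Q, q$Q + 1e-12)  # adding the intercept cannot increase RSS

  # identical ratios: Q = 0, p = 1
  h0 <- harmonized_set(c(0.1, 0.2, 0.4), rep(0.02, 3),
                       c(0.05, 0.10, 0.20), rep(0.1, 3))
  q0 <- cochran_q(h0, "ivw")
  expect_equal(q0$Q, 0, tolerance = 1e-12)
  expect_equal(q0$p, 1)
})

test_that("leave-one-out rows match independent two-SNP recomputation", {
  h <- harmonized_set(c(0.1, 0.2, 0.3), rep(0.01, 3),
                      c(0.08, 0.1, 0.12), c(0.02, 0.03, 0.04))
  loo <- mr_leave_one_out(h)
  expect_equal(nrow(loo), 4L)
  expect_equal(loo$excluded[1], "(none)")
  for (j in 1:3) {
    keep <- setdiff(1:3, j)
    w <- 1 / h$se_out[keep]^2
    bhat <- sum(w * h$beta_exp[keep] * h$beta_out[keep]) /
      sum(w * h$beta_exp[keep]^2)
    expect_equal(loo$beta[j + 1], bhat, tolerance = 1e-12)
  }

  # identical ratios: every row equals the full estimate, nothing influential
  h0 <- harmonized_set(c(0.1, 0.2, 0.4), rep(0.02, 3),
                       c(0.05, 0.10, 0.20), rep(0.1, 3))
  loo0 <- mr_leave_one_out(h0)
  expect_true(all(abs(loo0$beta - loo0$beta[1]) < 1e-12))
  expect_false(attr(loo0, "influential"))

  # a grossly displaced SNP is influential by the fixed-effect CI-leave rule
  hd <- harmonized_set(rep(c(0.2, 0.3), 4), rep(0.02, 8),
                       c(rep(c(0.06, 0.09), 3), 0.06, 2.0),
                       rep(0.05, 8))
  expect_true(attr(mr_leave_one_out(hd, random_effects = FALSE),
                   "influential"))
})

test_that("odds-ratio conversion matches the published headline estimate", {
  # beta back-solved from the published OR 1.415 with p = 0.046
  conv <- beta_to_or(0.3472, 0.1740)
  expect_equal(conv$or, 1.415, tolerance = 1e-3)
  expect_equal(conv$ci_low, 1.006, tolerance = 1e-3)
  expect_equal(conv$ci_high, 1.990, tolerance = 1e-3)

  conv0 <- beta_to_or(0, 0.2)
  expect_equal(conv0$or, 1)
  expect_equal(conv0$ci_low, exp(-1.96 * 0.2))

  # widening se widens the interval, point unchanged
  c1 <- beta_to_or(0.3, 0.1); c2 <- beta_to_or(0.3, 0.2)
  expect_equal(c1$or, c2$or)
  expect_lt(c1$ci_high - c1$ci_low, c2$ci_high - c2$ci_low)
})

test_that("estimators are scale-equivariant in the exposure units", {
  set.seed(15)
  bx <- runif(9, 0.1, 0.5)
  h <- harmonized_set(bx, rep(0.02, 9), 0.35 * bx + rnorm(9, 0, 0.05),
                      runif(9, 0.08, 0.2))
  h2 <- h
  h2$beta_exp <- h$beta_exp * 2
  h2$se_exp <- h$se_exp * 2
  expect_equal(mr_ivw(h2)$beta, mr_ivw(h)$beta / 2, tolerance = 1e-9)
  expect_equal(mr_egger(h2)$beta, mr_egger(h)$beta / 2, tolerance = 1e-9)
  expect_equal(mr_weighted_median(h2, n_boot = 100, seed = 1)$beta,
               mr_weighted_median(h, n_boot = 100, seed = 1)$beta / 2,
               tolerance = 1e-9)
  expect_equal(mr_mode(h2, "weighted", n_boot = 100, seed = 1)$beta,
               mr_mode(h, "weighted", n_boot = 100, seed = 1)$beta / 2,
               tolerance = 1e-6)
})

test_that("mr_fit assembles the five-estimator bundle with S3 methods", {
  sim <- simulate_gwas_pair(gwas_sim_config(seed = 17))
  h <- harmonize(sim$exposure, sim$outcome)
  fit <- mr_fit(h, n_boot = 150, seed = 8)
  expect_s3_class(fit, "mr_fit")
  expect_equal(nrow(fit$estimates), 5L)
  expect_setequal(names(fit$fits),
                  c("ivw", "egger", "weighted_median", "simple_mode",
                    "weighted_mode"))
  expect_equal(unname(coef(fit)), fit$estimates$beta)
  ci <- confint(fit)
  expect_true(all(ci[, 1] < fit$estimates$beta & fit$estimates$beta < ci[, 2]))
  expect_output(print(fit), "Inverse variance weighted")
  expect_output(print(summary(fit)), "Egger intercept")
  # or columns consistent with beta/se
  expect_equal(fit$estimates$or, exp(fit$estimates$beta))
  expect_equal(fit$estimates$ci_low, exp(fit$estimates$beta -
                                           1.96 * fit$estimates$se))

  # insufficient instruments: secondary estimators skipped with reasons
  fit2 <- mr_fit(h[1:2, ], n_boot = 150, seed = 8)
  expect_equal(names(fit2$fits), "ivw")
  expect_setequal(names(fit2$skipped),
                  c("egger", "weighted_median", "simple_mode",
                    "weighted_mode"))
})

test_that("MR-PRESSO flags a displaced instrument and spares clean sets", {
  sim <- simulate_gwas_pair(gwas_sim_config(seed = 19))
  h <- harmonize(sim$exposure, sim$outcome)
  clean <- mr_presso(h, n_sim = 1000, seed = 5)
  expect_false(any(clean$outliers$flag))
  expect_gt(clean$global_p, 0.05)

  hd <- h
  hd$beta_out[4] <- hd$beta_out[4] + 10 * hd$se_out[4]
  dirty <- mr_presso(hd, n_sim = 1000, seed = 5)
  expect_true(dirty$outliers$flag[4])
  # matched-seed comparison: the displaced SNP strictly reduces global p
  expect_lt(dirty$global_p, clean$global_p)

  expect_error(mr_presso(h[1:3, ], n_sim = 1000), "at least 4")
})
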