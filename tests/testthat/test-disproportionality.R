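test_that("contingency cells count reports once, with set semantics", {
  rs <- make_report_set(
    c("r1", "r2", "r3", "r4"),
    list("d", "d", "x", "x"),
    list(1, 2, 1, 2))
  t <- contingency_table(rs, "d", 1)
  expect_equal(c(t$a, t$b, t$c, t$d), c(1, 1, 1, 1))

  # a report listing the drug twice and the PT twice contributes 1 to a
  rs2 <- make_report_set("r1", list(c("d", "d")), list(c(1, 1)))
  t2 <- contingency_table(rs2, "d", 1)
  expect_equal(c(t2$a, t2$b, t2$c, t2$d), c(1, 0, 0, 0))

  empty <- filter_by_pt(rs, 999999)  # no record carries this PT
  expect_error(contingency_table(empty, "d", 1), "empty")
})

test_that("contingency table equals a brute-force recount on simulated data", {
  rs <- simulate_srs(srs_config(n_reports = 3000, p_drug = 0.05,
                                p_event_background = 0.01, rr = 8,
                                n_decoy_pts = 5, decoy_rate = 0.02,
                                seed = 42))
  t <- contingency_table(rs, "somatropin", 10061019)
  bf <- brute_force_table(rs, "somatropin", 10061019L)
  expect_equal(c(t$a, t$b, t$c, t$d), unname(bf))
  expect_equal(sum(bf), n_reports(rs))
})

test_that("ROR point, interval and criterion follow the log-normal form", {
  s <- ror(contab(10, 10, 10, 10))
  expect_equal(s$point, 1.0)
  expect_false(s$flag)

  s2 <- ror(contab(20, 80, 100, 9800))
  expect_equal(s2$point, 24.5)
  expect_equal(s2$ci_low, 14.448, tolerance = 1e-4)
  expect_equal(s2$ci_high, 41.5456, tolerance = 1e-4)
  expect_true(s2$flag)

  # a < 3 fails the criterion regardless of the interval
  s3 <- ror(contab(2, 10, 10, 1000))
  expect_false(s3$flag)
  expect_true(s3$ci_low > 1)

  # zero cell: Haldane-Anscombe correction, noted
  s4 <- ror(contab(3, 0, 0, 997))
  expect_true(is.finite(s4$point))
  expect_true(s4$corrected)
})

test_that("PRR matches its defining ratio and chi-square criterion", {
  s <- prr(contab(10, 10, 10, 10))
  expect_equal(s$point, 1.0)
  expect_equal(s$chi2, 0.0)
  expect_false(s$flag)

  s2 <- prr(contab(20, 80, 100, 9800))
  expect_equal(s2$point, 19.8)
  chi2_oracle <- suppressWarnings(stats::chisq.test(
    matrix(c(20, 80, 100, 9800), 2, byrow = TRUE), correct = FALSE))
  expect_equal(s2$chi2, unname(chi2_oracle$statistic), tolerance = 1e-9)
  expect_equal(s2$flag, s2$point >= 2 && s2$chi2 >= 4)

  # Haldane-corrected when a cell is zero but margins are positive
  s3 <- prr(contab(3, 0, 0, 997))
  expect_true(is.finite(s3$point))
  expect_true(s3$corrected)
  expect_equal(s3$point, (3.5 / 4) / (0.5 / 998))

  expect_error(prr(contab(0, 0, 5, 5)), "margin")

  # Yates switch lowers the statistic
  sY <- prr(contab(20, 80, 100, 9800), yates = TRUE)
  expect_lt(sY$chi2, s2$chi2)
  chi2_yates <- suppressWarnings(stats::chisq.test(
    matrix(c(20, 80, 100, 9800), 2, byrow = TRUE), correct = TRUE))
  expect_equal(sY$chi2, unname(chi2_yates$statistic), tolerance = 1e-9)
})

test_that("IC is the shrinkage log2 observed-to-expected with IC025 bound", {
  # observed equals expected at large a: IC near 0, no flag
  t <- contab(100, 900, 1000, 8000)
  expected <- 1000 * 1100 / 10000
  s <- ic(t)
  expect_equal(s$point, log2(100.5 / (expected + 0.5)))

  s2 <- ic(contab(20, 80, 100, 9800))
  expect_equal(s2$point, log2(20.5 / 1.7))
  expect_equal(s2$point, log(20.5 / 1.7) / log(2))  # log-identity check
  expect_equal(s2$point, 3.592, tolerance = 1e-3)

  # IC025 plug-in at a = 3
  t3 <- contab(3, 7, 90, 9900)
  e3 <- 10 * 93 / 10000
  s3 <- ic(t3)
  expect_equal(s3$ci_low,
               log2(3.5 / (e3 + 0.5)) - 3.3 / sqrt(3.5) - 2 / 3.5^1.5)
  # shrinkage terms are positive: IC025 < IC always
  for (i in 1:50) {
    set.seed(i)
    s <- ic(random_contab())
    expect_lt(s$ci_low, s$point)
  }
})

test_that("signal verdict requires at least two positive methods", {
  t <- contab(20, 80, 100, 9800)
  stats <- list(ror(t), prr(t), ic(t))
  flags <- vapply(stats, `[[`, logical(1), "flag")
  res <- classify_signal("d", "e", stats, t)
  expect_equal(res$n_positive_methods, sum(flags))
  expect_equal(res$is_signal, sum(flags) >= 2)

  fake <- function(flag) structure(list(method = "ROR", point = 1,
                                        flag = flag),
                                   class = "signal_stat")
  expect_true(classify_signal("d", "e", list(fake(TRUE), fake(TRUE),
                                             fake(FALSE)))$is_signal)
  expect_false(classify_signal("d", "e", list(fake(TRUE), fake(FALSE),
                                              fake(FALSE)))$is_signal)
})

test_that("planted relative risk of 12 triggers all three methods", {
  rs <- simulate_srs(srs_config(n_reports = 200000, seed = 2024))
  res <- disprop(rs, "somatropin", 10061019)
  expect_true(res$is_signal)
  expect_equal(res$n_positive_methods, 3L)
  # direct criteria evaluation as oracle
  t <- res$table
  expect_true(t$a >= 3 && ror(t)$ci_low > 1)
  expect_true(prr(t)$point >= 2 && prr(t)$chi2 >= 4)
  expect_true(ic(t)$ci_low > 0)
})

test_that("all three statistics agree in sign for strictly positive tables", {
  set.seed(99)
  done <- 0
  while (done < 200) {
    t <- contab(sample(1:40, 1), sample(1:80, 1), sample(1:80, 1),
                sample(1:3000, 1))
    sr <- sign(log(ror(t)$point))
    sp <- sign(log(prr(t)$point))
    # IC shrinkage can cross zero for tiny a when obs ~ expected; compare
    # the unshrunk observed-to-expected instead for the sign identity
    n <- t$a + t$b + t$c + t$d
    si <- sign(log(t$a * n / ((t$a + t$b) * (t$a + t$c))))
    if (sr == 0 || sp == 0 || si == 0) next
    expect_equal(sr, sp)
    expect_equal(sr, si)
    done <- done + 1
  }
})

test_that("doubling all cells fixes ROR/PRR and shrinks the ROR interval", {
  t1 <- contab(8, 40, 60, 2000)
  t2 <- contab(16, 80, 120, 4000)
  expect_equal(ror(t2)$point, ror(t1)$point)
  expect_equal(prr(t2)$point, prr(t1)$point)
  w1 <- log(ror(t1)$ci_high) - log(ror(t1)$ci_low)
  w2 <- log(ror(t2)$ci_high) - log(ror(t2)$ci_low)
  expect_lt(w2, w1)
})

test_that("ROR equals PRR exactly when the non-case shares match", {
  # b/(a+b) = d/(c+d) <=> ROR = PRR; construct such a table
  t_eq <- contab(10, 30, 20, 60)   # b/(a+b) = 0.75 = d/(c+d)
  expect_equal(ror(t_eq)$point, prr(t_eq)$point, tolerance = 1e-12)
  t_neq <- contab(10, 30, 20, 100)
  expect_gt(abs(ror(t_neq)$point - prr(t_neq)$point), 1e-6)
})

test_that("volcano statistics: Fisher p, Bonferroni universe, monotonicity", {
  # single PT: m = 1, adjusted p equals raw p
  rs1 <- make_report_set(c("r1", "r2", "r3", "r4"),
                         list("d", "d", "x", "x"), list(1, 1, 1, 1))
  v1 <- volcano_stats(rs1, "d")
  expect_equal(nrow(v1), 1L)
  expect_equal(v1$p_bonferroni, v1$p_fisher)

  # balanced table: two-sided Fisher p = 1
  expect_equal(fisher_exact_p(10, 10, 10, 10), 1.0, tolerance = 1e-12)

  # multi-PT set: p matches stats::fisher.test and the hypergeometric tail
  rs <- simulate_srs(srs_config(n_reports = 4000, p_drug = 0.05,
                                p_event_background = 0.01, rr = 6,
                                n_decoy_pts = 4, decoy_rate = 0.03,
                                seed = 5))
  v <- volcano_stats(rs, "somatropin")
  expect_gte(nrow(v), 5)
  n <- n_reports(rs)
  for (i in seq_len(nrow(v))) {
    t <- contingency_table(rs, "somatropin", v$pt_code[i])
    ft <- stats::fisher.test(matrix(c(t$a, t$b, t$c, t$d), 2, byrow = TRUE))
    expect_equal(v$p_fisher[i], ft$p.value, tolerance = 1e-9)
    expect_equal(v$p_bonferroni[i], min(1, v$p_fisher[i] * nrow(v)))
  }
  expect_true(all(v$p_fisher >= 0 & v$p_fisher <= 1))
  expect_true(all(v$p_bonferroni >= v$p_fisher))
  expect_equal(v$neg_log10_p, -log10(v$p_bonferroni))
})
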