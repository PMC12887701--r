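# MR engine: selection, harmonization, estimators, sensitivity suite.

test_that("select_instruments applies greedy clumping with the window rule", {
  gwas <- data.frame(snp = c("s1", "s2", "s3"), chr = "1",
                     pos = c(1e5, 2e5, 3e5), pval = c(1e-10, 1e-9, 1e-8))
  ld <- diag(1, 3); dimnames(ld) <- list(gwas$snp, gwas$snp)
  ld["s1", "s2"] <- ld["s2", "s1"] <- 0.5
  ld["s1", "s3"] <- ld["s3", "s1"] <- 1e-4
  ld["s2", "s3"] <- ld["s3", "s2"] <- 1e-4
  expect_equal(select_instruments(gwas, ld), c("s1", "s3"))
  # nothing significant -> empty with message
  weak <- transform(gwas, pval = 1e-6)
  expect_message(out <- select_instruments(weak, ld), "no instruments")
  expect_length(out, 0)
  # SNPs 2 Mb apart in high LD: both kept (outside the 1 Mb window)
  far <- data.frame(snp = c("a", "b"), chr = "1", pos = c(1e6, 3e6),
                    pval = c(1e-10, 1e-9))
  ldf <- matrix(c(1, 0.9, 0.9, 1), 2, dimnames = list(far$snp, far$snp))
  expect_equal(select_instruments(far, ldf), c("a", "b"))
  expect_error(select_instruments(gwas, ld[1:2, 1:2]), "cover")
})

test_that("harmonize aligns effect alleles and drops ambiguous SNPs", {
  exp <- gwas_row("rs1", "A", "G", beta = 0.1)
  out <- gwas_row("rs1", "G", "A", beta = -0.05, eaf = 0.7)
  h <- harmonize(exp, out)
  expect_equal(h$beta_out, 0.05)
  expect_true(h$flipped)
  expect_equal(h$eaf_out, 0.3)
  # palindromic at maximal ambiguity -> dropped
  h2 <- harmonize(gwas_row("rs2", "A", "T", 0.1, eaf = 0.5),
                  gwas_row("rs2", "A", "T", 0.1, eaf = 0.5))
  expect_equal(nrow(h2), 0)
  expect_match(attr(h2, "dropped")$reason, "palindromic")
  # palindromic outside the window -> retained
  h3 <- harmonize(gwas_row("rs3", "A", "T", 0.1, eaf = 0.2),
                  gwas_row("rs3", "A", "T", 0.1, eaf = 0.2))
  expect_equal(nrow(h3), 1)
  # identical coding -> unchanged
  h4 <- harmonize(gwas_row("rs4", "C", "T", 0.2),
                  gwas_row("rs4", "C", "T", 0.15))
  expect_false(h4$flipped)
  expect_equal(h4$beta_out, 0.15)
  # strand-complement coding resolves for non-palindromic SNPs
  h5 <- harmonize(gwas_row("rs5", "A", "G", 0.2),
                  gwas_row("rs5", "T", "C", 0.15))
  expect_false(h5$flipped)
  # disjoint SNP sets -> "no overlap" status
  expect_message(h6 <- harmonize(gwas_row("rs6", "A", "G", 0.1),
                                 gwas_row("rs7", "A", "G", 0.1)),
                 "no overlap")
  expect_equal(nrow(h6), 0)
})

test_that("IVW matches the hand-computed weighted least squares fixture", {
  pairs <- pairs_from_ratios(c(0.5, 0.3), c(0.1, 0.2))
  est <- mr_ivw(pairs)
  # w = (100, 25): beta = 57.5/125, fixed SE = 1/sqrt(125), Q = 0.8 < df
  expect_equal(est$beta_hat, 0.46, tolerance = 1e-10)
  expect_equal(est$se_hat, sqrt(1 / 125), tolerance = 1e-10)
  expect_equal(est$q_stat, 0.8, tolerance = 1e-10)
  expect_equal(est$or_, exp(0.46))
  expect_lt(est$ci_low, est$or_); expect_gt(est$ci_high, est$or_)
  # identical ratios: estimate exact, Q = 0
  est2 <- mr_ivw(pairs_from_ratios(c(0.3, 0.3, 0.3), c(0.1, 0.1, 0.1)))
  expect_equal(est2$beta_hat, 0.3)
  expect_equal(est2$q_stat, 0)
  # OR scale is exp of the log-scale estimate
  expect_equal(exp(0.131), 1.14, tolerance = 0.005)
  # degenerate inputs
  bad <- make_pairs(c(0, 1), c(0.1, 0.3), c(0.1, 0.1))
  expect_warning(expect_error(mr_ivw(bad), ">= 2"), "zero exposure beta")
})

test_that("IVW equals generic WLS through the origin (property)", {
  for (s in 1:20) {
    h <- withr::with_seed(s, make_pairs(runif(8, 0.05, 0.3),
                                        rnorm(8, 0.05, 0.05),
                                        runif(8, 0.02, 0.1)))
    est <- mr_ivw(h)
    wls <- lm.wfit(cbind(h$beta_exp), h$beta_out, 1 / h$se_out^2)
    expect_equal(est$beta_hat, unname(wls$coefficients), tolerance = 1e-10)
  }
})

test_that("Egger recovers an exact line and the zero-intercept case", {
  pe <- make_pairs(c(0.1, 0.2, 0.3), c(0.07, 0.12, 0.17), rep(0.05, 3))
  eg <- mr_egger(pe)
  expect_equal(eg$estimate$beta_hat, 0.5, tolerance = 1e-10)
  expect_equal(eg$intercept, 0.02, tolerance = 1e-10)
  # through the origin -> zero intercept
  eg0 <- mr_egger(make_pairs(c(0.1, 0.2, 0.3), c(0.05, 0.10, 0.15),
                             rep(0.05, 3)))
  expect_equal(eg0$intercept, 0, tolerance = 1e-10)
  expect_error(mr_egger(pe[1:2, ]), ">=3")
})

test_that("Egger with constrained zero intercept reduces to IVW", {
  h <- make_pairs(c(0.12, 0.2, 0.31), c(0.05, 0.11, 0.14),
                  c(0.03, 0.05, 0.04))
  est <- mr_ivw(h)
  wls0 <- lm.wfit(cbind(h$beta_exp), h$beta_out, 1 / h$se_out^2)
  expect_equal(est$beta_hat, unname(wls0$coefficients), tolerance = 1e-10)
})

test_that("Egger intercept test has power under directional pleiotropy", {
  pvals <- vapply(1:40, function(i) {
    h <- sim_harmonized(seed = child_seed(777, i), beta_causal = 0.1,
                        pleiotropy_mean = 0.05)
    mr_egger(h)$intercept_p
  }, numeric(1))
  expect_gt(mean(pvals < 0.05), 0.05)
})

test_that("Cochran's Q: hand fixture, degenerate case, monotonicity", {
  q <- cochran_q(pairs_from_ratios(c(0.5, 0.3), c(0.1, 0.2)))
  expect_equal(q$q_stat, 0.8, tolerance = 1e-10)   # 100*0.04^2 + 25*0.16^2
  expect_equal(q$q_df, 1L)
  q0 <- cochran_q(pairs_from_ratios(rep(0.3, 4), rep(0.1, 4)))
  expect_equal(q0$q_stat, 0)
  expect_equal(q0$q_p, 1)
  expect_error(cochran_q(pairs_from_ratios(0.3, 0.1)[1, ]), ">= 2")
  # mean Q grows with het_sd
  mean_q <- vapply(c(0, 0.3), function(h_sd) {
    mean(vapply(1:15, function(i) {
      h <- sim_harmonized(seed = child_seed(888, i + 100 * (h_sd > 0)),
                          beta_causal = 0.2, het_sd = h_sd)
      cochran_q(h)$q_stat
    }, numeric(1)))
  }, numeric(1))
  expect_gt(mean_q[2], mean_q[1])
})

test_that("leave-one-out flags the planted outlier and keeps cardinality", {
  hom <- pairs_from_ratios(rep(0.3, 3), rep(0.1, 3))
  loo <- leave_one_out(hom)
  expect_equal(loo$beta_hat, rep(0.3, 3))
  expect_false(any(loo$influential))
  out5 <- pairs_from_ratios(c(0.3, 0.31, 0.29, 0.3, 1.5),
                            rep(0.05, 5))
  loo5 <- leave_one_out(out5)
  expect_equal(nrow(loo5), 5)
  expect_equal(which.max(abs(loo5$delta_beta)), 5L)
  expect_error(leave_one_out(hom[1:2, ]), ">= 3")
})

test_that("radial outliers: detection, Bonferroni monotonicity", {
  hom <- pairs_from_ratios(rep(0.3, 5), rep(0.1, 5))
  expect_length(radial_outliers(hom), 0)
  disp <- pairs_from_ratios(c(rep(0.3, 10), 0.3 + 10 * 0.05), rep(0.05, 11))
  flagged <- radial_outliers(disp)
  expect_equal(as.character(flagged), "s11")
  # hand check: Q_i for the displaced SNP exceeds the Bonferroni cut
  q_i <- attr(flagged, "q_i")
  expect_gt(q_i[["s11"]], qchisq(0.05 / 11, 1, lower.tail = FALSE))
  # alpha without Bonferroni flags a superset
  lax <- radial_outliers(disp, bonferroni = FALSE)
  expect_true(all(as.character(flagged) %in% as.character(lax)))
})

test_that("Steiger filter implements the r2 comparison rule", {
  # forward-consistent: r2_exp >> r2_out -> retained
  h <- make_pairs(0.2, 0.01, 0.01, se_exp = 0.005)
  h <- rbind(h, h)  # two rows for a well-formed table
  st <- steiger_filter(h)
  expect_equal(nrow(st$retained), 2)
  expect_length(st$removed, 0)
  # reverse: outcome t-stat dominates -> removed
  h2 <- make_pairs(c(0.01, 0.2), c(0.2, 0.01), c(0.005, 0.01),
                   se_exp = c(0.01, 0.005))
  st2 <- steiger_filter(h2)
  expect_equal(st2$removed, "s01")
  # missing n errors with the dataset named
  h3 <- h; h3$n_exp <- NA
  expect_error(steiger_filter(h3), "exposure")
  # EAF-based estimator route
  st3 <- steiger_filter(h2, method = "eaf")
  expect_equal(st3$removed, "s01")
})

test_that("qualification applies the three-criterion rule", {
  fake_est <- function(p) list(pval = p)
  fake_sens <- function(pint, pq) list(egger_intercept_p = pint, q_p = pq)
  expect_true(qualify(fake_est(0.01), fake_sens(0.5, 0.5))$qualified)
  qa <- qualify(fake_est(0.01), fake_sens(0.01, 0.5))
  expect_false(qa$qualified)
  expect_false(qa$criteria[["no_pleiotropy"]])
  expect_false(qualify(fake_est(0.06), fake_sens(0.5, 0.5))$qualified)
})

test_that("mr_run wires the pieces together and honors exclude_region", {
  p <- simulate_gwas_pair(gwas_sim_config(n_instruments = 25,
                                          beta_causal = 0.25, seed = 31))
  qa <- mr_run(p$exposure, p$outcome, p$ld, exposure_id = "T2D",
               outcome_id = "Dementia", source_id = "sim")
  expect_s3_class(qa$estimate, "mr_estimate")
  expect_true(qa$qualified)
  expect_gt(length(qa$instruments), 2)
  # excluding every instrument's region aborts with a message
  expect_message(
    qa2 <- mr_run(p$exposure, p$outcome, p$ld,
                  exclude_region = sprintf("1:1-%d", max(p$exposure$pos))),
    "fewer than 3")
  expect_null(qa2)
})

test_that("CI coverage is nominal over replicated simulations", {
  covered <- vapply(1:100, function(i) {
    h <- sim_harmonized(seed = child_seed(4321, i), n_instruments = 50,
                        beta_causal = 0.2)
    est <- mr_ivw(h)
    log(est$ci_low) <= 0.2 && 0.2 <= log(est$ci_high)
  }, logical(1))
  expect_gte(mean(covered), 0.90)
  expect_lte(mean(covered), 0.99)
})
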