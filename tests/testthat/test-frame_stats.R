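test_that("report rounding is half-up and condition totals pool vignette means", {
  expect_equal(round_half_up(2.345, 2), 2.35)
  expect_equal(round_half_up(-2.345, 2), -2.35)
  expect_equal(round_half_up(2.5), 3)
  expect_equal(condition_total(c(3.985, 3.985)), 3.99)
  expect_equal(condition_total(c(1, 2, 3, 4)), 2.5)
})

test_that("rating-table validation catches malformed input", {
  tab <- toy_rating_table(4)
  expect_s3_class(tab, "framesim_ratings")
  expect_error(as_rating_table(tab[-1, ]), "incomplete",
               class = "framesim_config_error")
  bad <- tab; bad$rating[1] <- 6
  expect_error(as_rating_table(bad), class = "framesim_config_error")
  expect_error(as_rating_table(tab[, -5]), "rating",
               class = "framesim_config_error")
})

test_that("paired t matches t.test and the dz identity on toy tables", {
  tab <- toy_rating_table(5)
  res <- paired_t(tab)
  m <- tapply(tab$rating, list(tab$rater_id, tab$condition), mean)
  oracle <- t.test(m[, "theory"], m[, "non_theory"], paired = TRUE)
  expect_equal(res$t, unname(oracle$statistic), tolerance = 1e-12)
  expect_equal(res$df, unname(oracle$parameter))
  expect_equal(res$p, oracle$p.value, tolerance = 1e-12)
  expect_equal(res$mean_diff, unname(oracle$estimate), tolerance = 1e-12)
  expect_equal(res$ci_mean, as.numeric(oracle$conf.int), tolerance = 1e-10)
  expect_equal(res$t, res$dz * sqrt(res$n), tolerance = 1e-12)

  for (s in 1:5) {
    tt <- generate_ratings(n_raters = 8, seed = s)
    r <- paired_t(tt)
    expect_equal(r$t, r$dz * sqrt(r$n), tolerance = 1e-10)
    expect_true(r$ci_dz[1] <= r$dz && r$dz <= r$ci_dz[2])
  }

  # identical ratings in both conditions: zero differences
  tab0 <- toy_rating_table(4)
  m0 <- tab0$rating[match(paste(tab0$rater_id, sub("N", "T", tab0$vignette_id),
                                tab0$dimension),
                          paste(tab0$rater_id, tab0$vignette_id,
                                tab0$dimension))]
  tab0$rating <- m0
  r0 <- paired_t(tab0)
  expect_identical(r0$t, 0)
  expect_identical(r0$p, 1)
})

test_that("ICC matches the brute-force mean-square oracle", {
  tab <- generate_ratings(n_raters = 6, seed = 13)
  res <- icc(tab, "overall")

  # independent oracle: explicit two-way decomposition + Shrout-Fleiss
  item <- paste(tab$vignette_id, tab$dimension)
  m <- matrix(NA_real_, length(unique(item)), length(unique(tab$rater_id)),
              dimnames = list(sort(unique(item)), sort(unique(tab$rater_id))))
  for (r in seq_len(nrow(tab)))
    m[paste(tab$vignette_id[r], tab$dimension[r]), tab$rater_id[r]] <-
      tab$rating[r]
  n <- nrow(m); k <- ncol(m); g <- mean(m)
  msr <- msc <- mse <- 0
  for (i in 1:n) msr <- msr + k * (mean(m[i, ]) - g)^2
  for (j in 1:k) msc <- msc + n * (mean(m[, j]) - g)^2
  sst <- sum((m - g)^2)
  mse_ss <- sst - msr - msc
  MSR <- msr / (n - 1); MSC <- msc / (k - 1)
  MSE <- mse_ss / ((n - 1) * (k - 1))
  icc2k <- (MSR - MSE) / (MSR + (MSC - MSE) / n)
  icc3k <- (MSR - MSE) / MSR
  Fo <- MSR / MSE
  po <- pf(Fo, n - 1, (n - 1) * (k - 1), lower.tail = FALSE)

  expect_equal(res$icc, icc2k, tolerance = 1e-10)
  expect_equal(res$F, Fo, tolerance = 1e-10)
  expect_equal(res$p, po, tolerance = 1e-10)
  expect_equal(icc(tab, "overall", type = "consistency")$icc, icc3k,
               tolerance = 1e-10)
  expect_true(res$lower < res$icc && res$icc < res$upper)
})

test_that("ICC edge cases: perfect agreement and zero item variance", {
  tab <- toy_rating_table(4)
  # make all raters exact copies while items vary
  ref <- tab[tab$rater_id == "r1", ]
  key <- paste(tab$vignette_id, tab$dimension)
  tab$rating <- ref$rating[match(key, paste(ref$vignette_id, ref$dimension))]
  expect_equal(icc(tab, "overall")$icc, 1)

  flat <- toy_rating_table(4)
  flat$rating <- 3L
  r <- icc(flat, "overall")
  expect_true(is.na(r$icc))
  expect_match(r$note, "undefined")
})

test_that("repeated-measures ANOVA matches independent oracles", {
  tab <- generate_ratings(n_raters = 6, seed = 21)
  res <- rm_anova(tab)$anova

  # brute-force oracle: explicit loops over the 2 x 4 x n cell means and a
  # polynomial (not Helmert) orthonormal contrast basis for sphericity
  a <- tapply(tab$rating, list(tab$rater_id, tab$condition, tab$dimension),
              mean)
  conds <- sort(dimnames(a)[[2]]); dims <- frame_dimensions()
  n <- dim(a)[1]
  Y <- array(0, c(n, 2, 4))
  for (i in 1:n) for (j in 1:2) for (k in 1:4)
    Y[i, j, k] <- a[i, conds[j], dims[k]]
  g <- mean(Y)
  SSA <- SSB <- SSAB <- SSAS <- SSBS <- SSS <- 0
  mi <- apply(Y, 1, mean); mj <- apply(Y, 2, mean); mk <- apply(Y, 3, mean)
  for (j in 1:2) SSA <- SSA + n * 4 * (mj[j] - g)^2
  for (k in 1:4) SSB <- SSB + n * 2 * (mk[k] - g)^2
  for (i in 1:n) SSS <- SSS + 8 * (mi[i] - g)^2
  for (i in 1:n) for (j in 1:2)
    SSAS <- SSAS + 4 * (mean(Y[i, j, ]) - mi[i] - mj[j] + g)^2
  for (i in 1:n) for (k in 1:4)
    SSBS <- SSBS + 2 * (mean(Y[i, , k]) - mi[i] - mk[k] + g)^2
  for (j in 1:2) for (k in 1:4)
    SSAB <- SSAB + n * (mean(Y[, j, k]) - mj[j] - mk[k] + g)^2
  SSABS <- sum((Y - g)^2) - SSS - SSA - SSB - SSAB - SSAS - SSBS

  FA <- SSA / (SSAS / (n - 1))
  FB <- (SSB / 3) / (SSBS / (3 * (n - 1)))
  FAB <- (SSAB / 3) / (SSABS / (3 * (n - 1)))
  expect_equal(res$F, c(FA, FB, FAB), tolerance = 1e-10)
  expect_equal(res$eta_p_sq,
               c(SSA / (SSA + SSAS), SSB / (SSB + SSBS),
                 SSAB / (SSAB + SSABS)), tolerance = 1e-10)
  expect_equal(res$df1, c(1, 3, 3))
  expect_equal(res$df2, c(n - 1, 3 * (n - 1), 3 * (n - 1)))

  poly <- contr.poly(4)  # already orthonormal
  D <- apply(Y, c(1, 3), mean)
  S <- cov(D %*% poly)
  eps_oracle <- sum(diag(S))^2 / (3 * sum(S * S))
  W_oracle <- det(S) / (sum(diag(S)) / 3)^3
  expect_equal(res$gg_epsilon[2], eps_oracle, tolerance = 1e-10)
  expect_equal(res$mauchly_W[2], W_oracle, tolerance = 1e-10)
  expect_equal(res$p_gg[2],
               pf(FB, eps_oracle * 3, eps_oracle * 3 * (n - 1),
                  lower.tail = FALSE), tolerance = 1e-10)

  # two-level factor: sphericity holds trivially, no correction applied
  expect_equal(res$gg_epsilon[1], 1)
  expect_identical(res$p[1], res$p_gg[1])
})

test_that("repeated-measures ANOVA agrees with anova.mlm at larger n", {
  tab <- generate_ratings(n_raters = 12, seed = 3)
  res <- rm_anova(tab)$anova
  a <- tapply(tab$rating, list(tab$rater_id, tab$condition, tab$dimension),
              mean)
  conds <- sort(dimnames(a)[[2]]); dims <- frame_dimensions()
  Y <- do.call(cbind, lapply(conds, function(cc) a[, cc, dims]))
  idata <- expand.grid(dimension = factor(dims, levels = dims),
                       type = factor(conds, levels = conds))[, c(2, 1)]
  fit <- lm(Y ~ 1)
  grab <- function(M, X) {
    tab <- suppressWarnings(anova(fit, M = M, X = X, idata = idata,
                                  test = "Spherical"))
    eps <- attr(tab, "sph")
    list(F = tab$F[1], p = tab$`Pr(>F)`[1], gg = tab$`G-G Pr`[1],
         eps = if (!is.null(eps)) eps else NA)
  }
  o_type <- grab(~type, ~1)
  o_dim <- grab(~type + dimension, ~type)
  o_int <- grab(~type * dimension, ~type + dimension)
  expect_equal(res$F, c(o_type$F, o_dim$F, o_int$F), tolerance = 1e-8)
  expect_equal(res$p, c(o_type$p, o_dim$p, o_int$p), tolerance = 1e-8)
  expect_equal(res$p_gg[2:3], c(o_dim$gg, o_int$gg), tolerance = 1e-6)

  mo_dim <- mauchly.test(fit, M = ~type + dimension, X = ~type,
                         idata = idata)
  mo_int <- mauchly.test(fit, M = ~type * dimension, X = ~type + dimension,
                         idata = idata)
  expect_equal(res$mauchly_W[2], unname(mo_dim$statistic), tolerance = 1e-8)
  expect_equal(res$mauchly_W[3], unname(mo_int$statistic), tolerance = 1e-8)
  # p-values agree to the accuracy of the Box approximation variants
  expect_equal(res$mauchly_p[2], mo_dim$p.value, tolerance = 5e-3)
  expect_equal(res$mauchly_p[3], mo_int$p.value, tolerance = 5e-3)
})

test_that("exchangeable data yield a Greenhouse-Geisser epsilon near 1", {
  model <- calibration_model(0.3)
  tab <- generate_ratings(model, n_raters = 80, seed = 31,
                          discretize = FALSE)
  res <- rm_anova(tab)$anova
  expect_gt(res$gg_epsilon[2], 0.9)
  expect_gt(res$gg_epsilon[3], 0.9)
})

test_that("Holm adjustment matches the hand-enumerated step-down", {
  expect_equal(holm_posthoc(0.03), 0.03)
  expect_equal(holm_posthoc(c(0.01, 0.03, 0.04)), c(0.03, 0.06, 0.06))
  expect_error(holm_posthoc(numeric(0)), class = "framesim_config_error")

  holm_oracle <- function(p) {
    m <- length(p); o <- order(p)
    adj <- pmin(1, (m - seq_len(m) + 1) * p[o])
    adj <- cummax(adj)
    out <- numeric(m); out[o] <- adj
    out
  }
  set.seed(17)
  for (i in 1:50) {
    p <- runif(sample(2:8, 1))
    adj <- holm_posthoc(p)
    expect_equal(adj, holm_oracle(p), tolerance = 1e-12)
    expect_true(all(adj <= 1) && all(adj >= p))
  }
})

test_that("post-hoc families carry the right sizes and paired-t estimates", {
  tab <- generate_ratings(n_raters = 10, seed = 5)
  byd <- posthoc_comparisons(tab, "type_within_dimension")
  expect_equal(nrow(byd), 4)
  d <- framesim:::rater_dimension_diffs(tab)
  expect_equal(byd$estimate, unname(colMeans(d)), tolerance = 1e-12)
  o <- t.test(d[, "Adaptability"])
  expect_equal(byd$t[byd$comparison == "Adaptability"],
               unname(o$statistic), tolerance = 1e-10)
  byt <- posthoc_comparisons(tab, "dimension_within_type")
  expect_equal(nrow(byt), 12)
  expect_equal(as.integer(table(byt$condition)), c(6L, 6L))
  expect_equal(nrow(posthoc_comparisons(tab, "dimension_overall")), 6)
})

test_that("bootstrap CIs are seeded, percentile-based and collapse on constants", {
  tab <- generate_ratings(n_raters = 12, seed = 9)
  b1 <- bootstrap_ci(tab, B = 500, seed = 4)
  b2 <- bootstrap_ci(tab, B = 500, seed = 4)
  expect_identical(b1, b2)
  b3 <- bootstrap_ci(tab, B = 500, seed = 5)
  expect_false(identical(b1$lower, b3$lower))
  expect_true(all(b1$lower <= b1$mean_diff & b1$mean_diff <= b1$upper))
  expect_identical(eval(formals(bootstrap_ci)$B), 10000)

  # constant rater differences: zero-width interval at the constant
  const <- toy_rating_table(6)
  const$rating <- ifelse(const$condition == "theory", 4L, 3L)
  bc <- bootstrap_ci(const, B = 200, seed = 1)
  expect_true(all(bc$lower == 1 & bc$upper == 1 & bc$mean_diff == 1))
})

test_that("paired-t power search matches power.t.test", {
  for (d in c(0.3, 0.5, 0.8, 1.2)) {
    n_pkg <- required_n_paired_t(d, 0.05, 0.80)
    n_ref <- ceiling(power.t.test(delta = d, sd = 1, sig.level = 0.05,
                                  power = 0.80, type = "paired")$n)
    expect_equal(n_pkg, n_ref)
    expect_gte(power_paired_t(n_pkg, d), 0.80)
    expect_lt(power_paired_t(n_pkg - 1, d), 0.80)
  }
  expect_lt(required_n_paired_t(3, 0.05, 0.80),
            required_n_paired_t(0.5, 0.05, 0.80))
  expect_error(required_n_paired_t(0.001, 0.05, 0.999, n_max = 50),
               class = "framesim_config_error")
  expect_error(required_n_paired_t(-1), class = "framesim_config_error")
})

test_that("summaries degrade gracefully when all ratings agree", {
  flat <- toy_rating_table(4)
  flat$rating <- 4L
  s <- summarize_ratings(flat)
  expect_true(all(s$by_vignette$sd == 0))
  expect_true(all(s$by_vignette$ci_lower == 4 & s$by_vignette$ci_upper == 4))
  expect_true(all(s$by_condition$mean == 4))
})
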