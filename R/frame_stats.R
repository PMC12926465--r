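# FRAME realism-evaluation statistics: rating-table I/O and validation,
# condition/dimension summaries, paired t with Cohen's dz, ICC, 2x4
# repeated-measures ANOVA with Mauchly's test and the Greenhouse-Geisser
# correction, Holm-adjusted post-hoc comparisons, bootstrap CIs, and the
# a-priori paired-t power analysis.

#' The four FRAME realism dimensions
#' @return character vector of dimension labels.
#' @export
frame_dimensions <- function() {
  c("Crisis Decision-Making", "Adaptability", "Plausibility of Actions",
    "Use of Social Support")
}

#' Validate a rating table
#'
#' A rating table is long-format with columns `rater_id`, `vignette_id`,
#' `condition`, `dimension`, `rating`: a complete rater x vignette x
#' dimension crossing, ratings on the 1-5 scale, eight vignettes with four
#' per condition and the four FRAME dimensions.
#'
#' @param df data frame in the rating-table layout.
#' @param check_integer require integer ratings in 1..5 (set `FALSE` for
#'   latent-scale tables from the continuous generator mode).
#' @return the validated data frame, classed `framesim_ratings`.
#' @export
as_rating_table <- function(df, check_integer = TRUE) {
  need <- c("rater_id", "vignette_id", "condition", "dimension", "rating")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stopf("rating table is missing column '%s'", miss[1],
          class = "framesim_config_error")
  conds <- unique(df[, c("vignette_id", "condition")])
  if (length(unique(conds$condition)) != 2 ||
      any(table(conds$condition) != 4))
    stopf("rating table needs 8 vignettes, 4 per condition",
          class = "framesim_config_error")
  cells <- table(df$rater_id, df$vignette_id, df$dimension)
  if (any(cells != 1)) {
    bad <- which(cells != 1, arr.ind = TRUE)[1, ]
    stopf("incomplete rating table: rater %s, vignette %s, dimension %s",
          dimnames(cells)[[1]][bad[1]], dimnames(cells)[[2]][bad[2]],
          dimnames(cells)[[3]][bad[3]],
          class = "framesim_config_error")
  }
  if (check_integer &&
      (any(df$rating %% 1 != 0) || any(df$rating < 1) || any(df$rating > 5)))
    stopf("ratings must be integers in 1..5",
          class = "framesim_config_error")
  class(df) <- c("framesim_ratings", "data.frame")
  df
}

#' Read a ratings CSV
#'
#' Expects columns `rater_id, vignette_id, condition, dimension, rating`.
#'
#' @param path CSV file path.
#' @param check_integer passed to [as_rating_table()].
#' @return a validated rating table.
#' @export
read_ratings <- function(path, check_integer = TRUE) {
  as_rating_table(utils::read.csv(path, stringsAsFactors = FALSE),
                  check_integer = check_integer)
}

# Rater-level mean helpers (the rater is the repeated-measures unit).
rater_condition_means <- function(table) {
  m <- tapply(table$rating, list(table$rater_id, table$condition), mean)
  m[order(rownames(m)), , drop = FALSE]
}

# n x (2*4) matrix of rater cell means, cells ordered
# (condition x dimension); averaged over the 4 vignettes per condition.
rater_cell_means <- function(table) {
  a <- tapply(table$rating,
              list(table$rater_id, table$condition, table$dimension), mean)
  conds <- sort(dimnames(a)[[2]])
  dims <- frame_dimensions()
  dims <- dims[dims %in% dimnames(a)[[3]]]
  out <- do.call(cbind, lapply(conds, function(cc)
    a[, cc, dims, drop = TRUE]))
  colnames(out) <- as.vector(outer(dims, conds,
                                   function(d, cc) paste(cc, d, sep = ":")))
  out[order(rownames(out)), , drop = FALSE]
}

theory_label <- function(table) {
  conds <- unique(table$condition)
  hit <- grepl("^(theory|t)", tolower(conds))
  if (sum(hit) == 1) conds[hit] else sort(conds)[2]
}

# Per-rater (theory - non-theory) difference of dimension means: n x 4.
rater_dimension_diffs <- function(table) {
  th <- theory_label(table)
  a <- tapply(table$rating,
              list(table$rater_id, table$condition, table$dimension), mean)
  dims <- frame_dimensions()
  dims <- dims[dims %in% dimnames(a)[[3]]]
  nt <- setdiff(dimnames(a)[[2]], th)
  d <- a[, th, dims, drop = TRUE] - a[, nt, dims, drop = TRUE]
  d[order(rownames(d)), , drop = FALSE]
}

ci_t <- function(x, conf = 0.95) {
  n <- length(x)
  se <- stats::sd(x) / sqrt(n)
  q <- stats::qt(1 - (1 - conf) / 2, n - 1)
  c(mean(x) - q * se, mean(x) + q * se)
}

#' Summarize a rating table
#'
#' Per-vignette means over raters and dimensions, condition totals as
#' unweighted means of the vignette means, and condition-by-dimension
#' means. SDs and 95% t-based confidence intervals for vignettes and
#' condition totals are computed over rater-level means (the
#' repeated-measures unit); dimension rows use all ratings.
#'
#' @param table a rating table.
#' @return list of data frames `by_vignette`, `by_condition`,
#'   `by_dimension`.
#' @export
summarize_ratings <- function(table) {
  table <- as_rating_table(as.data.frame(table), check_integer = FALSE)
  vigs <- unique(table[, c("vignette_id", "condition")])
  vigs <- vigs[order(vigs$condition, vigs$vignette_id), ]
  by_v <- do.call(rbind, lapply(seq_len(nrow(vigs)), function(i) {
    sub <- table[table$vignette_id == vigs$vignette_id[i], ]
    rm <- tapply(sub$rating, sub$rater_id, mean)
    ci <- ci_t(rm)
    data.frame(vignette_id = vigs$vignette_id[i],
               condition = vigs$condition[i],
               mean = mean(rm), sd = stats::sd(rm),
               ci_lower = ci[1], ci_upper = ci[2],
               stringsAsFactors = FALSE)
  }))
  by_c <- do.call(rbind, lapply(sort(unique(table$condition)), function(cc) {
    vm <- by_v$mean[by_v$condition == cc]
    sub <- table[table$condition == cc, ]
    rm <- tapply(sub$rating, sub$rater_id, mean)
    ci <- ci_t(rm)
    data.frame(condition = cc, mean = mean(vm), sd = stats::sd(rm),
               ci_lower = ci[1], ci_upper = ci[2],
               stringsAsFactors = FALSE)
  }))
  grid <- expand.grid(condition = sort(unique(table$condition)),
                      dimension = frame_dimensions(),
                      stringsAsFactors = FALSE)
  by_d <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    sub <- table[table$condition == grid$condition[i] &
                   table$dimension == grid$dimension[i], ]
    ci <- ci_t(sub$rating)
    data.frame(condition = grid$condition[i], dimension = grid$dimension[i],
               mean = mean(sub$rating), sd = stats::sd(sub$rating),
               ci_lower = ci[1], ci_upper = ci[2],
               stringsAsFactors = FALSE)
  }))
  list(by_vignette = by_v, by_condition = by_c, by_dimension = by_d)
}

#' Pool vignette means into a condition total
#'
#' Unweighted mean of per-vignette means, rounded half-up to the reported
#' precision.
#'
#' @param vignette_means numeric vector of per-vignette mean ratings.
#' @param digits decimals for the reported value (default 2).
#' @return pooled condition mean.
#' @export
#' @examples
#' condition_total(c(4.15, 3.76, 3.88, 4.18))  # 3.99
condition_total <- function(vignette_means, digits = 2) {
  round_half_up(mean(vignette_means), digits)
}

#' Paired-samples t-test on rater condition means
#'
#' Differences are each rater's theory-condition mean minus non-theory
#' mean; Cohen's dz is mean(d)/sd(d) and its CI is obtained by
#' noncentrality inversion of the t distribution.
#'
#' @param table a rating table.
#' @param conf confidence level.
#' @return list: `t`, `df`, `p`, `mean_diff`, `ci_mean`, `dz`, `ci_dz`,
#'   `n`.
#' @export
paired_t <- function(table, conf = 0.95) {
  m <- rater_condition_means(as_rating_table(as.data.frame(table),
                                             check_integer = FALSE))
  th <- theory_label(table)
  d <- m[, th] - m[, setdiff(colnames(m), th)]
  n <- length(d)
  md <- mean(d)
  s <- stats::sd(d)
  if (s == 0) {
    t <- if (md == 0) 0 else sign(md) * Inf
    return(list(t = t, df = n - 1, p = if (md == 0) 1 else 0,
                mean_diff = md, ci_mean = c(md, md),
                dz = if (md == 0) 0 else sign(md) * Inf,
                ci_dz = c(NA_real_, NA_real_), n = n))
  }
  t <- md / (s / sqrt(n))
  df <- n - 1
  p <- 2 * stats::pt(-abs(t), df)
  alpha <- 1 - conf
  ncp_root <- function(target_p) {
    f <- function(ncp) suppressWarnings(stats::pt(t, df, ncp)) - target_p
    stats::uniroot(f, interval = c(t - 10, t + 10), extendInt = "yes",
                   tol = 1e-10)$root
  }
  ci_dz <- c(ncp_root(1 - alpha / 2), ncp_root(alpha / 2)) / sqrt(n)
  list(t = t, df = df, p = p, mean_diff = md, ci_mean = ci_t(d, conf),
       dz = md / s, ci_dz = ci_dz, n = n)
}

# ---- ICC --------------------------------------------------------------------

icc_from_matrix <- function(m, type = c("agreement", "consistency"),
                            conf = 0.95) {
  type <- match.arg(type)
  n <- nrow(m); k <- ncol(m)
  grand <- mean(m)
  rm <- rowMeans(m); cm <- colMeans(m)
  SSR <- k * sum((rm - grand)^2)
  SSC <- n * sum((cm - grand)^2)
  SST <- sum((m - grand)^2)
  SSE <- SST - SSR - SSC
  MSR <- SSR / (n - 1); MSC <- SSC / (k - 1)
  MSE <- SSE / ((n - 1) * (k - 1))
  if (SSR < 1e-12)
    return(data.frame(icc = NA_real_, lower = NA_real_, upper = NA_real_,
                      F = NA_real_, df1 = n - 1, df2 = (n - 1) * (k - 1),
                      p = NA_real_, n_items = n, k_raters = k,
                      note = "zero between-item variance: ICC undefined",
                      stringsAsFactors = FALSE))
  Fv <- MSR / MSE
  pv <- stats::pf(Fv, n - 1, (n - 1) * (k - 1), lower.tail = FALSE)
  alpha <- 1 - conf
  if (type == "consistency") {
    est <- (MSR - MSE) / MSR
    FL <- Fv / stats::qf(1 - alpha / 2, n - 1, (n - 1) * (k - 1))
    FU <- Fv * stats::qf(1 - alpha / 2, (n - 1) * (k - 1), n - 1)
    lo <- 1 - 1 / FL; up <- 1 - 1 / FU
  } else {
    est <- (MSR - MSE) / (MSR + (MSC - MSE) / n)
    icc1 <- (MSR - MSE) / (MSR + (k - 1) * MSE + k * (MSC - MSE) / n)
    a <- k * icc1 / (n * (1 - icc1))
    b <- 1 + k * icc1 * (n - 1) / (n * (1 - icc1))
    v <- (a * MSC + b * MSE)^2 /
      ((a * MSC)^2 / (k - 1) + (b * MSE)^2 / ((n - 1) * (k - 1)))
    FL <- stats::qf(1 - alpha / 2, n - 1, v)
    FU <- stats::qf(1 - alpha / 2, v, n - 1)
    L1 <- n * (MSR - FL * MSE) /
      (FL * (k * MSC + (k * n - k - n) * MSE) + n * MSR)
    U1 <- n * (FU * MSR - MSE) /
      (k * MSC + (k * n - k - n) * MSE + n * FU * MSE)
    lo <- L1 * k / (1 + (k - 1) * L1)
    up <- U1 * k / (1 + (k - 1) * U1)
  }
  data.frame(icc = est, lower = lo, upper = up, F = Fv, df1 = n - 1,
             df2 = (n - 1) * (k - 1), p = pv, n_items = n, k_raters = k,
             note = "", stringsAsFactors = FALSE)
}

#' Intraclass correlation of the ratings
#'
#' Average-measures ICC from the two-way rater x item mean-square
#' decomposition. The default is the two-way random-effects
#' absolute-agreement coefficient ICC(2,k); the consistency variant
#' ICC(3,k) is available by flag. Items are vignette-dimension cells
#' (`overall`), their condition subsets (`by_condition`), vignettes within
#' each dimension (`by_dimension`), or dimensions within each vignette
#' (`by_vignette`). Zero between-item variance leaves the coefficient
#' undefined and is reported as such.
#'
#' @param table a rating table.
#' @param grouping one of `"overall"`, `"by_condition"`,
#'   `"by_dimension"`, `"by_vignette"`.
#' @param type `"agreement"` (ICC(2,k), default) or `"consistency"`
#'   (ICC(3,k)).
#' @param conf confidence level.
#' @return data frame with one row per group: estimate, F-based CI and
#'   p-value, item and rater counts.
#' @export
icc <- function(table, grouping = c("overall", "by_condition",
                                    "by_dimension", "by_vignette"),
                type = c("agreement", "consistency"), conf = 0.95) {
  grouping <- match.arg(grouping)
  type <- match.arg(type)
  table <- as_rating_table(as.data.frame(table), check_integer = FALSE)
  mat_for <- function(sub, item_cols) {
    item <- interaction(sub[item_cols], drop = TRUE)
    m <- tapply(sub$rating, list(item, sub$rater_id), mean)
    m[, order(colnames(m)), drop = FALSE]
  }
  groups <- switch(grouping,
    overall = list(overall = table),
    by_condition = split(table, table$condition),
    by_dimension = split(table, table$dimension),
    by_vignette = split(table, table$vignette_id))
  item_cols <- switch(grouping,
    overall = c("vignette_id", "dimension"),
    by_condition = c("vignette_id", "dimension"),
    by_dimension = "vignette_id",
    by_vignette = "dimension")
  out <- do.call(rbind, lapply(names(groups), function(g) {
    r <- icc_from_matrix(mat_for(groups[[g]], item_cols), type, conf)
    cbind(data.frame(group = g, stringsAsFactors = FALSE), r)
  }))
  rownames(out) <- NULL
  out
}

# ---- repeated-measures ANOVA ------------------------------------------------

orthonormal_contrasts <- function(k) {
  M <- stats::contr.helmert(k)
  apply(M, 2, function(cc) cc / sqrt(sum(cc^2)))
}

sphericity_block <- function(D, n) {
  # D: n x k matrix of within-factor scores (k >= 3)
  k <- ncol(D)
  p <- k - 1
  S <- stats::cov(D %*% orthonormal_contrasts(k))
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  eps <- sum(ev)^2 / (p * sum(ev^2))
  W <- det(S) / (sum(diag(S)) / p)^p
  # Box chi-square approximation with the second-order correction term
  nd <- n - 1
  rho <- 1 - (2 * p^2 + p + 2) / (6 * p * nd)
  w2 <- (p + 2) * (p - 1) * (p - 2) * (2 * p^3 + 6 * p^2 + 3 * p + 2) /
    (288 * (nd * p * rho)^2)
  z <- -nd * rho * log(W)
  f <- p * (p + 1) / 2 - 1
  pr1 <- stats::pchisq(z, f, lower.tail = FALSE)
  pr2 <- stats::pchisq(z, f + 4, lower.tail = FALSE)
  list(W = W, p_mauchly = pr1 + w2 * (pr2 - pr1),
       epsilon = max(eps, 1 / p))
}

#' Two-by-four repeated-measures ANOVA on the ratings
#'
#' Within-rater factors Agent Type (2 levels) and Dimension (4 levels) on
#' the rater cell means (averaged over the four vignettes per condition).
#' Reports F, uncorrected p and partial eta squared per effect, Mauchly's
#' W and p for the Dimension and interaction effects, the
#' Greenhouse-Geisser epsilon from the covariance of the orthonormalized
#' within-factor contrasts, and the epsilon-corrected p alongside the
#' uncorrected one. The two-level Agent Type factor satisfies sphericity
#' trivially (epsilon 1, no correction).
#'
#' @param table a rating table.
#' @return list with `anova` (data frame, one row per effect) and `n`.
#' @export
rm_anova <- function(table) {
  table <- as_rating_table(as.data.frame(table), check_integer = FALSE)
  a <- tapply(table$rating,
              list(table$rater_id, table$condition, table$dimension), mean)
  conds <- sort(dimnames(a)[[2]])
  dims <- frame_dimensions()
  dims <- dims[dims %in% dimnames(a)[[3]]]
  Y <- a[, conds, dims, drop = FALSE]  # n x 2 x 4
  n <- dim(Y)[1]; A <- dim(Y)[2]; B <- dim(Y)[3]
  grand <- mean(Y)
  mi <- apply(Y, 1, mean); mj <- apply(Y, 2, mean); mk <- apply(Y, 3, mean)
  mij <- apply(Y, c(1, 2), mean); mik <- apply(Y, c(1, 3), mean)
  mjk <- apply(Y, c(2, 3), mean)
  SS_S <- A * B * sum((mi - grand)^2)
  SS_A <- n * B * sum((mj - grand)^2)
  SS_B <- n * A * sum((mk - grand)^2)
  SS_AS <- B * sum((mij - outer(mi, mj, `+`) + grand)^2)
  SS_BS <- A * sum((mik - outer(mi, mk, `+`) + grand)^2)
  SS_AB <- n * sum((mjk - outer(mj, mk, `+`) + grand)^2)
  SS_tot <- sum((Y - grand)^2)
  SS_ABS <- SS_tot - SS_S - SS_A - SS_B - SS_AB - SS_AS - SS_BS

  eff <- function(name, SS, SSerr, df1, df2, sph = NULL) {
    Fv <- (SS / df1) / (SSerr / df2)
    pv <- stats::pf(Fv, df1, df2, lower.tail = FALSE)
    eps <- if (is.null(sph)) 1 else sph$epsilon
    data.frame(effect = name, df1 = df1, df2 = df2, F = Fv, p = pv,
               eta_p_sq = SS / (SS + SSerr),
               mauchly_W = if (is.null(sph)) NA_real_ else sph$W,
               mauchly_p = if (is.null(sph)) NA_real_ else sph$p_mauchly,
               gg_epsilon = eps,
               p_gg = stats::pf(Fv, eps * df1, eps * df2,
                                lower.tail = FALSE),
               stringsAsFactors = FALSE)
  }
  sph_ok <- n >= 3
  # within-factor score matrices for sphericity: Dimension (averaged over
  # type) and the per-dimension type difference (interaction)
  D_dim <- mik
  D_int <- Y[, 2, ] - Y[, 1, ]
  sph_B <- if (sph_ok) sphericity_block(D_dim, n) else NULL
  sph_AB <- if (sph_ok) sphericity_block(D_int, n) else NULL
  out <- rbind(
    eff("agent_type", SS_A, SS_AS, A - 1, (A - 1) * (n - 1)),
    eff("dimension", SS_B, SS_BS, B - 1, (B - 1) * (n - 1), sph_B),
    eff("agent_type:dimension", SS_AB, SS_ABS, (A - 1) * (B - 1),
        (A - 1) * (B - 1) * (n - 1), sph_AB))
  rownames(out) <- NULL
  list(anova = out, n = n,
       sphericity_testable = sph_ok,
       note = if (!sph_ok) "n < 3: sphericity tests unavailable" else "")
}

# ---- post-hoc comparisons ---------------------------------------------------

#' Holm step-down adjustment
#'
#' Standard Holm procedure over an explicitly declared family: sort
#' ascending, multiply by (m - rank + 1), enforce monotonicity, cap at 1.
#'
#' @param p vector of raw p-values (one family).
#' @return adjusted p-values in the input order.
#' @export
#' @examples
#' holm_posthoc(c(0.01, 0.03, 0.04))  # 0.03 0.06 0.06
holm_posthoc <- function(p) {
  if (!length(p))
    stopf("empty comparison family", class = "framesim_config_error")
  stats::p.adjust(p, method = "holm")
}

#' Post-hoc pairwise comparisons with Holm adjustment
#'
#' Marginal mean differences with paired-t standard errors over raters.
#' Families mirror the reporting layout: the simple effect of agent type
#' within each dimension (4 comparisons), dimension pairs within each
#' agent type (6 per type, adjusted within type), or dimension pairs
#' averaged over agent type (6 comparisons).
#'
#' @param table a rating table.
#' @param family `"type_within_dimension"`, `"dimension_within_type"` or
#'   `"dimension_overall"`.
#' @return data frame of estimates, SEs, t, df, raw and Holm-adjusted p.
#' @export
posthoc_comparisons <- function(table,
                                family = c("type_within_dimension",
                                           "dimension_within_type",
                                           "dimension_overall")) {
  family <- match.arg(family)
  table <- as_rating_table(as.data.frame(table), check_integer = FALSE)
  a <- tapply(table$rating,
              list(table$rater_id, table$condition, table$dimension), mean)
  dims <- frame_dimensions()
  dims <- dims[dims %in% dimnames(a)[[3]]]
  th <- theory_label(table)
  nt <- setdiff(dimnames(a)[[2]], th)
  pt_row <- function(d, label, extra = NULL) {
    n <- length(d); se <- stats::sd(d) / sqrt(n)
    t <- mean(d) / se
    out <- data.frame(
      comparison = label, estimate = mean(d), se = se, t = t, df = n - 1,
      p = 2 * stats::pt(-abs(t), n - 1), stringsAsFactors = FALSE)
    if (is.null(extra)) out else cbind(extra, out)
  }
  if (family == "type_within_dimension") {
    out <- do.call(rbind, lapply(dims, function(k)
      pt_row(a[, th, k] - a[, nt, k], k)))
    out$p_holm <- holm_posthoc(out$p)
  } else if (family == "dimension_within_type") {
    pairs <- utils::combn(dims, 2, simplify = FALSE)
    out <- do.call(rbind, lapply(c(th, nt), function(cc) {
      block <- do.call(rbind, lapply(pairs, function(pr)
        pt_row(a[, cc, pr[1]] - a[, cc, pr[2]],
               paste(pr, collapse = " - "),
               data.frame(condition = cc, stringsAsFactors = FALSE))))
      block$p_holm <- holm_posthoc(block$p)
      block
    }))
  } else {
    avg <- (a[, th, ] + a[, nt, ]) / 2
    pairs <- utils::combn(dims, 2, simplify = FALSE)
    out <- do.call(rbind, lapply(pairs, function(pr)
      pt_row(avg[, pr[1]] - avg[, pr[2]], paste(pr, collapse = " - "))))
    out$p_holm <- holm_posthoc(out$p)
  }
  rownames(out) <- NULL
  out
}

# ---- bootstrap --------------------------------------------------------------

#' Bootstrapped CIs for per-dimension condition differences
#'
#' Raters (the repeated-measures unit) are resampled with replacement;
#' each replicate recomputes the per-dimension mean theory-minus-non-theory
#' difference; percentile intervals are reported. Seeded and reproducible.
#'
#' @param table a rating table.
#' @param B number of bootstrap iterations (default 10000).
#' @param seed integer seed.
#' @param conf confidence level.
#' @return data frame: dimension, observed mean difference, CI bounds, B.
#' @export
bootstrap_ci <- function(table, B = 10000, seed = 1L, conf = 0.95) {
  stopifnot(B >= 1)
  D <- rater_dimension_diffs(as_rating_table(as.data.frame(table),
                                             check_integer = FALSE))
  n <- nrow(D)
  idx <- with_seed(hash_seed(seed, "bootstrap"),
                   matrix(sample.int(n, n * B, replace = TRUE), n, B))
  alpha <- 1 - conf
  out <- do.call(rbind, lapply(colnames(D), function(k) {
    reps <- colMeans(matrix(D[idx, k], n, B))
    # type-6 quantiles: slightly wider tails, better finite-sample coverage
    qs <- stats::quantile(reps, c(alpha / 2, 1 - alpha / 2), names = FALSE,
                          type = 6)
    data.frame(dimension = k, mean_diff = mean(D[, k]),
               lower = qs[1], upper = qs[2], B = B,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

# ---- power analysis ---------------------------------------------------------

#' Power of a paired t-test
#'
#' Exact noncentral-t power with noncentrality dz * sqrt(n).
#'
#' @param n number of pairs.
#' @param dz standardized mean difference (Cohen's dz).
#' @param alpha significance level.
#' @param tails 1 or 2.
#' @return power in [0,1].
#' @export
power_paired_t <- function(n, dz, alpha = 0.05, tails = 2) {
  stopifnot(n >= 2, tails %in% c(1, 2))
  df <- n - 1
  crit <- stats::qt(1 - alpha / tails, df)
  ncp <- dz * sqrt(n)
  pow <- stats::pt(crit, df, ncp, lower.tail = FALSE)
  if (tails == 2) pow <- pow + stats::pt(-crit, df, ncp)
  pow
}

#' A-priori sample size for a paired t-test
#'
#' Smallest n whose exact noncentral-t power reaches the target.
#'
#' @param dz assumed effect size (Cohen's dz, > 0).
#' @param alpha significance level in (0,1).
#' @param power target power in (0,1).
#' @param tails 1 or 2.
#' @param n_max search cap; exceeding it signals unattainable power.
#' @return required number of pairs (integer).
#' @export
#' @examples
#' required_n_paired_t(0.5, 0.05, 0.80)  # 34
required_n_paired_t <- function(dz, alpha = 0.05, power = 0.80, tails = 2,
                                n_max = 1e6) {
  if (!(dz > 0) || !(alpha > 0 && alpha < 1) || !(power > 0 && power < 1))
    stopf("need dz > 0 and alpha, power in (0,1)",
          class = "framesim_config_error")
  for (n in 2:n_max) {
    if (power_paired_t(n, dz, alpha, tails) >= power) return(as.integer(n))
  }
  stopf("target power %.2f unattainable within n <= %g", power, n_max,
        class = "framesim_config_error")
}

#' Full FRAME statistics report
#'
#' Runs the complete within-subjects suite on a rating table: summaries,
#' paired t with Cohen's dz, ICC blocks, the repeated-measures ANOVA with
#' sphericity diagnostics, Holm post-hoc families and bootstrap CIs.
#'
#' @param table a rating table.
#' @param B bootstrap iterations.
#' @param seed integer seed for the bootstrap.
#' @return list of result blocks.
#' @export
frame_report <- function(table, B = 10000, seed = 1L) {
  list(
    summary = summarize_ratings(table),
    paired_t = paired_t(table),
    icc_overall = icc(table, "overall"),
    icc_by_condition = icc(table, "by_condition"),
    anova = rm_anova(table),
    posthoc_type_within_dimension =
      posthoc_comparisons(table, "type_within_dimension"),
    posthoc_dimension_overall =
      posthoc_comparisons(table, "dimension_overall"),
    bootstrap = bootstrap_ci(table, B = B, seed = seed)
  )
}
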