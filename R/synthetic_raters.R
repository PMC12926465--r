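# Synthetic Likert rating tables with controllable rater, vignette,
# condition and dimension effects, so the evaluation pipeline can be
# exercised and calibrated without human raters.

#' Specify a synthetic rating model
#'
#' Latent rating = grand mean + condition effect (+delta/2 for the theory
#' condition, -delta/2 otherwise) + dimension effect + condition x
#' dimension interaction + rater intercept + vignette intercept + residual
#' noise, discretized onto the 1-5 scale. Defaults produce tables with
#' condition means around 3.4-4.0 and SDs around 0.6-1.3 — realistic
#' fixtures, not a fit to any particular data set.
#'
#' @param grand_mean latent grand mean.
#' @param condition_effect latent theory-minus-non-theory shift (delta).
#' @param dimension_effects length-4 vector summing to 0 (FRAME dimension
#'   order).
#' @param interaction_effects 2 x 4 matrix (rows: non-theory, theory)
#'   summing to 0 by row and column.
#' @param rater_sd,vignette_sd,residual_sd SDs of the random components
#'   (all >= 0).
#' @param thresholds optional increasing cutpoints (length 4) for ordinal
#'   threshold discretization; default `NULL` uses round-and-clamp.
#' @return a `framesim_rating_model` list.
#' @export
rating_model <- function(grand_mean = 3.70,
                         condition_effect = 0.58,
                         dimension_effects = c(0.12, 0.03, -0.11, -0.04),
                         interaction_effects = rbind(
                           non_theory = c(0.100, -0.010, 0.105, -0.195),
                           theory = c(-0.100, 0.010, -0.105, 0.195)),
                         rater_sd = 0.30, vignette_sd = 0.15,
                         residual_sd = 1.00, thresholds = NULL) {
  stopifnot(rater_sd >= 0, vignette_sd >= 0, residual_sd >= 0,
            length(dimension_effects) == 4,
            all(dim(interaction_effects) == c(2, 4)))
  if (abs(sum(dimension_effects)) > 1e-8)
    stopf("dimension_effects must sum to 0", class = "framesim_config_error")
  if (any(abs(rowSums(interaction_effects)) > 1e-8) ||
      any(abs(colSums(interaction_effects)) > 1e-8))
    stopf("interaction_effects must sum to 0 by row and column",
          class = "framesim_config_error")
  structure(list(grand_mean = grand_mean,
                 condition_effect = condition_effect,
                 dimension_effects = dimension_effects,
                 interaction_effects = interaction_effects,
                 rater_sd = rater_sd, vignette_sd = vignette_sd,
                 residual_sd = residual_sd, thresholds = thresholds),
            class = "framesim_rating_model")
}

#' Latent delta for a target Cohen's dz
#'
#' In the continuous model each rater's theory-minus-non-theory mean has
#' SD `residual_sd / sqrt(8)` (16 cells per condition, rater and vignette
#' intercepts cancel or are fixed within a table), so the latent effect
#' size is `dz = delta * sqrt(8) / residual_sd`.
#'
#' @param dz target standardized effect size.
#' @param model a `framesim_rating_model`.
#' @return the latent condition effect delta.
#' @export
delta_for_dz <- function(dz, model = rating_model()) {
  dz * model$residual_sd / sqrt(8)
}

#' Generate a synthetic rating table
#'
#' Complete rater x vignette x dimension table under the latent model,
#' fully determined by `(model, n_raters, seed)`. Discretization is
#' round-and-clamp onto 1..5, ordinal thresholds when the model carries
#' cutpoints, or none (`discretize = FALSE`) for exact latent-scale
#' checks.
#'
#' @param model a `framesim_rating_model`.
#' @param n_raters number of raters (>= 2).
#' @param seed integer seed.
#' @param discretize map the latent scale onto 1..5 (default `TRUE`).
#' @return a rating table (`framesim_ratings`).
#' @export
generate_ratings <- function(model = rating_model(), n_raters = 34L,
                             seed = 1L, discretize = TRUE) {
  stopifnot(n_raters >= 2)
  dims <- frame_dimensions()
  vids <- c(paste0("T", 1:4), paste0("N", 1:4))
  conds <- rep(c("theory", "non_theory"), each = 4)
  grid <- expand.grid(rater_id = sprintf("r%02d", seq_len(n_raters)),
                      vignette_id = vids, dimension = dims,
                      stringsAsFactors = FALSE)
  grid$condition <- conds[match(grid$vignette_id, vids)]
  with_seed(hash_seed(seed, "ratings"), {
    r_int <- stats::rnorm(n_raters, 0, model$rater_sd)
    v_int <- stats::rnorm(length(vids), 0, model$vignette_sd)
    names(r_int) <- sprintf("r%02d", seq_len(n_raters))
    names(v_int) <- vids
    sgn <- ifelse(grid$condition == "theory", 0.5, -0.5)
    ci <- ifelse(grid$condition == "theory", 2L, 1L)
    ki <- match(grid$dimension, dims)
    latent <- model$grand_mean + sgn * model$condition_effect +
      model$dimension_effects[ki] +
      model$interaction_effects[cbind(ci, ki)] +
      r_int[grid$rater_id] + v_int[grid$vignette_id] +
      stats::rnorm(nrow(grid), 0, model$residual_sd)
    grid$rating <- if (!discretize) latent
    else if (is.null(model$thresholds)) clamp(floor(latent + 0.5), 1, 5)
    else 1 + rowSums(outer(latent, model$thresholds, `>`))
  })
  rownames(grid) <- NULL
  as_rating_table(grid[, c("rater_id", "vignette_id", "condition",
                           "dimension", "rating")],
                  check_integer = isTRUE(discretize))
}

#' Parameter-recovery experiment for the evaluation pipeline
#'
#' Repeatedly generates rating tables under the model and runs the paired
#' t-test (and overall ICC) on each replicate, summarizing the bias of the
#' estimated condition difference, the empirical rejection rate at the
#' given alpha, and the mean ICC.
#'
#' @param model a `framesim_rating_model`.
#' @param n_raters raters per replicate.
#' @param reps number of replicates (>= 1).
#' @param seed integer seed (each replicate uses a hashed substream).
#' @param alpha rejection level for the paired t.
#' @param discretize passed to [generate_ratings()].
#' @param compute_icc also compute the overall ICC per replicate.
#' @return list: `mean_estimate`, `bias`, `rejection_rate`, `mean_icc`,
#'   `reps`, `delta`.
#' @export
recovery_experiment <- function(model = rating_model(), n_raters = 34L,
                                reps = 100L, seed = 1L, alpha = 0.05,
                                discretize = TRUE, compute_icc = FALSE) {
  stopifnot(reps >= 1)
  est <- p <- ic <- numeric(reps)
  for (r in seq_len(reps)) {
    tab <- generate_ratings(model, n_raters, seed = hash_seed(seed, "rep", r),
                            discretize = discretize)
    res <- paired_t(tab)
    est[r] <- res$mean_diff
    p[r] <- res$p
    if (compute_icc) ic[r] <- icc(tab, "overall")$icc[1]
  }
  list(mean_estimate = mean(est),
       bias = mean(est) - model$condition_effect,
       rejection_rate = mean(p < alpha),
       mean_icc = if (compute_icc) mean(ic) else NA_real_,
       reps = reps, delta = model$condition_effect)
}

#' Bootstrap coverage experiment
#'
#' Simulates normal rater-level differences, computes the percentile
#' bootstrap CI of the mean in each replicate, and reports the fraction of
#' replicates whose interval covers the true mean.
#'
#' @param reps number of replicates.
#' @param n raters per replicate.
#' @param B bootstrap iterations per replicate.
#' @param mean,sd parameters of the simulated differences.
#' @param seed integer seed.
#' @param conf nominal confidence level.
#' @return list: `coverage`, `reps`, `n`, `B`.
#' @export
coverage_experiment <- function(reps = 500L, n = 34L, B = 2000L,
                                mean = 0.5, sd = 1, seed = 1L,
                                conf = 0.95) {
  alpha <- 1 - conf
  cover <- logical(reps)
  for (r in seq_len(reps)) {
    cover[r] <- with_seed(hash_seed(seed, "cov", r), {
      d <- stats::rnorm(n, mean, sd)
      idx <- matrix(sample.int(n, n * B, replace = TRUE), n, B)
      reps_b <- colMeans(matrix(d[idx], n, B))
      qs <- stats::quantile(reps_b, c(alpha / 2, 1 - alpha / 2),
                            names = FALSE, type = 6)
      qs[1] <= mean && mean <= qs[2]
    })
  }
  list(coverage = base::mean(cover), reps = reps, n = n, B = B)
}
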