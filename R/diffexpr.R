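#' Build the per-muscle design matrix
#'
#' Encodes stress and diet with centred +/- 0.5 codes and, optionally,
#' their interaction, so that the stress coefficient is the stress minus
#' limited-stress mean difference averaged over diets (the main-effect
#' contrast of interest). An optional additive batch covariate can be
#' supplied.
#'
#' @param design data.frame with columns `sample`, `stress`, `diet` (and
#'   optionally the batch column).
#' @param interaction include the stress:diet interaction term.
#' @param batch optional name of a column in `design` used as an additive
#'   covariate.
#' @return numeric design matrix with a `"stress"` column; attribute
#'   `"contrast"` names the coefficient of interest.
#' @export
build_design_matrix <- function(design, interaction = TRUE, batch = NULL) {
  stress_lv <- sort(unique(design$stress))
  if (length(stress_lv) != 2)
    stop("design must contain exactly two stress levels")
  s <- ifelse(design$stress == "stress", 0.5, -0.5)
  X <- cbind(intercept = 1, stress = s)
  diet_lv <- unique(design$diet)
  if (!is.null(design$diet) && length(diet_lv) == 2) {
    d <- ifelse(design$diet == diet_lv[2], 0.5, -0.5)
    X <- cbind(X, diet = d)
    if (interaction) X <- cbind(X, stress_diet = s * d)
  }
  if (!is.null(batch)) {
    b <- design[[batch]]
    if (is.null(b)) stop(sprintf("batch column '%s' not found", batch))
    X <- cbind(X, batch = as.numeric(factor(b)) - mean(as.numeric(factor(b))))
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[seq(qrX$rank + 1, ncol(X))]]
    stop(sprintf("rank-deficient design; confounded term(s): %s",
                 paste(dropped, collapse = ", ")))
  }
  attr(X, "contrast") <- "stress"
  X
}

#' Fit per-probe linear models for one muscle
#'
#' Ordinary least-squares fit of each probe's log2 values on the design,
#' restricted to the samples of the requested muscle. All probes are
#' fitted in one matrix operation. Returns, per probe, the stress-effect
#' estimate (log2 stress - limited), the residual variance, the residual
#' degrees of freedom and the unscaled variance of the contrast.
#'
#' @param nm a `normalized_matrix` from [normalize_probes()].
#' @param muscle which muscle's arrays to fit (`NULL` = use all arrays).
#' @param interaction,batch passed to [build_design_matrix()].
#' @return data.frame `probe_id`, `log2_ratio`, `s2`, `df_residual`,
#'   `v_unscaled`.
#' @export
fit_probe_models <- function(nm, muscle = NULL, interaction = TRUE,
                             batch = NULL) {
  stopifnot(inherits(nm, "normalized_matrix"))
  des <- nm$design
  if (is.null(des)) stop("normalized matrix carries no design table")
  sel <- if (is.null(muscle)) rep(TRUE, nrow(des)) else des$muscle == muscle
  if (!any(sel)) stop(sprintf("no samples for muscle '%s'", muscle))
  des <- des[sel, , drop = FALSE]
  Y <- nm$log2_value[, des$sample, drop = FALSE]
  X <- build_design_matrix(des, interaction = interaction, batch = batch)

  cells <- table(des$stress, des$diet)
  if (any(cells < 2))
    warning("fewer than 2 samples in some stress x diet cell")

  XtXi <- solve(crossprod(X))
  P <- XtXi %*% t(X)                      # p x n
  B <- Y %*% t(P)                         # probes x p
  resid <- Y - B %*% t(X)
  df <- ncol(Y) - ncol(X)
  if (df < 1) stop("not enough samples for residual degrees of freedom")
  s2 <- rowSums(resid^2) / df
  data.frame(probe_id = rownames(Y),
             log2_ratio = B[, "stress"],
             s2 = s2,
             df_residual = df,
             v_unscaled = XtXi["stress", "stress"],
             row.names = NULL, stringsAsFactors = FALSE)
}

# Invert the trigamma function by Newton iteration (monotone decreasing on
# (0, Inf)); used for moment-matching the variance prior.
trigamma_inverse <- function(x) {
  y <- 0.5 + 1 / x
  for (i in 1:60) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2)
    y <- y + dif
    if (max(abs(dif / y)) < 1e-10) break
  }
  y
}

#' Estimate the empirical-Bayes variance prior
#'
#' Moment-matches the log sample variances against the theoretical scaled
#' F distribution: with `e = log(s2) - digamma(df/2) + log(df/2)`, the
#' excess variance of `e` over `trigamma(df/2)` identifies the prior
#' degrees of freedom `d0` via the trigamma inverse, and its mean
#' identifies the prior variance `s0_sq`. Near-homogeneous variances
#' (non-positive excess) clamp `d0` at 1e6, effectively a fixed-variance
#' normal reference.
#'
#' @param s2 per-probe residual variances.
#' @param df residual degrees of freedom (scalar or vector).
#' @return list `d0`, `s0_sq`.
#' @export
estimate_variance_prior <- function(s2, df) {
  keep <- s2 > 0 & df >= 1
  if (!any(keep)) stop("no variance information: all residual variances are zero")
  if (sum(keep) < 10)
    stop("need at least 10 probes with positive variance to estimate the prior")
  s2 <- s2[keep]
  df <- rep_len(df, length(s2) + sum(!keep))[keep]
  e <- log(s2) - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  evar <- sum((e - emean)^2) / (length(e) - 1) - mean(trigamma(df / 2))
  if (evar > 0) {
    half_d0 <- trigamma_inverse(evar)
    d0 <- min(2 * half_d0, 1e6)
    s0_sq <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- 1e6
    s0_sq <- exp(emean)
  }
  list(d0 = d0, s0_sq = s0_sq)
}

#' Moderated t-statistics with empirical-Bayes shrunken variances
#'
#' Shrinks each probe's residual variance toward the prior:
#' `s2_post = (d0 * s0_sq + df * s2) / (d0 + df)`; the moderated t is the
#' effect divided by `sqrt(s2_post * v_unscaled)` and is referred to a t
#' distribution with `d0 + df` degrees of freedom (two-sided). `d0 = 0`
#' degenerates to the ordinary t; very large `d0` to a fixed-variance
#' normal reference.
#'
#' @param fit data.frame from [fit_probe_models()].
#' @param prior optional list `d0`, `s0_sq` overriding the estimated
#'   prior (used for the degenerate limits; estimated from `fit` when
#'   `NULL`).
#' @return `fit` with added columns `t_mod`, `p`, `d0`, `s0_sq`.
#' @export
moderate_t <- function(fit, prior = NULL) {
  if (is.null(prior))
    prior <- estimate_variance_prior(fit$s2, fit$df_residual)
  d0 <- prior$d0
  s0 <- prior$s0_sq
  s2_post <- if (is.infinite(d0)) rep(s0, nrow(fit)) else
    (d0 * s0 + fit$df_residual * fit$s2) / (d0 + fit$df_residual)
  se <- sqrt(s2_post * fit$v_unscaled)
  t_mod <- ifelse(se > 0, fit$log2_ratio / se,
                  ifelse(fit$log2_ratio == 0, 0, sign(fit$log2_ratio) * Inf))
  df_total <- pmin(d0 + fit$df_residual, 1e7)
  p <- 2 * stats::pt(-abs(t_mod), df = df_total)
  out <- fit
  out$t_mod <- t_mod
  out$p <- p
  out$d0 <- d0
  out$s0_sq <- s0
  out
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up adjustment (monotone, capped at 1). Input values must
#' lie in [0, 1].
#'
#' @param p numeric vector of p-values.
#' @return adjusted p-values in the input order.
#' @export
adjust_bh <- function(p) {
  if (length(p) == 0) return(numeric())
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Call differentially expressed genes from probe statistics
#'
#' A gene is called differentially expressed when at least `min_frac`
#' (default 80%) of its probes are significant at BH-adjusted p <
#' `alpha` (default 10%) and all of its probe log2 ratios share one sign
#' (all ratios below 1 or all above 1 on the natural scale). The
#' gene-level effect is the median probe log2 ratio; the fold change is
#' reported as `2^|effect|` signed by direction.
#'
#' @param stats data.frame from [moderate_t()] (needs `probe_id`,
#'   `log2_ratio` and either `p_adj` or `p`, which is then BH-adjusted).
#' @param probe_map data.frame `probe_id`, `gene`; must be functional
#'   (one gene per probe).
#' @param alpha adjusted-p significance threshold (strict `<`).
#' @param min_frac minimum fraction of significant probes (non-strict
#'   `>=`).
#' @return data.frame `gene`, `n_probes`, `n_significant`,
#'   `frac_significant`, `sign_consistent`, `direction`,
#'   `gene_log2_ratio`, `fold_change`, `is_deg`.
#' @export
call_genes <- function(stats, probe_map, alpha = 0.10, min_frac = 0.80) {
  if (anyDuplicated(probe_map$probe_id))
    stop("probe map is not functional: some probe maps to multiple genes")
  if (is.null(stats$p_adj)) stats$p_adj <- adjust_bh(stats$p)
  gene <- probe_map$gene[match(stats$probe_id, probe_map$probe_id)]
  if (any(is.na(gene)))
    stop("some probes in stats are absent from the probe map")
  sig <- stats$p_adj < alpha
  ratio <- stats$log2_ratio

  sp <- split(ratio, gene)
  n <- lengths(sp)
  ns <- vapply(split(sig, gene), sum, numeric(1))
  mins <- vapply(sp, min, numeric(1))
  maxs <- vapply(sp, max, numeric(1))
  med <- vapply(sp, stats::median, numeric(1))
  consistent <- mins > 0 | maxs < 0
  out <- data.frame(
    gene = names(sp), n_probes = as.integer(n), n_significant = as.integer(ns),
    frac_significant = ns / n, sign_consistent = consistent,
    direction = ifelse(!consistent, NA_character_,
                       ifelse(mins > 0, "up", "down")),
    gene_log2_ratio = med,
    fold_change = ifelse(med >= 0, 2^med, -(2^(-med))),
    is_deg = (ns / n >= min_frac) & consistent,
    row.names = NULL, stringsAsFactors = FALSE)
  out
}

#' Run the differential-expression stage for one muscle
#'
#' Convenience wrapper: fit, moderate, BH-adjust and call genes.
#'
#' @inheritParams fit_probe_models
#' @inheritParams call_genes
#' @return list `probe_stats` (with `p_adj`) and `gene_calls` (with a
#'   `muscle` column).
#' @export
run_diffexpr <- function(nm, probe_map, muscle = NULL, alpha = 0.10,
                         min_frac = 0.80, interaction = TRUE, batch = NULL) {
  fit <- fit_probe_models(nm, muscle = muscle, interaction = interaction,
                          batch = batch)
  st <- moderate_t(fit)
  st$p_adj <- adjust_bh(st$p)
  calls <- call_genes(st, probe_map, alpha = alpha, min_frac = min_frac)
  if (!is.null(muscle)) calls <- cbind(muscle = muscle, calls,
                                       stringsAsFactors = FALSE)
  list(probe_stats = st, gene_calls = calls)
}
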