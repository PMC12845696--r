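#' Fit a random-intercept mixed model for one feature
#'
#' Fits \eqn{y_{ij} = \beta_0 + \beta_1 Fatigue_{ij} + u_{0j} +
#' \varepsilon_{ij}} with participant-specific random intercepts
#' \eqn{u_{0j} \sim N(0, \sigma_u^2)} by REML (via \pkg{lme4}), where
#' \code{Fatigue} is the 0/1 condition label. Unequal per-participant stride
#' counts are handled naturally by the hierarchical structure.
#'
#' @param ft A feature table (see \code{\link{build_feature_table}}) with
#'   columns \code{participant}, \code{condition} and the feature.
#' @param feature Feature column name.
#' @param reml Use REML (default) or ML.
#' @return Object of class \code{lmm_fit}: list with the intercept and
#'   fatigue coefficient, standard errors, Wald z, p-value, 95\% Wald CI,
#'   group variance \code{sigma_u2}, residual variance \code{sigma2},
#'   variance of the fixed-effect linear predictor \code{sigma_f2},
#'   \code{n_obs}, \code{n_groups} and a \code{converged} flag.
#' @export
fit_random_intercept_model <- function(ft, feature, reml = TRUE) {
  if (!feature %in% names(ft)) stop("feature not in table: ", feature)
  d <- data.frame(y = ft[[feature]],
                  fatigue = as.numeric(ft$condition),
                  participant = factor(ft$participant))
  d <- d[is.finite(d$y), ]
  if (nlevels(droplevels(d$participant)) < 2)
    stop("need at least 2 participants to estimate a random intercept")
  if (length(unique(d$fatigue)) < 2)
    stop("both conditions must be present")
  fit <- lme4::lmer(y ~ fatigue + (1 | participant), data = d, REML = reml)
  msgs <- fit@optinfo$conv$lme4$messages
  converged <- is.null(msgs)
  if (!converged)
    warning("mixed-model fit flagged: ", paste(msgs, collapse = "; "))
  fe <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  z <- fe / se
  vc <- as.data.frame(lme4::VarCorr(fit))
  sigma_u2 <- vc$vcov[vc$grp == "participant"]
  sigma2 <- stats::sigma(fit)^2
  pred_fixed <- as.numeric(stats::model.matrix(fit) %*% fe)
  ci <- fe["fatigue"] + c(-1, 1) * stats::qnorm(0.975) * se["fatigue"]
  structure(list(feature = feature,
                 beta0 = unname(fe["(Intercept)"]),
                 beta1 = unname(fe["fatigue"]),
                 se0 = unname(se["(Intercept)"]),
                 se1 = unname(se["fatigue"]),
                 z = unname(z["fatigue"]),
                 p = unname(2 * stats::pnorm(-abs(z["fatigue"]))),
                 ci_lower = ci[1], ci_upper = ci[2],
                 sigma_u2 = sigma_u2, sigma2 = sigma2,
                 sigma_f2 = stats::var(pred_fixed),
                 n_obs = nrow(d),
                 n_groups = nlevels(droplevels(d$participant)),
                 converged = converged),
            class = "lmm_fit")
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat(sprintf(
    "Random-intercept LMM for %s: beta_fatigue = %.4f (SE %.4f, z = %.3f)\n",
    x$feature, x$beta1, x$se1, x$z))
  cat(sprintf("  group var %.4f, residual var %.4f, %d strides / %d participants\n",
              x$sigma_u2, x$sigma2, x$n_obs, x$n_groups))
  invisible(x)
}

#' Cohen's d from a mixed-model fit
#'
#' Standardized magnitude of the fatigue effect: the fixed-effect estimate
#' divided by the residual standard deviation, reported as a magnitude
#' (invariant to the sign of the coefficient).
#'
#' @param fit An \code{lmm_fit}.
#' @return Non-negative effect size d.
#' @export
cohen_d <- function(fit) {
  stopifnot(inherits(fit, "lmm_fit"), fit$sigma2 > 0)
  abs(fit$beta1) / sqrt(fit$sigma2)
}

#' Marginal and conditional R-squared (Nakagawa-Schielzeth)
#'
#' @param sigma_f2 Variance of the fixed-effect linear predictor over the
#'   observed design.
#' @param sigma_u2 Participant-level (random intercept) variance.
#' @param sigma2 Residual variance.
#' @return Named vector: \code{marginal} =
#'   \eqn{\sigma_f^2 / (\sigma_f^2 + \sigma_u^2 + \sigma^2)} and
#'   \code{conditional} = \eqn{(\sigma_f^2 + \sigma_u^2) / (\sigma_f^2 +
#'   \sigma_u^2 + \sigma^2)}.
#' @export
r2_marginal_conditional <- function(sigma_f2, sigma_u2, sigma2) {
  stopifnot(sigma_f2 >= 0, sigma_u2 >= 0, sigma2 >= 0)
  denom <- sigma_f2 + sigma_u2 + sigma2
  if (denom <= 0) stop("total variance must be positive")
  c(marginal = sigma_f2 / denom,
    conditional = (sigma_f2 + sigma_u2) / denom)
}

#' Partial R-squared of the fatigue effect
#'
#' Variance uniquely attributable to fatigue, from the Wald statistic of
#' the fatigue coefficient: \eqn{R^2 = z^2 / (z^2 + df)}, with \code{df}
#' approximating the effective residual degrees of freedom. By default the
#' effects layer uses \code{df = n_obs} (total strides in the model).
#'
#' @param z Wald z statistic of the fatigue coefficient.
#' @param df Effective residual degrees of freedom (> 0).
#' @return Partial R-squared in [0, 1); strictly increasing in |z| and
#'   strictly decreasing in df.
#' @export
partial_r2 <- function(z, df) {
  stopifnot(df > 0)
  z^2 / (z^2 + df)
}

#' Standardized effect sizes from a mixed-model fit
#'
#' @param fit An \code{lmm_fit}.
#' @param df Degrees of freedom for the partial R-squared (default: the
#'   fit's \code{n_obs}).
#' @return Object of class \code{effect_size_report}: list with Cohen's d,
#'   marginal, conditional and partial R-squared and the df used.
#' @export
effect_sizes <- function(fit, df = fit$n_obs) {
  stopifnot(inherits(fit, "lmm_fit"))
  r2 <- r2_marginal_conditional(fit$sigma_f2, fit$sigma_u2, fit$sigma2)
  structure(list(feature = fit$feature,
                 d = cohen_d(fit),
                 r2_marginal = unname(r2["marginal"]),
                 r2_conditional = unname(r2["conditional"]),
                 r2_partial = partial_r2(fit$z, df),
                 df = df),
            class = "effect_size_report")
}

#' Per-feature fatigue effects table with forest-plot export
#'
#' Fits the random-intercept model for each requested feature and derives
#' the standardized effect sizes; per-feature failures are isolated and
#' reported while the remaining features are still processed.
#'
#' @param ft A feature table.
#' @param features Character vector of feature column names.
#' @param df Degrees of freedom passed to \code{\link{effect_sizes}}
#'   (default: per-model n_obs).
#' @return Object of class \code{effects_table}: list with \code{effects}
#'   (one row per feature: coefficient, SE, z, p, CI, group/residual
#'   variance, d, marginal/conditional/partial R-squared), \code{forest}
#'   (feature, estimate, CI bounds) and \code{failures} (named character
#'   vector of error messages).
#' @export
effects_table <- function(ft, features, df = NULL) {
  rows <- list()
  forest <- list()
  failures <- character(0)
  for (f in features) {
    res <- tryCatch({
      fit <- fit_random_intercept_model(ft, f)
      es <- effect_sizes(fit, df = if (is.null(df)) fit$n_obs else df)
      list(fit = fit, es = es)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[f] <- conditionMessage(res)
      next
    }
    fit <- res$fit; es <- res$es
    rows[[f]] <- data.frame(
      feature = f, beta = fit$beta1, se = fit$se1, z = fit$z, p = fit$p,
      ci_lower = fit$ci_lower, ci_upper = fit$ci_upper,
      group_var = fit$sigma_u2, resid_var = fit$sigma2,
      d = es$d, r2_marginal = es$r2_marginal,
      r2_conditional = es$r2_conditional, r2_partial = es$r2_partial,
      df = es$df, n_obs = fit$n_obs, n_groups = fit$n_groups,
      converged = fit$converged)
    forest[[f]] <- data.frame(feature = f, estimate = fit$beta1,
                              ci_lower = fit$ci_lower,
                              ci_upper = fit$ci_upper)
  }
  if (length(failures))
    warning("effects_table: ", length(failures), " feature(s) failed: ",
            paste(names(failures), collapse = ", "))
  structure(list(effects = do.call(rbind, c(rows, make.row.names = FALSE)),
                 forest = do.call(rbind, c(forest, make.row.names = FALSE)),
                 failures = failures),
            class = "effects_table")
}

#' @export
print.effects_table <- function(x, ...) {
  cat("Fatigue fixed effects (random-intercept LMM):\n")
  print(x$effects[, c("feature", "beta", "se", "z", "p", "d", "r2_partial")],
        row.names = FALSE)
  invisible(x)
}
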