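#' Linear models with per-group residual variances
#'
#' Fits a main-effects linear model by iterative feasible generalized least
#' squares, optionally estimating a separate residual variance for each
#' level of a grouping factor (the classic "different variance per region"
#' structure for country growth rates). The algorithm alternates weighted
#' least squares for the coefficients with per-group variance
#' re-estimation, using leverage-corrected (REML-style) denominators
#' `RSS_g / (n_g - h_g)` where `h_g` is the trace of the weighted hat
#' matrix within group g, and iterates until the relative change in the
#' REML log-likelihood falls below `tol`. For the pure group-means model
#' this gives the exact REML estimates `RSS_g / (n_g - 1)`; with
#' covariates it is the standard feasible-GLS refinement. With
#' `variance = "homogeneous"` the fit is ordinary least squares.
#'
#' @param data Data frame holding the response, the grouping factor and any
#'   covariates. Rows with missing values in model variables are dropped
#'   listwise (count recorded in the fit).
#' @param formula Model formula, e.g. `d_diversity ~ region + d_area +
#'   d_dependence`.
#' @param group Name of the grouping factor whose levels get their own
#'   variance (default `"region"`). Must appear in the formula.
#' @param variance `"per_group"` (default) or `"homogeneous"`.
#' @param tol Convergence tolerance on the relative REML log-likelihood
#'   change (default 1e-8).
#' @param max_iter Maximum number of iterations (default 100).
#' @return An object of class `gls_fit`: a list with `coefficients`,
#'   `se`, `vcov`, `sigma2` (named per-group variances, or a single
#'   `residual` value), `logLik_ml`, `logLik_reml`, `aic` (REML-based),
#'   `fitted`, `residuals`, `data` (model frame used), `n_dropped`,
#'   `iterations`, `converged`, `trace` (REML log-likelihood per
#'   iteration), and bookkeeping needed by [ls_means()] and
#'   [tukey_contrasts()].
#' @seealso [compare_variance_models()], [ls_means()], [tukey_contrasts()],
#'   [tidy.gls_fit()], [glance.gls_fit()]
#' @export
fit_gls <- function(data, formula, group = "region",
                    variance = c("per_group", "homogeneous"),
                    tol = 1e-8, max_iter = 100) {
  variance <- match.arg(variance)
  vars <- all.vars(formula)
  if (!group %in% vars) {
    stop_cropdivr(sprintf("grouping factor '%s' must appear in the formula", group),
                  "cropdivr_validation_error")
  }
  df <- as_tibble(data)[vars]
  complete <- complete.cases(df)
  n_dropped <- sum(!complete)
  df <- df[complete, ]
  df[[group]] <- factor(df[[group]])
  g <- df[[group]]
  if (variance == "per_group") {
    small <- table(g) < 2
    if (any(small)) {
      stop_cropdivr(
        sprintf("group(s) with fewer than 2 observations under per_group variances: %s",
                paste(names(which(small)), collapse = ", ")),
        "cropdivr_validation_error"
      )
    }
  }
  levels_g <- levels(g)
  G <- length(levels_g)
  # a single-level factor cannot enter a model matrix; drop it (the fit
  # then coincides with the homogeneous fit on the remaining terms)
  formula_x <- formula
  if (G == 1) {
    formula_x <- stats::update.formula(formula, paste(". ~ . -", group))
  }
  X <- model.matrix(formula_x, data = df)
  y <- df[[all.vars(formula)[1]]]
  n <- length(y)
  p <- ncol(X)
  if (qr(X)$rank < p) {
    stop_cropdivr("design matrix is rank deficient", "cropdivr_validation_error")
  }
  gi <- split(seq_len(n), g)

  wls <- function(w) {
    # weighted LS: w are per-observation precisions 1/sigma2_i
    XtW <- t(X * w)
    XtWX <- XtW %*% X
    beta <- solve(XtWX, XtW %*% y)
    list(beta = drop(beta), XtWX = XtWX,
         resid = drop(y - X %*% beta))
  }
  loglik <- function(sigma2_i, resid, XtWX) {
    ml <- -n / 2 * log(2 * pi) - sum(log(sigma2_i)) / 2 - sum(resid^2 / sigma2_i) / 2
    reml <- -(n - p) / 2 * log(2 * pi) - sum(log(sigma2_i)) / 2 -
      sum(resid^2 / sigma2_i) / 2 - determinant(XtWX, logarithm = TRUE)$modulus / 2
    c(ml = ml, reml = as.numeric(reml))
  }

  if (variance == "homogeneous" || G == 1) {
    fit <- wls(rep(1, n))
    rss <- sum(fit$resid^2)
    s2 <- rss / (n - p)
    # ML profile uses sigma2 = rss/n; REML uses rss/(n-p)
    ml <- -n / 2 * (log(2 * pi) + log(rss / n) + 1)
    reml <- loglik(rep(s2, n), fit$resid, fit$XtWX / s2)[["reml"]]
    sigma2 <- c(residual = s2)
    vcov_beta <- solve(fit$XtWX) * s2
    iterations <- 1L
    converged <- TRUE
    trace <- reml
    beta <- fit$beta
    resid <- fit$resid
    n_varpar <- 1L
  } else {
    # start from OLS residual variances per group (leverage-corrected)
    sigma2_g <- setNames(rep(var(y), G), levels_g)
    trace <- numeric(0)
    prev <- -Inf
    converged <- FALSE
    iterations <- 0L
    repeat {
      iterations <- iterations + 1L
      sigma2_i <- sigma2_g[as.character(g)]
      fit <- wls(1 / sigma2_i)
      # leverage (trace of weighted hat matrix) within each group
      A <- solve(fit$XtWX)
      hat_diag <- rowSums((X %*% A) * (X / sigma2_i))
      new_sigma2 <- vapply(levels_g, function(lv) {
        i <- gi[[lv]]
        sum(fit$resid[i]^2) / (length(i) - sum(hat_diag[i]))
      }, numeric(1))
      sigma2_g <- new_sigma2
      sigma2_i <- sigma2_g[as.character(g)]
      refit <- wls(1 / sigma2_i)
      ll <- loglik(sigma2_i, refit$resid, refit$XtWX)
      trace <- c(trace, ll[["reml"]])
      if (is.finite(prev) && abs(ll[["reml"]] - prev) <=
          tol * (abs(prev) + tol)) {
        converged <- TRUE
        fit <- refit
        break
      }
      prev <- ll[["reml"]]
      fit <- refit
      if (iterations >= max_iter) break
    }
    if (!converged) {
      stop_cropdivr(
        sprintf("feasible GLS did not converge in %d iterations", max_iter),
        "cropdivr_convergence_error", trace = trace
      )
    }
    sigma2_i <- sigma2_g[as.character(g)]
    ll <- loglik(sigma2_i, fit$resid, fit$XtWX)
    ml <- ll[["ml"]]
    reml <- ll[["reml"]]
    sigma2 <- sigma2_g
    vcov_beta <- solve(fit$XtWX)
    beta <- fit$beta
    resid <- fit$resid
    n_varpar <- G
  }

  structure(list(
    formula = formula,
    formula_x = formula_x,
    group = group,
    variance = variance,
    coefficients = setNames(beta, colnames(X)),
    se = setNames(sqrt(diag(vcov_beta)), colnames(X)),
    vcov = vcov_beta,
    sigma2 = sigma2,
    logLik_ml = ml,
    logLik_reml = reml,
    aic = -2 * reml + 2 * (p + n_varpar),
    fitted = drop(X %*% beta),
    residuals = resid,
    data = df,
    X = X,
    n = n,
    p = p,
    n_dropped = n_dropped,
    group_levels = levels_g,
    group_sizes = as.integer(table(g)[levels_g]),
    iterations = iterations,
    converged = converged,
    trace = trace
  ), class = "gls_fit")
}

#' @export
print.gls_fit <- function(x, ...) {
  cat(sprintf("Feasible-GLS fit (%s variances)\n", x$variance))
  cat("  formula: ", deparse(x$formula), "\n", sep = "")
  cat(sprintf("  n = %d (%d dropped), iterations = %d\n", x$n, x$n_dropped, x$iterations))
  cat(sprintf("  logLik (ML) = %.4f, (REML) = %.4f, AIC = %.4f\n",
              x$logLik_ml, x$logLik_reml, x$aic))
  cat("  coefficients:\n")
  print(round(rbind(estimate = x$coefficients, se = x$se), 4))
  cat("  group variances:\n")
  print(round(x$sigma2, 4))
  invisible(x)
}

#' Tidy a feasible-GLS fit
#'
#' @param x A `gls_fit`.
#' @param ... Unused.
#' @return One row per coefficient: `term`, `estimate`, `std.error`,
#'   `statistic`, `p.value` (t test on residual df `n - p`).
#' @method tidy gls_fit
#' @export
tidy.gls_fit <- function(x, ...) {
  stat <- x$coefficients / x$se
  tibble(
    term = names(x$coefficients),
    estimate = unname(x$coefficients),
    std.error = unname(x$se),
    statistic = unname(stat),
    p.value = 2 * pt(abs(unname(stat)), df = x$n - x$p, lower.tail = FALSE)
  )
}

#' Glance at a feasible-GLS fit
#'
#' @param x A `gls_fit`.
#' @param ... Unused.
#' @return One-row tibble: `nobs`, `n_dropped`, `df_residual`, `logLik`
#'   (REML), `logLik_ml`, `AIC`, `n_groups`, `iterations`, `converged`.
#' @method glance gls_fit
#' @export
glance.gls_fit <- function(x, ...) {
  tibble(
    nobs = x$n, n_dropped = x$n_dropped, df_residual = x$n - x$p,
    logLik = x$logLik_reml, logLik_ml = x$logLik_ml, AIC = x$aic,
    n_groups = length(x$group_levels), iterations = x$iterations,
    converged = x$converged
  )
}

#' Compare homogeneous- and per-group-variance fits
#'
#' Likelihood-ratio test (REML likelihoods; identical fixed effects make
#' them comparable) on `G - 1` degrees of freedom, plus the AIC
#' difference. Negative `delta_aic` means the heterogeneous model is
#' preferred.
#'
#' @param fit_homo,fit_hetero `gls_fit` objects with identical formulas
#'   and data, `variance = "homogeneous"` and `"per_group"` respectively.
#' @return One-row tibble: `delta_aic` (hetero minus homo), `lr_stat`,
#'   `df`, `p_value`, `preferred` (`"per_group"` or `"homogeneous"` by
#'   AIC).
#' @export
compare_variance_models <- function(fit_homo, fit_hetero) {
  if (!identical(deparse(fit_homo$formula), deparse(fit_hetero$formula)) ||
      fit_homo$n != fit_hetero$n) {
    stop_cropdivr("fits must share formula and data", "cropdivr_validation_error")
  }
  G <- length(fit_hetero$group_levels)
  if (G < 2) {
    stop_cropdivr("variance-model comparison needs at least 2 groups",
                  "cropdivr_validation_error")
  }
  lr <- max(0, 2 * (fit_hetero$logLik_reml - fit_homo$logLik_reml))
  df <- G - 1
  tibble(
    delta_aic = fit_hetero$aic - fit_homo$aic,
    lr_stat = lr,
    df = df,
    p_value = pchisq(lr, df = df, lower.tail = FALSE),
    preferred = if (fit_hetero$aic < fit_homo$aic) "per_group" else "homogeneous"
  )
}

# contrast vector for the adjusted mean of one factor level: factor at the
# level, covariates at their grand means, other factors at proportional
# weights (only the group factor is supported as a factor here)
lsmean_rows <- function(fit) {
  df <- fit$data
  g <- fit$group
  grid <- lapply(fit$group_levels, function(lv) {
    row <- df[1, , drop = FALSE]
    row[[g]] <- factor(lv, levels = fit$group_levels)
    for (v in names(df)) {
      if (v != g && is.numeric(df[[v]])) row[[v]] <- mean(df[[v]])
    }
    row
  })
  grid <- bind_rows(grid)
  model.matrix(fit$formula_x[-2], data = grid)
}

# Satterthwaite df for var(l' beta_hat) = sum_g v_g, v_g estimated on
# (n_g - h_g) df; homogeneous fits use the residual df directly.
contrast_df <- function(fit, l) {
  if (fit$variance == "homogeneous" || length(fit$group_levels) == 1) {
    return(fit$n - fit$p)
  }
  g <- factor(fit$data[[fit$group]], levels = fit$group_levels)
  sigma2_i <- fit$sigma2[as.character(g)]
  A <- fit$vcov # (X'WX)^-1
  u <- drop(fit$X %*% (A %*% l)) # per-observation loadings
  hat_diag <- rowSums((fit$X %*% A) * (fit$X / sigma2_i))
  v_g <- vapply(fit$group_levels, function(lv) {
    i <- which(g == lv)
    sum(u[i]^2) / fit$sigma2[lv]
  }, numeric(1))
  df_g <- vapply(fit$group_levels, function(lv) {
    i <- which(g == lv)
    length(i) - sum(hat_diag[i])
  }, numeric(1))
  v <- sum(v_g)
  v^2 / sum(v_g^2 / df_g)
}

#' Least-squares (adjusted) means per group level
#'
#' Model-based means for each level of the grouping factor, with numeric
#' covariates held at their grand means. With no covariates (and one
#' factor) these equal the raw group means.
#'
#' @param fit A `gls_fit` containing the grouping factor.
#' @return Tibble `level`, `estimate`, `se`, `df` (Satterthwaite under
#'   per-group variances, residual df otherwise).
#' @export
ls_means <- function(fit) {
  L <- lsmean_rows(fit)
  est <- unname(drop(L %*% fit$coefficients))
  se <- unname(sqrt(rowSums((L %*% fit$vcov) * L)))
  df <- vapply(seq_len(nrow(L)), function(i) contrast_df(fit, L[i, ]), numeric(1))
  out <- tibble(level = fit$group_levels, estimate = est, se = se, df = df)
  class(out) <- c("ls_means", class(out))
  attr(out, "fit") <- fit
  out
}

#' Tukey-adjusted pairwise contrasts between group levels
#'
#' All pairwise differences of least-squares means with Tukey-Kramer
#' adjustment through the studentized-range distribution, per-contrast
#' Satterthwaite degrees of freedom under per-group variances, and a
#' compact letter display (levels sharing a letter do not differ at
#' `alpha`).
#'
#' @param fit A `gls_fit`.
#' @param alpha Significance level for the letter display (default 0.05).
#' @return List with `contrasts` (tibble `level_1`, `level_2`, `estimate`,
#'   `se`, `df`, `t`, `p_adjusted`, `p_unadjusted`) and `letters` (tibble
#'   `level`, `estimate`, `letters`).
#' @export
tukey_contrasts <- function(fit, alpha = 0.05) {
  k <- length(fit$group_levels)
  if (k < 2) {
    stop_cropdivr("need at least 2 group levels for contrasts", "cropdivr_validation_error")
  }
  L <- lsmean_rows(fit)
  pairs <- utils::combn(k, 2)
  res <- lapply(seq_len(ncol(pairs)), function(j) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    l <- L[i1, ] - L[i2, ]
    est <- sum(l * fit$coefficients)
    se <- sqrt(drop(t(l) %*% fit$vcov %*% l))
    df <- contrast_df(fit, l)
    tval <- est / se
    tibble(
      level_1 = fit$group_levels[i1],
      level_2 = fit$group_levels[i2],
      estimate = est, se = se, df = df, t = tval,
      p_adjusted = ptukey(sqrt(2) * abs(tval), nmeans = k, df = df, lower.tail = FALSE),
      p_unadjusted = 2 * pt(abs(tval), df = df, lower.tail = FALSE)
    )
  })
  contrasts <- bind_rows(res)
  lsm <- ls_means(fit)
  letters_tbl <- compact_letters(
    levels = fit$group_levels,
    means = lsm$estimate,
    sig = contrasts$p_adjusted < alpha,
    pair_1 = contrasts$level_1,
    pair_2 = contrasts$level_2
  )
  list(contrasts = contrasts, letters = left_join(
    lsm %>% select("level", "estimate"), letters_tbl, by = "level"
  ))
}

# insert-and-absorb compact letter display: start with one all-level
# group; split every group containing a significantly different pair;
# drop groups that are subsets of others; letter groups ordered by mean.
compact_letters <- function(levels, means, sig, pair_1, pair_2) {
  groups <- list(levels)
  for (j in which(sig)) {
    a <- pair_1[j]; b <- pair_2[j]
    new_groups <- list()
    for (gset in groups) {
      if (a %in% gset && b %in% gset) {
        new_groups <- c(new_groups, list(setdiff(gset, a)), list(setdiff(gset, b)))
      } else {
        new_groups <- c(new_groups, list(gset))
      }
    }
    # absorb: drop any group contained in another
    keep <- rep(TRUE, length(new_groups))
    for (i in seq_along(new_groups)) {
      for (l in seq_along(new_groups)) {
        if (i != l && keep[i] &&
            all(new_groups[[i]] %in% new_groups[[l]]) &&
            (length(new_groups[[i]]) < length(new_groups[[l]]) || i > l)) {
          keep[i] <- FALSE
        }
      }
    }
    groups <- new_groups[keep]
  }
  groups <- groups[vapply(groups, length, integer(1)) > 0]
  ord <- order(vapply(groups, function(gset) mean(means[match(gset, levels)]), numeric(1)))
  groups <- groups[ord]
  lab <- vapply(levels, function(lv) {
    paste0(letters[which(vapply(groups, function(gset) lv %in% gset, logical(1)))],
           collapse = "")
  }, character(1))
  tibble(level = levels, letters = unname(lab))
}
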