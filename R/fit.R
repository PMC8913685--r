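#' Fit the gamma log-link growth GLMM
#'
#' Maximizes the Laplace-approximated marginal likelihood of the gamma
#' log-link mixed model with correlated per-tree random intercept and random
#' slope on standardized previous-year basal area. Estimation is delegated
#' to \pkg{glmmTMB} (maximum likelihood); the fit is warm-started from a
#' fixed-effects-only gamma GLM.
#'
#' @param design A [build_design()] object, or a pre-subsetted design list
#'   with the same fields.
#' @param keep_cols Optional character vector restricting the fixed-effect
#'   columns (used by the model ladder); `NULL` keeps all.
#' @param on_nonconvergence `"error"` (default) or `"warning"`.
#' @param optimizer_control Passed to [glmmTMB::glmmTMBControl()]'s
#'   `optCtrl`.
#' @return An object of class `fitted_growth_model` holding the fixed
#'   coefficients and their covariance, the 2x2 random-effect covariance,
#'   per-tree BLUPs, the gamma shape, log-likelihood, parameter count and
#'   AIC, plus the design's scaler and spec for prediction.
#' @export
fit_glmm <- function(design, keep_cols = NULL,
                     on_nonconvergence = c("error", "warning"),
                     optimizer_control = list(iter.max = 1000, eval.max = 1200)) {
  on_nonconvergence <- match.arg(on_nonconvergence)
  X <- design$X
  if (!is.null(keep_cols)) X <- X[, keep_cols, drop = FALSE]
  if (nlevels(design$tree) < 2L)
    stop("fit_glmm: need at least 2 trees for the random structure")
  n_par_free <- ncol(X) + 1L + 3L + 1L
  if (length(design$y) < 10L * n_par_free)
    warning(sprintf("fit_glmm: only %.1f observations per parameter",
                    length(design$y) / n_par_free))
  dat <- data.frame(.bai = design$y, .tree = design$tree, .ba_z = design$ba_z,
                    check.names = FALSE)
  for (nm in colnames(X)) dat[[nm]] <- X[, nm]
  fx <- if (ncol(X) > 0L) paste0("`", colnames(X), "`") else "1"
  form <- stats::as.formula(paste(".bai ~", paste(fx, collapse = " + "),
                                  "+ (1 + .ba_z | .tree)"))
  start <- NULL
  if (ncol(X) > 0L) {
    g0 <- try(stats::glm(stats::as.formula(paste(".bai ~", paste(fx, collapse = " + "))),
                         family = stats::Gamma(link = "log"), data = dat),
              silent = TRUE)
    if (!inherits(g0, "try-error") && all(is.finite(coef(g0))))
      start <- list(beta = coef(g0))
  }
  m <- glmmTMB::glmmTMB(
    form, data = dat, family = stats::Gamma(link = "log"), REML = FALSE,
    start = start,
    control = glmmTMB::glmmTMBControl(optCtrl = optimizer_control))
  if (!is.null(m$fit$convergence) && m$fit$convergence != 0) {
    msg <- sprintf("fit_glmm: optimizer did not converge (code %s): %s",
                   m$fit$convergence, m$fit$message %||% "")
    if (on_nonconvergence == "error") stop(msg) else warning(msg)
  }
  beta <- glmmTMB::fixef(m)$cond
  names(beta) <- gsub("`", "", names(beta))
  V <- try(as.matrix(vcov(m)$cond), silent = TRUE)
  if (inherits(V, "try-error") || !all(dim(V) == length(beta)))
    V <- matrix(NA_real_, length(beta), length(beta))
  dimnames(V) <- list(names(beta), names(beta))
  vc <- glmmTMB::VarCorr(m)$cond$.tree
  re_cov <- matrix(as.numeric(vc), 2, 2,
                   dimnames = list(c("intercept", "ba_slope"),
                                   c("intercept", "ba_slope")))
  boundary <- min(eigen(re_cov, symmetric = TRUE, only.values = TRUE)$values) < 1e-8
  if (boundary)
    warning("fit_glmm: random-effect covariance is (near-)singular; boundary fit")
  rr <- glmmTMB::ranef(m)$cond$.tree
  blups <- data.frame(tree = rownames(rr), b0 = rr[["(Intercept)"]],
                      b1 = rr[[".ba_z"]], stringsAsFactors = FALSE)
  ll <- logLik(m)
  llval <- as.numeric(ll)
  n_par <- attr(ll, "df")
  if (!is.finite(llval)) {
    # boundary fits (e.g. a random-effect variance collapsing to zero) give
    # a non-positive-definite Hessian; the optimizer objective is still the
    # maximized log-likelihood
    llval <- -m$fit$objective
    n_par <- ncol(X) + 1L + 3L + 1L
    warning("fit_glmm: non-finite logLik from a boundary fit; using the optimizer objective")
  }
  structure(
    list(beta = beta, vcov = V,
         se = sqrt(diag(V)),
         re_cov = re_cov, re_blups = blups,
         gamma_shape = 1 / glmmTMB::sigma(m)^2,
         loglik = llval, n_params = n_par,
         aic = 2 * n_par - 2 * llval,
         nobs = length(design$y), n_trees = nlevels(design$tree),
         boundary = boundary,
         fixed_cols = colnames(X),
         col_info = design$col_info, scaler = design$scaler,
         spec = design$spec),
    class = "fitted_growth_model")
}

#' @export
print.fitted_growth_model <- function(x, ...) {
  cat(sprintf("<fitted_growth_model> gamma(log) GLMM: %d obs, %d trees\n",
              x$nobs, x$n_trees))
  cat(sprintf("  %d fixed effects | shape %.3g | logLik %.1f | AIC %.1f (%d params)\n",
              length(x$beta) - 1L, x$gamma_shape, x$loglik, x$aic, x$n_params))
  cat(sprintf("  re sd (int, slope) = (%.3g, %.3g), corr %.2f%s\n",
              sqrt(x$re_cov[1, 1]), sqrt(x$re_cov[2, 2]),
              x$re_cov[1, 2] / sqrt(x$re_cov[1, 1] * x$re_cov[2, 2] + 1e-300),
              if (x$boundary) " [boundary]" else ""))
  invisible(x)
}

#' Coefficient table of a fitted growth model
#' @param object A `fitted_growth_model`.
#' @param ... Unused.
#' @return Data.frame with `term`, `estimate`, `se`.
#' @export
coef.fitted_growth_model <- function(object, ...) {
  data.frame(term = names(object$beta), estimate = unname(object$beta),
             se = unname(object$se), row.names = NULL)
}

#' The default nested model ladder
#'
#' The eight inclusion patterns of the three fixed-effect groups — moisture
#' (AI), seasonal climate (Cli) and geography (Geo) — with the random
#' structure always present: null (random effects only), each single group,
#' each pair, and the full model.
#'
#' @return Named list of character vectors (subsets of `ai`, `cli`, `geo`).
#' @export
default_ladder <- function() {
  list("Null model" = character(0),
       "AI" = "ai",
       "Geo" = "geo",
       "AI+Geo" = c("ai", "geo"),
       "Cli" = "cli",
       "AI+Cli" = c("ai", "cli"),
       "Cli+Geo" = c("cli", "geo"),
       "Full model" = c("ai", "cli", "geo"))
}

# fixed-effect columns active under a group-inclusion pattern
.pattern_cols <- function(col_info, groups) {
  keep <- logical(nrow(col_info))
  for (i in seq_len(nrow(col_info))) {
    g <- strsplit(col_info$groups[i], ",", fixed = TRUE)[[1]]
    keep[i] <- all(g %in% groups)
  }
  col_info$name[keep]
}

#' Fit and compare the nested model ladder
#'
#' Fits each group-inclusion pattern on the identical data and reports, per
#' model, the AIC, the AIC difference to the best model, and a likelihood
#' ratio test against the null model (chi-square `2 * delta logLik`, degrees
#' of freedom equal to the difference in parameter counts).
#'
#' @param design A [build_design()] object.
#' @param ladder Named list of group patterns; defaults to [default_ladder()].
#' @param ... Passed to [fit_glmm()].
#' @return A `model_comparison` data.frame with one row per model, plus the
#'   fitted models in attribute `fits`.
#' @export
compare_models <- function(design, ladder = default_ladder(), ...) {
  fits <- lapply(ladder, function(groups)
    fit_glmm(design, keep_cols = .pattern_cols(design$col_info, groups), ...))
  aic <- vapply(fits, `[[`, numeric(1), "aic")
  ll <- vapply(fits, `[[`, numeric(1), "loglik")
  np <- vapply(fits, `[[`, numeric(1), "n_params")
  has <- function(g) vapply(ladder, function(p) g %in% p, logical(1))
  null_idx <- which(vapply(ladder, length, integer(1)) == 0L)
  chisq <- df <- p <- rep(NA_real_, length(fits))
  if (length(null_idx) == 1L) {
    chisq <- 2 * (ll - ll[null_idx])
    df <- np - np[null_idx]
    p <- pchisq(chisq, df, lower.tail = FALSE)
    chisq[null_idx] <- df[null_idx] <- p[null_idx] <- NA_real_
  }
  out <- data.frame(
    model = names(ladder),
    ai = has("ai"), cli = has("cli"), geo = has("geo"),
    n_params = np, loglik = ll, aic = aic,
    delta_aic = aic - min(aic),
    chisq = chisq, df = df, p = p,
    row.names = NULL)
  attr(out, "fits") <- fits
  class(out) <- c("model_comparison", "data.frame")
  out
}

#' Likelihood-ratio test of one effect block
#'
#' Fits the design with and without the named group(s) and returns the
#' chi-square statistic, degrees of freedom and p-value of the nested
#' comparison.
#'
#' @param design A [build_design()] object.
#' @param drop Character vector of groups to drop (e.g. `"cli"`).
#' @param groups Groups of the encompassing model.
#' @param ... Passed to [fit_glmm()].
#' @return List with `chisq`, `df`, `p`, and both fits.
#' @export
lrt_block <- function(design, drop, groups = c("ai", "cli", "geo"), ...) {
  if (!all(drop %in% groups)) stop("lrt_block: models are not nested")
  full <- fit_glmm(design, keep_cols = .pattern_cols(design$col_info, groups), ...)
  red <- fit_glmm(design,
                  keep_cols = .pattern_cols(design$col_info, setdiff(groups, drop)),
                  ...)
  chisq <- 2 * (full$loglik - red$loglik)
  df <- full$n_params - red$n_params
  list(chisq = chisq, df = df, p = pchisq(chisq, df, lower.tail = FALSE),
       full = full, reduced = red)
}

#' Predict annual BAI from a fitted growth model
#'
#' Applies the stored scaler and design expansion to new data and returns
#' `exp(eta)` in mm^2/yr. At population level the random effects are set to
#' zero; otherwise per-tree BLUPs (intercept and basal-area slope) are
#' added for the trees named in `tree`.
#'
#' @param model A `fitted_growth_model`.
#' @param newdata Data.frame with the vocabulary variables (`ai`, `lat`,
#'   `alt`, seasonal climate columns such as `tmax_SUM`) and `ba_prev`
#'   unless `ba_fixed` is given.
#' @param ba_fixed Optional single basal area (mm^2) overriding `ba_prev`
#'   for every row (the "reference tree" of gridded application).
#' @param population_level If `TRUE` (default), random effects are zero.
#' @param tree Tree labels (matching the fitted grouping factor) for
#'   BLUP-level prediction.
#' @return Numeric vector of predicted BAI, mm^2/yr (strictly positive).
#' @export
predict_bai <- function(model, newdata, ba_fixed = NULL,
                        population_level = TRUE, tree = NULL) {
  stopifnot(inherits(model, "fitted_growth_model"))
  if (!is.null(ba_fixed)) newdata$ba_prev <- ba_fixed
  if (is.null(newdata$ba_prev))
    stop("predict_bai: newdata needs ba_prev (or pass ba_fixed)")
  dm <- .design_matrix(newdata, model$spec, scaler = model$scaler)
  X <- dm$X[, model$fixed_cols, drop = FALSE]
  eta <- model$beta[["(Intercept)"]] +
    drop(X %*% model$beta[colnames(X)])
  if (!population_level) {
    if (is.null(tree)) stop("predict_bai: tree labels needed for BLUP-level prediction")
    i <- match(as.character(tree), model$re_blups$tree)
    if (anyNA(i)) stop("predict_bai: unknown tree label(s)")
    eta <- eta + model$re_blups$b0[i] + model$re_blups$b1[i] * dm$ba_z
  }
  exp(eta)
}
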