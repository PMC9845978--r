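#' Between-tip trait correlation implied by the signal parameter
#'
#' The working correlation between tips decays with their patristic
#' distance at a rate set by the signal parameter alpha, in units of
#' inverse (normalized) tree height: alpha = 0 gives perfect correlation
#' everywhere, large alpha approaches independence.
#'
#' @param dist A `patristic` object or distance matrix.
#' @param alpha Non-negative signal parameter.
#' @param form `"exponential"` (default): R_ij = exp(-alpha d_ij), the
#'   correlation of a stationary two-state switching process;
#'   `"arcsine"`: R_ij = (2/pi) asin(exp(-alpha d_ij)), the binary-scale
#'   correlation a latent threshold process induces at balanced
#'   prevalence (the fitter's default working correlation, see
#'   [phyloglm_control()]).
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
tip_correlation <- function(dist, alpha, form = c("exponential", "arcsine")) {
  form <- match.arg(form)
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) || alpha < 0) {
    stop("alpha must be a single non-negative number", call. = FALSE)
  }
  D <- as_dist_matrix(dist)
  R <- exp(-alpha * D)
  if (form == "arcsine") R <- (2 / pi) * asin(R)
  diag(R) <- 1
  R
}

#' Control parameters for phylogenetic logistic regression
#'
#' @param alpha_min,alpha_max Bounds for the signal parameter (on the
#'   height-normalized tree). Hitting a bound is reported via
#'   `alpha_at_bound`, never silently clamped.
#' @param n_grid Number of log-spaced alpha values scanned before
#'   refinement.
#' @param refine Golden-section iterations refining alpha inside the best
#'   grid bracket (0 disables refinement, leaving alpha on the grid).
#' @param max_iter Maximum Newton iterations for the coefficient solve at
#'   each alpha.
#' @param tol Convergence tolerance on the coefficient change.
#' @param alpha_fixed Optional fixed value of the signal parameter; when
#'   given, no profile search is run (useful for sensitivity analyses and
#'   for evaluating the independence limit with a large value).
#' @param corr_form Working correlation family as a function of the signal
#'   parameter: `"arcsine"` (default), the binary-scale correlation
#'   (2/pi) asin(exp(-alpha d)) induced by a latent threshold process —
#'   its square-root-fast initial decay matches thresholded traits, so
#'   the estimated signal retains the long-range dependence that drives
#'   Wald-test calibration; or `"exponential"`, exp(-alpha d), the
#'   correlation of a stationary two-state switching process.
#' @return List of class `phyloglm_control`.
#' @export
phyloglm_control <- function(alpha_min = 1e-3, alpha_max = 1e3,
                             n_grid = 15L, refine = 25L,
                             max_iter = 100L, tol = 1e-8,
                             alpha_fixed = NULL,
                             corr_form = c("arcsine", "exponential")) {
  corr_form <- match.arg(corr_form)
  stopifnot(alpha_min > 0, alpha_max > alpha_min, n_grid >= 2L,
            max_iter >= 1L, tol > 0)
  if (!is.null(alpha_fixed)) stopifnot(alpha_fixed > 0)
  structure(list(alpha_min = alpha_min, alpha_max = alpha_max,
                 n_grid = as.integer(n_grid), refine = as.integer(refine),
                 max_iter = as.integer(max_iter), tol = tol,
                 alpha_fixed = alpha_fixed, corr_form = corr_form),
            class = "phyloglm_control")
}

#' Phylogenetic logistic regression for a binary tip trait
#'
#' Fits logit P(y_i = 1) = x_i' beta with phylogenetically correlated
#' residuals: the working covariance is
#' V(alpha) = D_mu^(1/2) R(alpha) D_mu^(1/2), D_mu = diag(mu(1-mu)),
#' with R(alpha) a correlation family decaying in the patristic
#' distances (see the `corr_form` control). Coefficients
#' solve iteratively reweighted estimating equations with a Firth-type
#' (Jeffreys) penalty, which keeps estimates finite under separation and
#' reduces small-sample bias; in the independence limit (large alpha or a
#' star phylogeny) the solution is exactly ordinary Firth-penalized
#' logistic regression. The signal parameter alpha is estimated by
#' maximizing the penalized Gaussian working log-likelihood over
#' [alpha_min, alpha_max], profiled over beta (coarse log-grid plus
#' golden-section refinement). Initialization is deterministic (the
#' ordinary Firth solution), so fits are reproducible without seeds.
#'
#' @param y Binary (0/1) response, one value per tip, in the row order of
#'   `dist`; must contain both classes.
#' @param X Design matrix including an intercept column, or NULL for an
#'   intercept-only fit. A vector is taken as a single predictor and an
#'   intercept is prepended.
#' @param dist A `patristic` object (see [patristic_matrix()]) or a
#'   distance matrix aligned with `y`.
#' @param control A [phyloglm_control()] list.
#' @return Object of class `phyloglm_fit`: coefficients (log-odds), their
#'   standard errors (from the working information at the solution),
#'   two-sided Wald p-values, `alpha`, `alpha_at_bound`, `converged`,
#'   `n_tips`, `logLik`, `vcov`.
#' @export
fit_phyloglm <- function(y, X = NULL, dist, control = phyloglm_control()) {
  D <- as_dist_matrix(dist)
  y <- as.numeric(y)
  n <- length(y)
  if (nrow(D) != n) stop("y and dist dimensions differ", call. = FALSE)
  if (!all(y %in% c(0, 1))) stop("y must be 0/1", call. = FALSE)
  if (all(y == y[1L])) stop("degenerate response: y is constant",
                            call. = FALSE)
  if (is.null(X)) X <- matrix(1, n, 1L, dimnames = list(NULL, "(Intercept)"))
  if (is.null(dim(X))) {
    X <- cbind("(Intercept)" = 1, x = as.numeric(X))
  }
  X <- as.matrix(X)
  if (nrow(X) != n) stop("y and X dimensions differ", call. = FALSE)
  if (qr(X)$rank < ncol(X)) stop("singular design matrix", call. = FALSE)
  if (is.null(colnames(X))) colnames(X) <- paste0("b", seq_len(ncol(X)) - 1L)

  res <- if (is.null(control$alpha_fixed)) {
    cpp_fit_phyloglm(y, X, D, control$alpha_min, control$alpha_max,
                     control$n_grid, control$refine,
                     control$max_iter, control$tol,
                     corr_form_code(control$corr_form))
  } else {
    a <- control$alpha_fixed
    cpp_fit_phyloglm(y, X, D, a, a * (1 + 1e-12), 2L, 0L,
                     control$max_iter, control$tol,
                     corr_form_code(control$corr_form))
  }
  fit <- build_phyloglm_fit(res, colnames(X), n, control)
  if (!is.null(control$alpha_fixed)) fit$alpha_at_bound <- FALSE
  fit
}

build_phyloglm_fit <- function(res, coef_names, n, control) {
  beta <- as.numeric(res$beta)
  se <- as.numeric(res$se)
  names(beta) <- names(se) <- coef_names
  z <- beta / se
  p <- 2 * stats::pnorm(-abs(z))
  p <- pmin(pmax(p, .Machine$double.xmin), 1)
  if (!res$converged) {
    warning("phyloglm fit did not converge; partial results returned")
  }
  if (isTRUE(res$ridged)) {
    warning("correlation matrix required a diagonal ridge; ",
            "consider a larger tip jitter")
  }
  structure(list(coefficients = beta, se = se, zstat = z, p_values = p,
                 alpha = res$alpha, alpha_at_bound = res$alpha_at_bound,
                 converged = res$converged, n_tips = n,
                 logLik = res$logLik,
                 vcov = matrix(res$vcov, length(beta),
                               dimnames = list(coef_names, coef_names)),
                 control = control),
            class = "phyloglm_fit")
}

#' @export
print.phyloglm_fit <- function(x, ...) {
  cat(sprintf(
    "phyloglm_fit: %d tips, alpha = %.4g%s%s\n", x$n_tips, x$alpha,
    if (x$alpha_at_bound) " (at bound)" else "",
    if (x$converged) "" else " [NOT CONVERGED]"))
  tab <- cbind(Estimate = x$coefficients, `Std.Err` = x$se,
               z = x$zstat, `p` = x$p_values)
  print(round(tab, 5))
  invisible(x)
}

#' @export
coef.phyloglm_fit <- function(object, ...) object$coefficients

#' @export
vcov.phyloglm_fit <- function(object, ...) object$vcov

#' Two-sided Wald test for one coefficient
#'
#' Positive and negative associations are both of interest, so the test is
#' two-sided: p = 2 Phi(-|beta_j / se_j|), with the coefficient sign
#' reported alongside.
#'
#' @param fit A converged `phyloglm_fit`.
#' @param coef_index Coefficient position (e.g. 2 for the predictor in an
#'   intercept + slope model).
#' @return List with `p` and `sign` (-1, 0 or 1).
#' @export
wald_p <- function(fit, coef_index) {
  stopifnot(inherits(fit, "phyloglm_fit"))
  if (coef_index < 1L || coef_index > length(fit$coefficients)) {
    stop("coef_index out of range", call. = FALSE)
  }
  b <- fit$coefficients[[coef_index]]
  list(p = unname(fit$p_values[[coef_index]]), sign = sign(b))
}

#' Serialize a fitted model to JSON
#' @param fit A `phyloglm_fit`.
#' @param path Output path.
#' @export
write_phyloglm <- function(fit, path) {
  jsonlite::write_json(
    list(coefficients = as.list(fit$coefficients),
         se = as.list(fit$se), p_values = as.list(fit$p_values),
         alpha = fit$alpha, alpha_at_bound = fit$alpha_at_bound,
         converged = fit$converged, n_tips = fit$n_tips,
         logLik = fit$logLik),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# grid-restricted fit against a precomputed correlation grid; internal,
# used by the bootstrap pipeline so Cholesky work is shared across fits
fit_phyloglm_grid <- function(y, X, grid, control) {
  res <- cpp_fit_grid(y, X, grid$Rinv, grid$logdetR, grid$alphas,
                      control$max_iter, control$tol)
  build_phyloglm_fit(res, colnames(X), length(y), control)
}

make_corr_grid <- function(D, control) {
  alphas <- exp(seq(log(control$alpha_min), log(control$alpha_max),
                    length.out = control$n_grid))
  g <- cpp_corr_grid(D, alphas, corr_form_code(control$corr_form))
  g$alphas <- alphas
  g
}

corr_form_code <- function(form) {
  if (identical(form, "arcsine")) 1L else 0L
}
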