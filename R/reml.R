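# Average-information REML engine.
#
# The model is y = X beta + sum_i c_i,  c_i ~ N(0, K_i theta_i),
# with the last structure always the identity (residual). The REML
# log-likelihood (up to a constant) is
#   logL = -1/2 [ log|V| + log|X' V^-1 X| + y' P y ],
#   P = V^-1 - V^-1 X (X' V^-1 X)^-1 X' V^-1.
# Updates are Newton steps with the average-information matrix
#   AI_ij = 1/2 y' P K_i P K_j P y,
# gradient dL/dtheta_i = -1/2 [ tr(P K_i) - y' P K_i P y ],
# with an expectation-maximization fallback whenever an AI step would leave
# the feasible region. Variance components are constrained to
# >= floor_frac * var(y); an optional projection enforces nonlinear
# feasibility constraints (used by the bivariate fit for the covariance).

# K entries may be NULL to denote the identity structure.
kmatvec <- function(K, x) if (is.null(K)) x else drop(K %*% x)

build_v <- function(K, theta, n) {
  V <- matrix(0, n, n)
  for (i in seq_along(K)) {
    if (is.null(K[[i]])) {
      diag(V) <- diag(V) + theta[i]
    } else {
      V <- V + theta[i] * K[[i]]
    }
  }
  V
}

#' Evaluate the REML log-likelihood directly
#'
#' Computes \eqn{-\frac12[\log|V| + \log|X'V^{-1}X| + y'Py]} for a given
#' variance-component vector, without any iteration. Useful for profiling
#' and verifying fits against direct maximization.
#'
#' @param theta Numeric vector of variance components, one per structure.
#' @param y Response vector.
#' @param X Fixed-effects design matrix (full column rank).
#' @param K List of covariance structure matrices aligned with \code{theta};
#'   use \code{NULL} for the identity (residual) structure.
#' @return The REML log-likelihood (constant terms omitted).
#' @export
reml_loglik <- function(theta, y, X, K) {
  n <- length(y)
  V <- build_v(K, theta, n)
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) return(-Inf)
  Vi <- chol2inv(ch)
  ViX <- Vi %*% X
  XtViX <- crossprod(X, ViX)
  chX <- tryCatch(chol(XtViX), error = function(e) NULL)
  if (is.null(chX)) return(-Inf)
  beta <- chol2inv(chX) %*% crossprod(ViX, y)
  r <- y - X %*% beta
  yPy <- sum(r * (Vi %*% r))
  -0.5 * (2 * sum(log(diag(ch))) + 2 * sum(log(diag(chX))) + yPy)
}

aireml <- function(y, X, K, is_var = rep(TRUE, length(K)), init = NULL,
                   floor_frac = 1e-6, tol_logl = 1e-8, tol_theta = 1e-6,
                   max_iter = 100L, project = NULL) {
  n <- length(y)
  q <- length(K)
  X <- as.matrix(X)
  if (qr(X)$rank < ncol(X)) stopf("fixed-effects design X is singular")
  if (n < ncol(X) + q + 1)
    stopf("need n >= n_fixed + n_components + 1 observations")
  vary <- var(y)
  floor_v <- floor_frac * vary
  if (is.null(init)) {
    init <- rep(vary / (q + 1), q)
    init[!is_var] <- 0
  }
  theta <- init
  flags <- character(0)
  logl_prev <- -Inf
  converged <- FALSE
  AI <- NULL
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    V <- build_v(K, theta, n)
    ch <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(ch)) {
      # feasibility projection should prevent this; recover with a ridge
      diag(V) <- diag(V) + 1e-6 * mean(diag(V))
      ch <- chol(V)
      flags <- union(flags, "ridge_added")
    }
    Vi <- chol2inv(ch)
    ViX <- Vi %*% X
    XtViX <- crossprod(X, ViX)
    chX <- chol(XtViX)
    XtViX_inv <- chol2inv(chX)
    P <- Vi - ViX %*% tcrossprod(XtViX_inv, ViX)
    Py <- drop(P %*% y)
    yPy <- sum(y * Py)
    logl <- -0.5 * (2 * sum(log(diag(ch))) + 2 * sum(log(diag(chX))) + yPy)

    KPy <- lapply(K, kmatvec, x = Py)
    trPK <- vapply(K, function(Ki) {
      if (is.null(Ki)) sum(diag(P)) else sum(P * Ki)
    }, numeric(1))
    yPKPy <- vapply(KPy, function(w) sum(Py * w), numeric(1))
    grad <- -0.5 * (trPK - yPKPy)
    PKPy <- lapply(KPy, function(w) drop(P %*% w))
    AI <- matrix(0, q, q)
    for (i in seq_len(q)) for (j in i:q) {
      AI[i, j] <- AI[j, i] <- 0.5 * sum(KPy[[i]] * PKPy[[j]])
    }

    dlogl <- abs(logl - logl_prev) / (abs(logl_prev) + 1e-10)
    if (rcond(AI) < 1e-12) flags <- union(flags, "flat_likelihood")
    step <- tryCatch(solve(AI, grad), error = function(e) NULL)
    if (is.null(step) || !all(is.finite(step))) {
      flags <- union(flags, "flat_likelihood")
      step <- grad / max(abs(diag(AI)), 1e-12)   # gradient fallback
    }
    proposal <- theta + step
    # active-set constrained Newton: clamp variance components that an AI
    # step would push below the floor and re-solve for the free ones;
    # fall back to EM when the constrained system degenerates
    at_bound <- rep(FALSE, q)
    for (pass in seq_len(q)) {
      viol <- is_var & !at_bound & proposal < floor_v
      if (!any(viol)) break
      at_bound <- at_bound | viol
      free <- !at_bound
      proposal[at_bound] <- floor_v
      if (!any(free)) break
      dv <- floor_v - theta[at_bound]
      rhs <- grad[free] - AI[free, at_bound, drop = FALSE] %*% dv
      step_f <- tryCatch(solve(AI[free, free, drop = FALSE], rhs),
                         error = function(e) NULL)
      if (is.null(step_f) || !all(is.finite(step_f))) {
        em <- theta + theta^2 / n * (yPKPy - trPK)
        proposal[free] <- ifelse(is_var[free],
                                 pmax(em[free], floor_v), em[free])
        break
      }
      proposal[free] <- theta[free] + drop(step_f)
    }
    if (any(is_var & proposal < floor_v))
      proposal[is_var] <- pmax(proposal[is_var], floor_v)
    if (!is.null(project)) proposal <- project(proposal)
    dtheta <- max(abs(proposal - theta))
    if (iter > 1L && dlogl < tol_logl && dtheta < tol_theta * vary) {
      converged <- TRUE
      theta <- proposal
      break
    }
    theta <- proposal
    logl_prev <- logl
  }
  if (!converged && !("flat_likelihood" %in% flags))
    flags <- union(flags, "max_iterations")
  # final evaluation at the accepted parameters
  logl <- reml_loglik(theta, y, X, K)
  vcv <- tryCatch(solve(AI), error = function(e) NULL)
  if (is.null(vcv) || any(!is.finite(vcv))) {
    flags <- union(flags, "se_unavailable")
    vcv <- matrix(NA_real_, q, q)
  }
  V <- build_v(K, theta, n)
  Vi <- chol2inv(chol(V))
  ViX <- Vi %*% X
  XtViX_inv <- chol2inv(chol(crossprod(X, ViX)))
  beta <- drop(XtViX_inv %*% crossprod(ViX, y))
  list(theta = theta, se = sqrt(pmax(diag(vcv), 0)), vcov = vcv,
       logLik = logl, iterations = iter,
       converged = converged && !("flat_likelihood" %in% flags),
       flags = flags, beta = beta, beta_cov = XtViX_inv)
}

#' Fit GRM-structured variance components by REML
#'
#' Partitions the phenotypic variance of \code{y} into components with the
#' supplied covariance structures plus an independent residual, by
#' average-information REML with expectation-maximization fallback.
#' Components are constrained to at least \code{1e-6 * var(y)}; standard
#' errors come from the inverse average-information matrix, and standard
#' errors of the variance proportions from the delta method.
#'
#' @param y Named numeric phenotype vector (typically a z-score from
#'   \code{\link{adjust_age}}). Missing values are dropped.
#' @param grms A \code{\link{grm_matrix}} or a named list of them (e.g.
#'   \code{list(G = A_g, GxE = A_ge)}). Matrices are aligned to the samples
#'   shared with \code{y}.
#' @param X Optional fixed-effects design matrix (named rows); an intercept
#'   column is always included.
#' @param max_iter,tol Iteration cap and relative log-likelihood tolerance.
#' @return An object of class \code{"greml"} with components, proportions of
#'   phenotypic variance, standard errors, the REML log-likelihood,
#'   convergence information, and fixed-effect estimates. Methods:
#'   \code{print}, \code{summary}, \code{coef}, \code{logLik}, \code{vcov},
#'   \code{fitted}, \code{residuals}, \code{simulate}.
#' @examples
#' sim <- simulate_cohort(sim_config(300, 300, h2_g = 0.4, seed = 6))
#' A <- compute_grm(sim$genotypes)
#' fit <- greml(setNames(sim$samples$TRAIT1, sim$samples$IID), list(G = A))
#' fit
#' @export
greml <- function(y, grms, X = NULL, max_iter = 100L, tol = 1e-8) {
  if (inherits(grms, "grm_matrix")) grms <- list(G = grms)
  if (!is.list(grms) || !all(vapply(grms, inherits, TRUE, "grm_matrix")))
    stopf("`grms` must be a grm_matrix or a list of them")
  if (is.null(names(grms)) || any(names(grms) == ""))
    names(grms) <- paste0("G", seq_along(grms))
  ids <- grms[[1]]$sample_ids
  if (!is.null(names(y))) {
    ids <- ids[ids %in% names(y)]
    yv <- y[ids]
  } else {
    if (length(y) != length(ids))
      stopf("`y` must be named by sample id or aligned with the GRM")
    yv <- y
    names(yv) <- ids
  }
  keep <- !is.na(yv)
  yv <- yv[keep]
  ids <- ids[keep]
  n <- length(yv)
  K <- lapply(grms, function(A) subset_grm(A, ids)$values)
  K <- c(K, list(e = NULL))
  if (is.null(X)) {
    Xm <- matrix(1, n, 1, dimnames = list(ids, "(Intercept)"))
  } else {
    X <- as.matrix(X)
    if (!is.null(rownames(X))) X <- X[ids, , drop = FALSE]
    else if (nrow(X) != n) stopf("X rows must match the analysis samples")
    Xm <- cbind("(Intercept)" = 1, X)
  }
  fit <- aireml(yv, Xm, K, max_iter = max_iter, tol_logl = tol)
  comp_names <- c(paste0("V(", names(grms), ")"), "V(e)")
  est <- setNames(fit$theta, comp_names)
  vp <- sum(est)
  props <- est[-length(est)] / vp
  names(props) <- paste0(comp_names[-length(comp_names)], "/Vp")
  # delta method for proportions h_i = theta_i / sum(theta)
  q <- length(est)
  J <- matrix(-rep(fit$theta[-q], each = q) / vp^2, nrow = q)
  J[cbind(seq_len(q - 1), seq_len(q - 1))] <-
    J[cbind(seq_len(q - 1), seq_len(q - 1))] + 1 / vp
  se_props <- sqrt(pmax(diag(t(J) %*% fit$vcov %*% J), 0))
  names(se_props) <- names(props)
  se_vp <- sqrt(max(sum(fit$vcov), 0))
  structure(list(
    call = match.call(), n = n, sample_ids = ids,
    components = est, se = setNames(fit$se, comp_names),
    Vp = vp, se_Vp = se_vp,
    props = props, se_props = se_props,
    vcov_components = fit$vcov,
    logLik = fit$logLik, iterations = fit$iterations,
    converged = fit$converged, flags = fit$flags,
    fixef = setNames(fit$beta, colnames(Xm)), beta_cov = fit$beta_cov,
    model = list(y = yv, X = Xm, K = K)
  ), class = "greml")
}

#' @export
print.greml <- function(x, digits = 4, ...) {
  cat("GREML variance-component fit (AI-REML)\n")
  tab <- data.frame(
    Source = c(names(x$components), "Vp", names(x$props)),
    Variance = c(x$components, x$Vp, x$props),
    SE = c(x$se, x$se_Vp, x$se_props)
  )
  tab$Variance <- signif(tab$Variance, digits)
  tab$SE <- signif(tab$SE, digits)
  print(tab, row.names = FALSE)
  cat(sprintf("logL = %.4f   n = %d   iterations = %d%s\n",
              x$logLik, x$n, x$iterations,
              if (x$converged) "" else
                paste0("   NOT CONVERGED [", paste(x$flags, collapse = ", "),
                       "]")))
  invisible(x)
}

#' @export
summary.greml <- function(object, ...) {
  structure(list(fit = object), class = "summary.greml")
}

#' @export
print.summary.greml <- function(x, ...) {
  print(x$fit)
  cat("\nFixed effects:\n")
  fe <- data.frame(Estimate = x$fit$fixef,
                   SE = sqrt(diag(x$fit$beta_cov)))
  print(signif(fe, 4))
  invisible(x)
}

#' @export
coef.greml <- function(object, ...) object$fixef

#' @export
logLik.greml <- function(object, ...) {
  structure(object$logLik, df = length(object$components),
            nobs = object$n, class = "logLik")
}

#' @export
vcov.greml <- function(object, which = c("fixef", "varcomp"), ...) {
  which <- match.arg(which)
  if (which == "fixef") object$beta_cov else object$vcov_components
}

#' @export
fitted.greml <- function(object, ...) {
  drop(object$model$X %*% object$fixef)
}

#' @export
residuals.greml <- function(object, ...) {
  object$model$y - fitted(object)
}

#' @export
simulate.greml <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  n <- object$n
  V <- build_v(object$model$K, object$components, n)
  ch <- chol(V)
  mu <- fitted(object)
  out <- as.data.frame(
    mu + t(ch) %*% matrix(rnorm(n * nsim), n, nsim)
  )
  names(out) <- paste0("sim_", seq_len(nsim))
  rownames(out) <- object$sample_ids
  out
}

#' Boundary likelihood-ratio test for a variance component
#'
#' The statistic is twice the log-likelihood difference between the full and
#' reduced fits (clamped at 0 with a warning if negative). Because the null
#' value of a variance component lies on the boundary of the parameter
#' space, the null distribution is the 50:50 mixture of a point mass at 0
#' and chi-square with 1 df, so \eqn{p = \frac12 P(\chi^2_1 \ge LRT)}; a
#' statistic of 0 gives p = 0.5.
#'
#' @param full,reduced \code{\link{greml}} fits, the reduced model nested in
#'   the full with exactly one fewer variance component. Numeric
#'   log-likelihoods are also accepted.
#' @return An object of class \code{"greml_lrt"} with \code{statistic},
#'   \code{p_value}, and \code{df_note}.
#' @examples
#' lrt(5.84, 0)  # statistic 11.68
#' @export
lrt <- function(full, reduced) {
  if (inherits(full, "greml") && inherits(reduced, "greml")) {
    if (length(full$components) - length(reduced$components) != 1L)
      stopf("reduced model must have exactly one fewer component than the full model")
    nf <- names(reduced$components)
    if (!all(nf %in% names(full$components)))
      stopf("models are not nested: reduced components %s not all in full",
            paste(nf, collapse = ", "))
    ll_f <- full$logLik
    ll_r <- reduced$logLik
  } else if (is.numeric(full) && is.numeric(reduced)) {
    ll_f <- full
    ll_r <- reduced
  } else {
    stopf("`full` and `reduced` must both be greml fits (or log-likelihoods)")
  }
  stat <- 2 * (ll_f - ll_r)
  if (stat < 0) {
    warnf("negative LRT statistic (%.3g) clamped to 0", stat)
    stat <- 0
  }
  p <- 0.5 * pchisq(stat, df = 1, lower.tail = FALSE)
  structure(list(statistic = stat, p_value = p,
                 df_note = "50:50 mixture of point mass at 0 and chi-square(1)"),
            class = "greml_lrt")
}

#' @export
print.greml_lrt <- function(x, ...) {
  cat(sprintf("Boundary LRT: statistic = %.4f, p = %.3g\n", x$statistic,
              x$p_value))
  cat(" null:", x$df_note, "\n")
  invisible(x)
}

#' Genotype-environment interaction heritability
#'
#' Headline analysis for one trait and one environmental factor: fits the
#' full mixed model with additive and environment-masked interaction GRMs,
#' \eqn{V = A_g\sigma^2_g + A_{ge}\sigma^2_{ge} + I\sigma^2_\epsilon}, the
#' reduced model without the interaction component, and the boundary
#' likelihood-ratio test of \eqn{H_0: \sigma^2_{ge} = 0} (with
#' \eqn{\sigma^2_g} free). An environment-indicator column is included among
#' the fixed effects.
#'
#' @param y Named phenotype vector (adjusted z-scores).
#' @param grm Additive \code{\link{grm_matrix}}.
#' @param env Environment factor (named by sample id), >= 2 levels.
#' @param ... Passed to \code{\link{greml}}.
#' @return An object of class \code{"gxe_herit"}: list with \code{full},
#'   \code{reduced} (both \code{greml} fits), \code{lrt}, and the factor
#'   name.
#' @examples
#' cfg <- sim_config(400, 300, h2_g = 0.1, h2_ge = 0.3, seed = 8)
#' sim <- simulate_cohort(cfg)
#' A <- compute_grm(sim$genotypes)
#' fit <- gxe_heritability(setNames(sim$samples$TRAIT1, sim$samples$IID),
#'                         A, sim$env)
#' fit
#' @export
gxe_heritability <- function(y, grm, env, ...) {
  stopifnot(inherits(grm, "grm_matrix"))
  env_name <- attr(env, "env_name") %||% "environment"
  env <- align_env(env, grm$sample_ids)
  attr(env, "env_name") <- env_name
  if (nlevels(env) < 2L)
    stopf("interaction analysis needs an environment factor with >= 2 levels")
  A_ge <- gxe_grm(grm, env)
  Xe <- stats::model.matrix(~env)[, -1, drop = FALSE]
  rownames(Xe) <- grm$sample_ids
  colnames(Xe) <- paste0("env", levels(env)[-1])
  full <- greml(y, list(G = grm, GxE = A_ge), X = Xe, ...)
  reduced <- greml(y, list(G = grm), X = Xe, ...)
  test <- lrt(full, reduced)
  structure(list(full = full, reduced = reduced, lrt = test,
                 env_name = attr(env, "env_name") %||% "env"),
            class = "gxe_herit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.gxe_herit <- function(x, digits = 3, ...) {
  f <- x$full
  cat(sprintf("Genotype-%s interaction analysis (n = %d)\n", x$env_name, f$n))
  cat(sprintf("  V(G)/Vp   = %.3f (s.e. %.3f)\n",
              f$props[["V(G)/Vp"]], f$se_props[["V(G)/Vp"]]))
  cat(sprintf("  V(GxE)/Vp = %.3f (s.e. %.3f)\n",
              f$props[["V(GxE)/Vp"]], f$se_props[["V(GxE)/Vp"]]))
  cat(sprintf("  LRT = %.2f, p = %.2g (boundary mixture null)\n",
              x$lrt$statistic, x$lrt$p_value))
  if (!f$converged) cat("  WARNING: full model did not converge cleanly\n")
  invisible(x)
}

#' Write a variance-component result as tab-separated text
#'
#' Emits an .hsq-style table (Source, Variance, SE) with log-likelihood,
#' LRT, p-value and sample size rows.
#'
#' @param x A \code{"gxe_herit"} or \code{"greml"} object.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_hsq <- function(x, path) {
  if (inherits(x, "gxe_herit")) {
    f <- x$full
    extra <- data.frame(Source = c("logL", "logL0", "LRT", "Pval", "n"),
                        Variance = c(f$logLik, x$reduced$logLik,
                                     x$lrt$statistic, x$lrt$p_value, f$n),
                        SE = NA_real_)
  } else {
    f <- x
    extra <- data.frame(Source = c("logL", "n"),
                        Variance = c(f$logLik, f$n), SE = NA_real_)
  }
  tab <- rbind(
    data.frame(Source = names(f$components), Variance = unname(f$components),
               SE = unname(f$se)),
    data.frame(Source = "Vp", Variance = f$Vp, SE = f$se_Vp),
    data.frame(Source = names(f$props), Variance = unname(f$props),
               SE = unname(f$se_props)),
    extra
  )
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
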