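# Bivariate REML: the same trait measured in two environments, on disjoint
# individuals, treated as two traits. Genetic (co)variances flow through the
# between-set blocks of the additive GRM; there is no residual covariance
# because no individual carries both traits.

# AI-REML on the fixed-correlation manifold sigma_g12 = r sqrt(s1 s2):
# V = s1 K11 + s2 K22 + r sqrt(s1 s2) Kc + e1 E1 + e2 E2, optimized over
# theta = (s1, s2, e1, e2) with analytic dV/dtheta. Used as the constrained
# fit for correlation tests and to polish unconstrained fits whose optimum
# lies on the |r_g| = 1 boundary.
reml_rg_fixed <- function(y, X, K11, K22, Kc, E1, E2, r, init,
                          floor_frac = 1e-6, tol_logl = 1e-8,
                          max_iter = 100L) {
  n <- length(y)
  vary <- var(y)
  floor_v <- floor_frac * vary
  theta <- pmax(init, floor_v)
  build <- function(th) {
    th[1] * K11 + th[2] * K22 + r * sqrt(th[1] * th[2]) * Kc +
      th[3] * E1 + th[4] * E2
  }
  loglik <- function(th) reml_loglik_vm(build(th), y, X)
  logl_prev <- -Inf
  converged <- FALSE
  AI <- NULL
  for (iter in seq_len(max_iter)) {
    V <- build(theta)
    ch <- chol(V)
    Vi <- chol2inv(ch)
    ViX <- Vi %*% X
    XtViX <- crossprod(X, ViX)
    chX <- chol(XtViX)
    P <- Vi - ViX %*% tcrossprod(chol2inv(chX), ViX)
    Py <- drop(P %*% y)
    logl <- -0.5 * (2 * sum(log(diag(ch))) + 2 * sum(log(diag(chX))) +
                      sum(y * Py))
    B <- list(
      K11 + (r / 2) * sqrt(theta[2] / theta[1]) * Kc,
      K22 + (r / 2) * sqrt(theta[1] / theta[2]) * Kc,
      E1, E2
    )
    BPy <- lapply(B, function(Bi) drop(Bi %*% Py))
    trPB <- vapply(B, function(Bi) sum(P * Bi), numeric(1))
    yPBPy <- vapply(BPy, function(w) sum(Py * w), numeric(1))
    grad <- -0.5 * (trPB - yPBPy)
    PBPy <- lapply(BPy, function(w) drop(P %*% w))
    AI <- matrix(0, 4, 4)
    for (i in 1:4) for (j in i:4) {
      AI[i, j] <- AI[j, i] <- 0.5 * sum(BPy[[i]] * PBPy[[j]])
    }
    step <- tryCatch(solve(AI, grad), error = function(e) grad / diag(AI))
    proposal <- theta + step
    h <- 1
    while (any(proposal < floor_v) && h > 1e-3) {
      h <- h / 2
      proposal <- theta + h * step
    }
    proposal <- pmax(proposal, floor_v)
    dlogl <- abs(logl - logl_prev) / (abs(logl_prev) + 1e-10)
    if (iter > 1L && dlogl < tol_logl) {
      converged <- TRUE
      theta <- proposal
      break
    }
    theta <- proposal
    logl_prev <- logl
  }
  list(theta = theta, logLik = loglik(theta), converged = converged,
       AI = AI)
}

# REML log-likelihood for an already-built V.
reml_loglik_vm <- function(V, y, X) {
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) return(-Inf)
  Vi <- chol2inv(ch)
  ViX <- Vi %*% X
  XtViX <- crossprod(X, ViX)
  chX <- tryCatch(chol(XtViX), error = function(e) NULL)
  if (is.null(chX)) return(-Inf)
  beta <- chol2inv(chX) %*% crossprod(ViX, y)
  rr <- y - X %*% beta
  -0.5 * (2 * sum(log(diag(ch))) + 2 * sum(log(diag(chX))) +
            sum(rr * (Vi %*% rr)))
}

#' Bivariate REML genetic correlation across two environments
#'
#' Stacks the two phenotype vectors and fits the five-parameter model with
#' structures \eqn{\sigma^2_{g1}} and \eqn{\sigma^2_{g2}} on the
#' within-environment GRM blocks, the genetic covariance \eqn{\sigma_{g12}}
#' on the between-environment blocks, and per-environment residual
#' variances. The genetic correlation is derived as
#' \eqn{r_g = \sigma_{g12} / \sqrt{\sigma^2_{g1}\sigma^2_{g2}}} with a
#' delta-method standard error; the feasibility constraint
#' \eqn{|\sigma_{g12}| \le \sqrt{\sigma^2_{g1}\sigma^2_{g2}}} is enforced by
#' projection, so \eqn{r_g \in [-1, 1]} by construction.
#'
#' @param y1,y2 Named phenotype vectors for the two environments; the sample
#'   sets must be disjoint and each of size >= 30.
#' @param A Additive \code{\link{grm_matrix}} covering the union of both
#'   sample sets.
#' @param max_iter,tol Iteration cap and relative log-likelihood tolerance.
#' @return An object of class \code{"greml_bivar"}: genetic variances,
#'   covariance and residual variances with SEs, \code{rg} and \code{se_rg},
#'   the REML log-likelihood, and convergence information.
#' @examples
#' cfg <- sim_config(400, 300, h2_g = 0.5, rg = 1, seed = 9)
#' G <- simulate_genotypes(cfg)
#' env <- factor(rep(c(1, 2), each = 200))
#' sim <- simulate_bivariate(G, env, cfg)
#' fit <- bivar_reml(sim$y[env == 1], sim$y[env == 2], compute_grm(G))
#' fit$rg
#' @export
bivar_reml <- function(y1, y2, A, max_iter = 100L, tol = 1e-8) {
  stopifnot(inherits(A, "grm_matrix"))
  if (is.null(names(y1)) || is.null(names(y2)))
    stopf("`y1` and `y2` must be named by sample id")
  y1 <- y1[!is.na(y1)]
  y2 <- y2[!is.na(y2)]
  if (length(intersect(names(y1), names(y2))) > 0)
    stopf("the two sample sets must be disjoint")
  if (length(y1) < 30 || length(y2) < 30)
    stopf("each environment needs at least 30 phenotyped individuals")
  ids <- c(names(y1), names(y2))
  if (!all(ids %in% A$sample_ids))
    stopf("GRM does not cover all phenotyped samples")
  As <- subset_grm(A, ids)$values
  n1 <- length(y1)
  n2 <- length(y2)
  n <- n1 + n2
  i1 <- seq_len(n1)
  i2 <- n1 + seq_len(n2)
  zero <- matrix(0, n, n)
  K_g1 <- zero; K_g1[i1, i1] <- As[i1, i1]
  K_g2 <- zero; K_g2[i2, i2] <- As[i2, i2]
  K_c <- zero;  K_c[i1, i2] <- As[i1, i2]; K_c[i2, i1] <- As[i2, i1]
  K_e1 <- diag(c(rep(1, n1), rep(0, n2)))
  K_e2 <- diag(c(rep(0, n1), rep(1, n2)))
  K <- list(g1 = K_g1, g2 = K_g2, g12 = K_c, e1 = K_e1, e2 = K_e2)
  y <- c(y1, y2)
  X <- cbind(mu1 = c(rep(1, n1), rep(0, n2)),
             mu2 = c(rep(0, n1), rep(1, n2)))
  is_var <- c(TRUE, TRUE, FALSE, TRUE, TRUE)
  v1 <- var(y1); v2 <- var(y2)
  init <- c(v1 / 2, v2 / 2, 0, v1 / 2, v2 / 2)
  project <- function(theta) {
    bound <- sqrt(max(theta[1], 0) * max(theta[2], 0)) * (1 - 1e-8)
    theta[3] <- max(min(theta[3], bound), -bound)
    theta
  }
  fit <- aireml(y, X, K, is_var = is_var, init = init,
                max_iter = max_iter, tol_logl = tol, project = project)
  th <- fit$theta
  rg <- th[3] / sqrt(th[1] * th[2])
  if (abs(rg) >= 1 - 1e-6) {
    # the optimum lies on the |r_g| = 1 feasibility boundary: refit on the
    # fixed-correlation manifold, where the projected steps cannot stall
    r_sign <- sign(rg)
    bf <- reml_rg_fixed(y, X, K_g1, K_g2, K_c, K_e1, K_e2, r = r_sign,
                        init = th[c(1, 2, 4, 5)], tol_logl = tol,
                        max_iter = max_iter)
    if (bf$logLik >= fit$logLik - 1e-10) {
      th <- c(bf$theta[1], bf$theta[2],
              r_sign * sqrt(bf$theta[1] * bf$theta[2]),
              bf$theta[3], bf$theta[4])
      fit$theta <- th
      fit$logLik <- bf$logLik
      fit$converged <- bf$converged
      fit$flags <- union(fit$flags, "rg_boundary")
      rg <- r_sign
    }
  }
  # delta method for rg
  g <- c(-rg / (2 * th[1]), -rg / (2 * th[2]), 1 / sqrt(th[1] * th[2]), 0, 0)
  se_rg <- sqrt(max(drop(t(g) %*% fit$vcov %*% g), 0))
  est <- setNames(th, c("V(g1)", "V(g2)", "C(g12)", "V(e1)", "V(e2)"))
  structure(list(
    call = match.call(), n1 = n1, n2 = n2,
    components = est, se = setNames(fit$se, names(est)),
    rg = rg, se_rg = se_rg,
    h2 = c(env1 = th[1] / (th[1] + th[4]), env2 = th[2] / (th[2] + th[5])),
    vcov_components = fit$vcov,
    logLik = fit$logLik, iterations = fit$iterations,
    converged = fit$converged, flags = fit$flags,
    fixef = setNames(fit$beta, colnames(X)),
    model = list(y = y, X = X, K = K, is_var = is_var, project = project)
  ), class = "greml_bivar")
}

#' @export
print.greml_bivar <- function(x, digits = 4, ...) {
  cat("Bivariate GREML fit (two environments, disjoint samples)\n")
  tab <- data.frame(Source = names(x$components),
                    Estimate = signif(x$components, digits),
                    SE = signif(x$se, digits))
  print(tab, row.names = FALSE)
  cat(sprintf("r_g = %.3f (s.e. = %.3f)   h2: %.3f / %.3f\n",
              x$rg, x$se_rg, x$h2[1], x$h2[2]))
  cat(sprintf("logL = %.4f   n = %d + %d%s\n", x$logLik, x$n1, x$n2,
              if (x$converged) "" else "   NOT CONVERGED"))
  invisible(x)
}

#' @export
logLik.greml_bivar <- function(object, ...) {
  structure(object$logLik, df = length(object$components),
            nobs = object$n1 + object$n2, class = "logLik")
}

#' @export
coef.greml_bivar <- function(object, ...) object$fixef

#' Test the genetic correlation against a null value
#'
#' Refits the bivariate model with \eqn{r_g} constrained to
#' \code{null_value} and compares log-likelihoods. For \code{null_value = 0}
#' the constrained fit simply omits the covariance structure and the null is
#' interior, so \eqn{p = P(\chi^2_1 \ge 2\Delta logL)}. For
#' \code{null_value = 1} (or -1) the constraint
#' \eqn{\sigma_{g12} = r_0\sqrt{\sigma^2_{g1}\sigma^2_{g2}}} is imposed and
#' the likelihood is maximized over the remaining four log-variances by
#' direct optimization; the null then lies on the boundary of the feasible
#' region, which is noted in the output (the chi-square(1) reference is
#' conservative there).
#'
#' @param result A \code{\link{bivar_reml}} fit.
#' @param null_value The null genetic correlation, typically 0 or 1.
#' @return A list with \code{statistic}, \code{p_value}, \code{null_value},
#'   \code{logLik_constrained}, and \code{boundary} (logical note).
#' @export
test_rg <- function(result, null_value) {
  stopifnot(inherits(result, "greml_bivar"))
  if (!is.numeric(null_value) || abs(null_value) > 1)
    stopf("`null_value` must lie in [-1, 1]")
  m <- result$model
  if (null_value == 0) {
    K0 <- m$K[-3]
    fit0 <- aireml(m$y, m$X, K0, is_var = rep(TRUE, 4),
                   init = result$components[-3])
    ll0 <- fit0$logLik
    conv0 <- fit0$converged
  } else {
    th <- pmax(result$components, 1e-4 * var(m$y))
    bf <- reml_rg_fixed(m$y, m$X, m$K$g1, m$K$g2, m$K$g12,
                        m$K$e1, m$K$e2, r = null_value,
                        init = unname(th[c(1, 2, 4, 5)]))
    ll0 <- bf$logLik
    conv0 <- bf$converged
  }
  stat <- max(0, 2 * (result$logLik - ll0))
  p <- pchisq(stat, df = 1, lower.tail = FALSE)
  out <- list(statistic = stat, p_value = p, null_value = null_value,
              logLik_constrained = ll0, converged = conv0,
              boundary = abs(null_value) == 1)
  if (out$boundary)
    out$note <- "null on the feasibility boundary; chi-square(1) reference is conservative"
  class(out) <- "rg_test"
  out
}

#' @export
print.rg_test <- function(x, ...) {
  cat(sprintf("H0: r_g = %g   LRT = %.4f   p = %.3g\n", x$null_value,
              x$statistic, x$p_value))
  if (isTRUE(x$boundary)) cat(" note:", x$note, "\n")
  if (!x$converged) cat(" WARNING: constrained fit did not converge\n")
  invisible(x)
}
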