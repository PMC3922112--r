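# Independent oracles used to check package computations. These are written
# from first principles (base determinants, explicit enumeration, brute
# force) and deliberately share no code with the package internals.

# REML log-likelihood via base det()/solve(), no Cholesky shortcuts.
oracle_reml_loglik <- function(theta, y, X, Klist) {
  n <- length(y)
  V <- matrix(0, n, n)
  for (i in seq_along(Klist)) {
    Ki <- if (is.null(Klist[[i]])) diag(n) else Klist[[i]]
    V <- V + theta[i] * Ki
  }
  Vi <- solve(V)
  XtViX <- t(X) %*% Vi %*% X
  P <- Vi - Vi %*% X %*% solve(XtViX) %*% t(X) %*% Vi
  as.numeric(-0.5 * (determinant(V)$modulus +
                       determinant(XtViX)$modulus +
                       t(y) %*% P %*% y))
}

# Dense grid search over variance proportions with the overall scale
# profiled analytically (for ratios V0, the optimal scale is
# y'P0y / (n - p)). Returns the argmax proportions including the residual.
oracle_grid_reml <- function(y, X, Kstruct, step = 0.005) {
  n <- length(y)
  p <- ncol(X)
  q <- length(Kstruct)           # non-residual structures
  profile_logl <- function(h) {
    V0 <- diag(1 - sum(h), n)
    for (i in seq_len(q)) V0 <- V0 + h[i] * Kstruct[[i]]
    Vi <- tryCatch(solve(V0), error = function(e) NULL)
    if (is.null(Vi)) return(-Inf)
    XtViX <- t(X) %*% Vi %*% X
    P0 <- Vi - Vi %*% X %*% solve(XtViX) %*% t(X) %*% Vi
    qy <- as.numeric(t(y) %*% P0 %*% y)
    if (qy <= 0) return(-Inf)
    s <- qy / (n - p)
    as.numeric(-0.5 * (determinant(V0)$modulus + (n - p) * log(s) +
                         determinant(XtViX)$modulus + (n - p)))
  }
  grid1 <- seq(0, 1, by = step)
  best <- NULL
  best_ll <- -Inf
  if (q == 1L) {
    for (h1 in grid1) {
      ll <- profile_logl(h1)
      if (ll > best_ll) { best_ll <- ll; best <- h1 }
    }
  } else if (q == 2L) {
    for (h1 in grid1) {
      for (h2 in seq(0, 1 - h1, by = step)) {
        ll <- profile_logl(c(h1, h2))
        if (ll > best_ll) { best_ll <- ll; best <- c(h1, h2) }
      }
    }
  } else stop("oracle supports 1 or 2 structures")
  list(props = c(best, 1 - sum(best)), logLik = best_ll)
}

# HWE exact test by explicit enumeration with factorial(); valid for the
# small totals used in tests.
oracle_hwe <- function(nAA, nAa, naa) {
  n <- nAA + nAa + naa
  nA <- 2 * nAA + nAa
  na <- 2 * n - nA
  if (nA == 0 || na == 0) return(1)
  hets <- seq(nA %% 2, min(nA, na), by = 2)
  pr <- sapply(hets, function(h) {
    aa <- (nA - h) / 2
    bb <- (na - h) / 2
    factorial(n) / (factorial(aa) * factorial(h) * factorial(bb)) * 2^h
  })
  pr <- pr / sum(pr)
  obs <- pr[hets == nAa]
  sum(pr[pr <= obs + 1e-12])
}

# GRM entry by direct double loop over SNPs.
oracle_grm_entry <- function(dosage, j, k) {
  p <- colMeans(dosage, na.rm = TRUE) / 2
  tot <- 0
  cnt <- 0
  for (i in seq_len(ncol(dosage))) {
    xj <- dosage[j, i]
    xk <- dosage[k, i]
    if (is.na(xj) || is.na(xk)) next
    tot <- tot + (xj - 2 * p[i]) * (xk - 2 * p[i]) / (2 * p[i] * (1 - p[i]))
    cnt <- cnt + 1
  }
  tot / cnt
}

# Exhaustive search for the largest subset of individuals with no pair above
# the cutoff (feasible for tiny n).
oracle_max_unrelated <- function(values, cutoff) {
  n <- nrow(values)
  best <- integer(0)
  for (mask in seq_len(2^n) - 1L) {
    idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0)
    if (length(idx) <= length(best)) next
    sub <- values[idx, idx, drop = FALSE]
    diag(sub) <- 0
    if (all(sub <= cutoff)) best <- idx
  }
  best
}
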