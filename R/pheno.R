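#' Age-adjust and standardize a phenotype within strata
#'
#' Within each stratum independently, fits the ordinary least squares model
#' \eqn{y = b_0 + b_1 \times age + e} and standardizes the residuals to
#' z-scores (sample standard deviation, n - 1 denominator). The intended
#' strata are cohort-area x sex combinations, so that area and sex effects
#' are absorbed by the standardization and need not be refit downstream.
#'
#' Missing phenotype values propagate as \code{NA}; each stratum needs at
#' least 3 non-missing observations and non-zero residual variance.
#'
#' @param y Numeric phenotype vector (raw scale; apply any transform first,
#'   see \code{\link{apply_transform}}).
#' @param age Numeric age covariate, same length as \code{y}. If constant
#'   within a stratum the regression degenerates to centering.
#' @param strata Factor (or vector coercible to one) of stratum labels.
#' @return Numeric vector of z-scores aligned with \code{y} (mean 0,
#'   variance 1 within every stratum among non-missing entries).
#' @examples
#' set.seed(1)
#' y <- rnorm(40) + 0.02 * (50:89)
#' z <- adjust_age(y, 50:89, rep(c("m", "f"), 20))
#' tapply(z, rep(c("m", "f"), 20), mean)
#' @export
adjust_age <- function(y, age, strata) {
  if (length(y) != length(age) || length(y) != length(strata))
    stopf("`y`, `age` and `strata` must have equal length")
  strata <- as.factor(strata)
  if (anyNA(strata)) stopf("`strata` must be complete")
  out <- rep(NA_real_, length(y))
  for (s in levels(strata)) {
    idx <- which(strata == s)
    ok <- idx[!is.na(y[idx]) & !is.na(age[idx])]
    if (length(ok) < 3)
      stopf("stratum '%s' has fewer than 3 complete observations", s)
    ys <- y[ok]
    as_ <- age[ok]
    if (sd(as_) < .Machine$double.eps^0.5 * (abs(mean(as_)) + 1)) {
      r <- ys - mean(ys)
    } else {
      fit <- lm.fit(cbind(1, as_), ys)
      r <- fit$residuals
    }
    s_r <- sd(r)
    if (!is.finite(s_r) || s_r < 1e-10 * (sd(ys) + 1))
      stopf("stratum '%s' has zero residual variance; z-scores undefined", s)
    out[ok] <- r / s_r
  }
  names(out) <- names(y)
  out
}

#' Optional per-trait transform applied before adjustment
#'
#' @param y Numeric vector.
#' @param transform Either \code{"identity"} or \code{"log"} (natural log;
#'   requires strictly positive values).
#' @return Transformed vector.
#' @export
apply_transform <- function(y, transform = c("identity", "log")) {
  transform <- match.arg(transform)
  if (transform == "log") {
    if (any(y <= 0, na.rm = TRUE))
      stopf("log transform requires strictly positive phenotype values")
    return(log(y))
  }
  y
}

#' Encode an environmental factor from the sample table
#'
#' Three factors are supported: \code{area} (levels 1 = rural, 2 = urban),
#' \code{sex} (A = male, B = female), and \code{age_group}, a three-band
#' classification by birth year: A for years through 1945, B for 1946-1955,
#' C for 1956 onward. Birth years outside 1931-1963 are assigned by the same
#' band arithmetic with a warning.
#'
#' @param samples Data frame with columns \code{IID} and, as needed,
#'   \code{AREA}, \code{SEX}, \code{BIRTH_YEAR}.
#' @param factor_name One of \code{"area"}, \code{"sex"}, \code{"age_group"}.
#' @return A factor named by sample id, with attribute \code{"env_name"}.
#' @examples
#' s <- data.frame(IID = c("a", "b", "c"), BIRTH_YEAR = c(1945, 1946, 1960))
#' encode_env(s, "age_group")
#' @export
encode_env <- function(samples, factor_name = c("area", "sex", "age_group")) {
  factor_name <- match.arg(factor_name)
  if (!"IID" %in% names(samples)) stopf("sample table must have an IID column")
  col <- switch(factor_name, area = "AREA", sex = "SEX",
                age_group = "BIRTH_YEAR")
  if (!col %in% names(samples))
    stopf("sample table lacks required column '%s'", col)
  v <- samples[[col]]
  env <- switch(factor_name,
    area = factor(v, levels = sort(unique(v))),
    sex = factor(v, levels = sort(unique(v))),
    age_group = {
      if (any(v < 1931 | v > 1963, na.rm = TRUE))
        warnf("birth years outside 1931-1963 assigned by band arithmetic")
      factor(ifelse(v <= 1945, "A", ifelse(v <= 1955, "B", "C")),
             levels = c("A", "B", "C"))
    })
  env <- droplevels(env)
  names(env) <- samples$IID
  attr(env, "env_name") <- factor_name
  env
}

#' Adjust all traits of a sample table
#'
#' Applies the declared transform and \code{\link{adjust_age}} to each trait
#' column, standardizing within (area x sex) strata.
#'
#' @param samples Sample table with \code{IID}, \code{SEX}, \code{AREA} and
#'   the trait columns.
#' @param traits Character vector of trait column names.
#' @param age Numeric age vector aligned with the table (defaults to
#'   \code{exam_year - BIRTH_YEAR}).
#' @param transforms Named character vector mapping trait to
#'   \code{"identity"}/\code{"log"}; unlisted traits use identity.
#' @param exam_year Reference year used to derive age from birth year when
#'   no explicit age is supplied.
#' @return The sample table with adjusted z-score columns named
#'   \code{<trait>_Z}.
#' @export
adjust_traits <- function(samples, traits, age = NULL, transforms = NULL,
                          exam_year = 2003) {
  stopifnot(all(traits %in% names(samples)))
  if (is.null(age)) {
    if (!"BIRTH_YEAR" %in% names(samples))
      stopf("supply `age` or a BIRTH_YEAR column")
    age <- exam_year - samples$BIRTH_YEAR
  }
  strata <- interaction(samples$AREA, samples$SEX, drop = TRUE)
  for (tr in traits) {
    tf <- if (!is.null(transforms) && tr %in% names(transforms))
      transforms[[tr]] else "identity"
    yv <- apply_transform(samples[[tr]], tf)
    samples[[paste0(tr, "_Z")]] <- adjust_age(yv, age, strata)
  }
  samples
}
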