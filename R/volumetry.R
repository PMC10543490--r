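# Volumetry: mask volumes in cm^3, Gaussian GLMs (identity link) with Wald
# tests and maximum-likelihood log-likelihoods, McFadden pseudo-R^2, the
# lifespan regression of plexus volume on age/sex/TIV, and the regression
# of performance metrics on lateral ventricular volume.

#' Volume of a binary mask in cm^3
#'
#' Set-voxel count times voxel volume (product of spacings, mm^3) divided
#' by 1000. Additive over disjoint masks; an empty mask has volume 0.
#'
#' @param mask [binary_mask3d()].
#' @return Volume in cm^3.
#' @export
mask_volume_cm3 <- function(mask) {
  if (!is_mask(mask)) stopf("mask_volume_cm3: not a binary mask")
  sum(mask$data) * prod(mask$spacing) / 1000
}

#' Gaussian generalized linear model (identity link)
#'
#' Thin, validated wrapper around [stats::glm()] keeping the pieces needed
#' downstream: per-term coefficients with Wald tests, the Gaussian
#' log-likelihood under the maximum-likelihood variance estimate, and the
#' response (so nested fits can be checked before computing McFadden R^2).
#'
#' @param y numeric response.
#' @param X data frame of covariates (may be empty for an intercept-only
#'   fit).
#' @return Object of class `regression_fit`: `coefficients` data frame
#'   (`term`, `estimate`, `se`, `p_value`), `log_lik`, `n`, `response`,
#'   `perfect_fit` flag and the underlying `glm` object.
#' @export
fit_glm_gaussian <- function(y, X = NULL) {
  y <- as.numeric(y)
  if (anyNA(y)) stopf("response contains missing values")
  if (is.null(X) || ncol(as.data.frame(X)) == 0) {
    dat <- data.frame(.y = y)
    fml <- .y ~ 1
  } else {
    X <- as.data.frame(X)
    if (nrow(X) != length(y)) stopf("response/covariate length mismatch")
    if (anyNA(X)) stopf("covariates contain missing values")
    dat <- cbind(data.frame(.y = y), X)
    fml <- as.formula(paste(".y ~", paste(sprintf("`%s`", names(X)),
                                          collapse = " + ")))
  }
  fit <- glm(fml, data = dat, family = gaussian())
  mm <- stats::model.matrix(fit)
  if (fit$rank < ncol(mm)) {
    aliased <- names(which(is.na(coef(fit))))
    stopf("rank-deficient design; collinear term(s): %s",
          paste(aliased, collapse = ", "))
  }
  if (length(y) <= ncol(mm)) stopf("more terms than observations")
  sm <- summary(fit)$coefficients
  perfect <- summary(fit)$dispersion < 1e-12
  coefs <- data.frame(term = rownames(sm), estimate = sm[, 1], se = sm[, 2],
                      p_value = if (perfect) NA_real_ else sm[, 4],
                      row.names = NULL, stringsAsFactors = FALSE)
  structure(list(coefficients = coefs, log_lik = as.numeric(logLik(fit)),
                 n = length(y), response = y, perfect_fit = perfect,
                 glm = fit),
            class = "regression_fit")
}

#' @export
print.regression_fit <- function(x, ...) {
  cat(sprintf("<regression_fit> n = %d, logLik = %.3f\n", x$n, x$log_lik))
  print(x$coefficients, digits = 4)
  invisible(x)
}

#' McFadden pseudo-R^2
#'
#' `1 - logLik(fit) / logLik(null)` for a fit and its intercept-only null
#' on the same response.
#'
#' @param fit,null_fit [fit_glm_gaussian()] results sharing the response;
#'   `null_fit` must be intercept-only.
#' @return Scalar (0 when the fit is the null model).
#' @export
mcfadden_r2 <- function(fit, null_fit) {
  stopifnot(inherits(fit, "regression_fit"),
            inherits(null_fit, "regression_fit"))
  if (nrow(null_fit$coefficients) != 1L) {
    stopf("null fit must be intercept-only")
  }
  if (fit$n != null_fit$n ||
      max(abs(fit$response - null_fit$response)) > 1e-12) {
    stopf("fits do not share the same response")
  }
  1 - fit$log_lik / null_fit$log_lik
}

#' Lifespan regression of plexus volume on age, sex and TIV
#'
#' For each modality fits `volume ~ age + sex + tiv` (Gaussian GLM), with
#' sex coded F = 0, M = 1. All covariate p-values from the call are
#' adjusted jointly with Benjamini-Hochberg FDR; significance is declared
#' at adjusted p < `alpha`. The percent change per decade evaluates
#' `10 * beta_age / mean(volume) * 100` at the cohort mean volume, and
#' McFadden R^2 compares each fit with its intercept-only null.
#'
#' @param manifest cohort manifest (or any data frame with `subject_id`,
#'   `age`, `sex`, `tiv_cm3`).
#' @param volumes long-format data frame with columns `subject_id`,
#'   `modality`, `volume_cm3`.
#' @param alpha significance level on adjusted p-values.
#' @return list with `fits` (per modality), `table` (tidy coefficient table
#'   with `p_adj` and `significant`), `percent_per_decade` and
#'   `mcfadden_r2` per modality.
#' @export
lifespan_analysis <- function(manifest, volumes, alpha = 0.05) {
  need <- c("subject_id", "modality", "volume_cm3")
  if (!all(need %in% names(volumes))) {
    stopf("volumes table needs columns: %s", paste(need, collapse = ", "))
  }
  if (length(unique(manifest$subject_id)) < 10) {
    stopf("lifespan analysis needs at least 10 subjects")
  }
  mods <- unique(volumes$modality)
  fits <- list()
  rows <- list()
  ppd <- numeric(0)
  mcf <- numeric(0)
  for (mod in mods) {
    v <- volumes[volumes$modality == mod, ]
    m <- merge(v, as.data.frame(manifest), by = "subject_id")
    if (nrow(m) != nrow(v)) stopf("volumes reference unknown subjects")
    X <- data.frame(age = m$age, male = as.numeric(m$sex == "M"),
                    tiv = m$tiv_cm3)
    if (any(vapply(X, function(col) sd(col) < 1e-12, logical(1)))) {
      stopf("constant covariate column for modality %s", mod)
    }
    fit <- fit_glm_gaussian(m$volume_cm3, X)
    null_fit <- fit_glm_gaussian(m$volume_cm3)
    fits[[mod]] <- fit
    mcf[mod] <- mcfadden_r2(fit, null_fit)
    beta_age <- fit$coefficients$estimate[fit$coefficients$term == "age"]
    ppd[mod] <- 10 * beta_age / mean(m$volume_cm3) * 100
    cf <- fit$coefficients[fit$coefficients$term != "(Intercept)", ]
    cf$modality <- mod
    rows[[mod]] <- cf
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  tab$p_adj <- fdr_adjust(tab$p_value)
  tab$significant <- tab$p_adj < alpha
  list(fits = fits, table = tab, percent_per_decade = ppd,
       mcfadden_r2 = mcf, alpha = alpha)
}

#' Regress segmentation performance metrics on ventricular volume
#'
#' One Gaussian GLM per metric (`dice`, `hd95_mm`, `auc`) against lateral
#' ventricular volume, with a joint FDR adjustment of the slope p-values —
#' the atrophy-robustness check of the evaluation.
#'
#' @param scores per-subject metric table (as returned by
#'   [run_cross_validation()]).
#' @param lvv data frame with `subject_id` and `lvv_cm3`.
#' @return list with `fits` per metric and `table` of slopes with adjusted
#'   p-values.
#' @export
metrics_vs_ventricle <- function(scores, lvv) {
  m <- merge(scores, lvv, by = "subject_id")
  if (nrow(m) != nrow(scores)) stopf("subject ids do not match")
  metrics <- intersect(c("dice", "hd95_mm", "auc"), names(m))
  fits <- list()
  rows <- list()
  for (met in metrics) {
    keep <- is.finite(m[[met]])
    fit <- fit_glm_gaussian(m[[met]][keep],
                            data.frame(lvv = m$lvv_cm3[keep]))
    fits[[met]] <- fit
    cf <- fit$coefficients[fit$coefficients$term == "lvv", ]
    cf$metric <- met
    rows[[met]] <- cf
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  tab$p_adj <- NA_real_
  ok <- is.finite(tab$p_value)  # perfect fits carry no Wald p-value
  tab$p_adj[ok] <- fdr_adjust(tab$p_value[ok])
  list(fits = fits, table = tab)
}
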