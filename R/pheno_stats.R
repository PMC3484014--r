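# Phenotype computations associated with the rearranged allele: monomolecular
# (Brody) growth-curve fitting, sex-specific residual feed intake, and
# full-versus-reduced linear models with the variance share attributable to
# genotype.

#' Monomolecular (Brody) growth model
#'
#' W(t) = A - B * exp(-k t): A is the asymptotic body weight (g), B the range
#' of body weights from hatching to asymptote (g), k the relative growth rate
#' (per day), t the age in days.
#'
#' @param A,B,k Parameters (all > 0).
#' @export
GrowthParams <- function(A, B, k) {
  if (A <= 0 || B <= 0 || k <= 0)
    lavrec_error("growth parameters must be positive", "lavrec_validation_error")
  structure(list(A = A, B = B, k = k), class = "GrowthParams")
}

#' Evaluate the monomolecular growth curve
#' @param params A [GrowthParams] (or list with A, B, k).
#' @param t Age in days.
#' @export
growth_curve <- function(params, t) {
  params$A - params$B * exp(-params$k * t)
}

#' Fit the monomolecular growth model by nonlinear least squares
#'
#' Multi-start Levenberg-Marquardt fits of W(t) = A - B exp(-k t);
#' convergence to 1e-8 relative parameter change. Degenerate inputs (no
#' weight range, too few distinct ages) return a fit-failure report rather
#' than a silently wrong answer.
#'
#' @param ages Ages in days (>= 4 observations at >= 4 distinct ages).
#' @param weights Body weights in g.
#' @return List: `params` ([GrowthParams] or best candidate), `converged`,
#'   `r_squared`, `residual_sd`, `n`, and `reason` when not converged.
#' @export
fit_growth <- function(ages, weights) {
  keep <- is.finite(ages) & is.finite(weights)
  ages <- ages[keep]; weights <- weights[keep]
  if (length(ages) < 4L || length(unique(ages)) < 4L)
    lavrec_error("need >= 4 observations at >= 4 distinct ages",
                 "lavrec_validation_error")
  rng <- diff(range(weights))
  if (rng < 1e-8 * max(abs(weights), 1)) {
    return(list(params = list(A = mean(weights), B = 0, k = NA_real_),
                converged = FALSE, reason = "degenerate: no weight range (B ~ 0)",
                r_squared = NA_real_, residual_sd = NA_real_, n = length(ages)))
  }
  df <- data.frame(t = ages, w = weights)
  wmax <- max(weights)
  starts <- list(
    c(A = wmax * 1.05, B = wmax * 1.05 - min(weights), k = 0.04),
    c(A = wmax * 1.2, B = wmax * 1.2, k = 0.02),
    c(A = wmax * 1.01, B = rng, k = 0.1))
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(w ~ A - B * exp(-k * t), data = df,
                        start = as.list(s),
                        lower = c(A = 1e-6, B = 1e-6, k = 1e-9),
                        control = minpack.lm::nls.lm.control(
                          maxiter = 200, ftol = 1e-12, ptol = 1e-8)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::resid(fit)^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best))
    return(list(params = NULL, converged = FALSE,
                reason = "no start converged", r_squared = NA_real_,
                residual_sd = NA_real_, n = length(ages)))
  cf <- stats::coef(best$fit)
  tss <- sum((weights - mean(weights))^2)
  list(params = GrowthParams(cf[["A"]], cf[["B"]], cf[["k"]]),
       converged = TRUE,
       r_squared = 1 - best$rss / tss,
       residual_sd = sqrt(best$rss / max(1, length(ages) - 3)),
       n = length(ages))
}

#' Metabolic body weight
#'
#' Standard metabolic scaling of the mean on-test body weight.
#'
#' @param bw Body weight.
#' @param exponent Scaling exponent (default 0.75).
#' @export
metabolic_bw <- function(bw, exponent = 0.75) bw^exponent

#' Residual feed intake by sex-specific multiple regression
#'
#' Ordinary least squares of feed intake (FI) on body-weight gain on test
#' (BWG) and metabolic body weight (MBW), plus egg mass (EM) in females; the
#' residual is the RFI. Mean RFI per fitted group is 0 by construction.
#'
#' @param records Data frame with columns `fi`, `bwg`, `mbw` and (females)
#'   `em`.
#' @param sex `"F"` or `"M"` (selects the covariate set: EM only in females).
#' @return List: `records` (input plus `rfi`), `coefficients`, `r_squared`,
#'   `model` (the `lm` fit).
#' @export
compute_rfi <- function(records, sex = c("F", "M")) {
  sex <- match.arg(sex)
  covars <- if (sex == "F") c("bwg", "mbw", "em") else c("bwg", "mbw")
  need <- c("fi", covars)
  if (!all(need %in% names(records)))
    lavrec_error(paste("records need columns", paste(need, collapse = ", ")),
                 "lavrec_validation_error")
  if (nrow(records) < length(covars) + 2L)
    lavrec_error("too few records for the regression", "lavrec_validation_error")
  X <- as.matrix(cbind(1, records[covars]))
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    dropped <- colnames(X)[qr_x$pivot[(qr_x$rank + 1L):ncol(X)]]
    lavrec_error(sprintf("collinear covariate(s): %s",
                         paste(dropped, collapse = ", ")),
                 "lavrec_rank_error")
  }
  fml <- stats::as.formula(paste("fi ~", paste(covars, collapse = " + ")))
  fit <- stats::lm(fml, data = records)
  records$rfi <- stats::resid(fit)
  list(records = records,
       coefficients = stats::coef(fit),
       r_squared = summary(fit)$r.squared,
       model = fit)
}

#' Full-versus-reduced linear model comparison for one trait
#'
#' Fits trait ~ family + sex + genotype (+ covariate) and the reduced model
#' without genotype; reports both R-squared values, their difference, and the
#' nested-model F test for genotype. Significance codes follow the
#' *, **, ***, NS convention at 0.05 / 0.01 / 0.001.
#'
#' @param table Data frame with `family`, `sex`, `genotype` and the trait.
#' @param trait Trait column name.
#' @param factors Factor columns of the full model (genotype must be one).
#' @param covariate Optional numeric covariate column (ANCOVA).
#' @return A `ModelComparison` list: `trait`, `r2_full`, `r2_reduced`,
#'   `delta_r2` (proportions), `f_genotype`, `df`, `p_value`, `signif_code`.
#' @export
compare_models <- function(table, trait,
                           factors = c("family", "sex", "genotype"),
                           covariate = NULL) {
  if (!"genotype" %in% factors)
    lavrec_error("factors must include genotype", "lavrec_validation_error")
  for (f in factors) {
    if (!f %in% names(table))
      lavrec_error(sprintf("missing factor column '%s'", f),
                   "lavrec_validation_error")
    table[[f]] <- factor(table[[f]])
    if (any(table(table[[f]]) == 0L) || nlevels(table[[f]]) < 1L)
      lavrec_error(sprintf("empty level in factor '%s'", f),
                   "lavrec_validation_error")
    table[[f]] <- droplevels(table[[f]])
  }
  rhs_full <- c(factors, covariate)
  rhs_red <- c(setdiff(factors, "genotype"), covariate)
  f_full <- stats::as.formula(paste(trait, "~", paste(rhs_full, collapse = " + ")))
  f_red <- stats::as.formula(paste(trait, "~", paste(rhs_red, collapse = " + ")))
  m_full <- stats::lm(f_full, data = table)
  m_red <- stats::lm(f_red, data = table)
  a <- stats::anova(m_red, m_full)
  p <- a$`Pr(>F)`[2]
  code <- if (is.na(p)) "NS"
          else if (p < 0.001) "***" else if (p < 0.01) "**"
          else if (p < 0.05) "*" else "NS"
  structure(list(trait = trait,
                 r2_full = summary(m_full)$r.squared,
                 r2_reduced = summary(m_red)$r.squared,
                 delta_r2 = summary(m_full)$r.squared - summary(m_red)$r.squared,
                 f_genotype = a$F[2], df = c(a$Df[2], a$Res.Df[2]),
                 p_value = p, signif_code = code),
            class = "ModelComparison")
}

#' @export
print.ModelComparison <- function(x, ...) {
  cat(sprintf("%s: R2 full %.1f%%, reduced %.1f%%, delta %.1f points; F(%d,%d) = %.2f (%s)\n",
              x$trait, 100 * x$r2_full, 100 * x$r2_reduced, 100 * x$delta_r2,
              x$df[1], x$df[2], x$f_genotype, x$signif_code))
  invisible(x)
}
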