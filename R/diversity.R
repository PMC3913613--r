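#' Effective richness (Hill number of order 1)
#'
#' The exponential of Shannon entropy, `exp(-sum p_i log p_i)` with
#' natural logs and zero categories omitted: the number of equally
#' abundant species that would give the observed entropy. Equals the
#' species count for a perfectly even community and 1 for a point mass.
#'
#' @param counts non-negative numeric vector (counts or abundances) with
#'   at least one positive entry.
#' @return `^1D`, a number in \[1, S\].
#' @export
effective_richness <- function(counts) {
  if (any(counts < 0)) stop("counts must be non-negative")
  total <- sum(counts)
  if (total == 0) stop("all-zero count vector")
  p <- counts[counts > 0] / total
  exp(-sum(p * log(p)))
}

#' Per-sample alpha-diversity records
#'
#' @param table a [count_table()] with metadata.
#' @return data.frame: sample, subject, day, observed_richness (features
#'   with nonzero count), effective_richness (`^1D`).
#' @export
diversity_records <- function(table) {
  stopifnot(inherits(table, "count_table"))
  if (is.null(table$metadata)) stop("metadata required")
  data.frame(
    sample = rownames(table$counts),
    subject = table$metadata$subject,
    day = table$metadata$day,
    observed_richness = apply(table$counts, 1, function(x) sum(x > 0)),
    effective_richness = apply(table$counts, 1, effective_richness),
    row.names = NULL)
}

#' Mixed-effects time model for effective richness
#'
#' Fits `log(^1D) ~ day + (1 | subject)` (or `(day | subject)` with
#' `random_slope = TRUE`) by restricted maximum likelihood, modelling a
#' positive right-skewed diversity response on the log scale while letting
#' baseline diversity (and optionally its time trend) vary between
#' subjects. The day effect is tested by a Wald t test with Satterthwaite
#' degrees of freedom. AICs of the two random structures (identical fixed
#' effects, both REML) can be compared to choose between them.
#'
#' @param records data.frame from [diversity_records()] (columns subject,
#'   day, effective_richness).
#' @param random_slope add a per-subject random slope for day.
#' @return An object of class `mixed_fit`: fixed coefficients on the log
#'   scale, variance components, REML criterion, AIC, the day p-value, and
#'   the underlying fit.
#' @export
fit_mixed_model <- function(records, random_slope = FALSE) {
  need <- c("subject", "day", "effective_richness")
  stopifnot(all(need %in% names(records)))
  if (any(records$effective_richness <= 0)) stop("non-positive effective richness")
  if (length(unique(records$subject)) < 2) stop("need >= 2 subjects")
  dat <- data.frame(y = log(records$effective_richness),
                    day = as.numeric(records$day),
                    subject = factor(records$subject))
  form <- if (random_slope) y ~ day + (day | subject) else y ~ day + (1 | subject)
  fit <- lmerTest::lmer(form, data = dat, REML = TRUE)
  vc <- as.data.frame(lme4::VarCorr(fit))
  get_vc <- function(v1, v2 = NA) {
    row <- vc$grp == "subject" &
      (vc$var1 %in% v1 | (is.na(v1) & is.na(vc$var1))) &
      (if (is.na(v2)) is.na(vc$var2) else vc$var2 %in% v2)
    if (any(row)) vc$vcov[row][1] else NA_real_
  }
  if (lme4::isSingular(fit))
    warning("singular fit: a random-effect variance is estimated at zero")
  co <- coef(summary(fit))
  structure(list(
    fixed = c(intercept = unname(co["(Intercept)", "Estimate"]),
              day = unname(co["day", "Estimate"])),
    se = c(intercept = unname(co["(Intercept)", "Std. Error"]),
           day = unname(co["day", "Std. Error"])),
    var_intercept = get_vc("(Intercept)"),
    var_slope = if (random_slope) get_vc("day") else NA_real_,
    cov_intercept_slope = if (random_slope) get_vc("(Intercept)", "day") else NA_real_,
    var_residual = vc$vcov[vc$grp == "Residual"][1],
    reml_criterion = as.numeric(lme4::REMLcrit(fit)),
    aic = AIC(fit),
    p_day = unname(co["day", "Pr(>|t|)"]),
    random_slope = random_slope,
    response = "log(effective richness); Gaussian working model for a log-link gamma response",
    model = fit), class = "mixed_fit")
}

#' @export
print.mixed_fit <- function(x, ...) {
  cat("Mixed model of log(effective richness) on day",
      if (x$random_slope) "(random intercept + slope)" else "(random intercept)", "\n")
  cat(sprintf("  intercept %.4f  day %.5f (p = %.4g)\n",
              x$fixed["intercept"], x$fixed["day"], x$p_day))
  cat(sprintf("  var(subject) %.4g  var(resid) %.4g  AIC %.2f\n",
              x$var_intercept, x$var_residual, x$aic))
  invisible(x)
}
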