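#' Fit an intake array
#'
#' An intake array is the line (or curve) connecting the mean cumulative
#' intake points of groups each confined to one nutritionally imbalanced
#' diet. Its fitted slope in (AA, C) intake space is the classical diagnostic
#' for the global rule of compromise: a slope of -1 indicates the
#' equal-distance rule (deficits in one nutrient balance surpluses in the
#' other), a slope of 0 indicates pure carbohydrate regulation
#' (no-interaction rule prioritising carbohydrate), and a vertical array
#' indicates pure amino-acid regulation.
#'
#' The fit is ordinary least squares of mean carbohydrate intake (response)
#' on mean amino-acid intake (explanatory), one point per diet, with the
#' slope standard error computed from the residual variance on `n - 2`
#' degrees of freedom. A per-cage variant (`use = "cages"`) fits all cage
#' points instead of the per-diet means.
#'
#' @param intake Either a per-cage intake data frame from [compute_intake()]
#'   (columns `diet_id`, `aa_mmol_per_bee`, `c_mmol_per_bee`), or a per-diet
#'   summary from [intake_means()] (columns `mean_aa_mmol`, `mean_c_mmol`),
#'   or a plain data frame with columns `aa` and `c` of per-diet means.
#' @param panel Optional `diet_panel` fixing diet order (required for
#'   per-cage input).
#' @param use `"means"` (default: fit the per-diet means, one point per diet)
#'   or `"cages"` (fit every cage's point).
#' @return An object of class `intake_array`: list with `points` (the
#'   per-diet means +/- SE), `fit` (the underlying `lm`), `coefficients`
#'   (intercept, slope), `slope`, `slope_se`, `intercept`, `n_diets`, `use`.
#' @examples
#' pts <- data.frame(aa = c(0, 1, 2), c = c(1, 3, 2))
#' arr <- fit_intake_array(pts)
#' coef(arr)          # intercept 1.5, slope 0.5
#' slope_test(arr, beta_h = c(-1, 0))
#' @export
fit_intake_array <- function(intake, panel = NULL, use = c("means", "cages")) {
  use <- match.arg(use)
  per_cage <- NULL

  if (all(c("aa_mmol_per_bee", "c_mmol_per_bee", "diet_id") %in% names(intake))) {
    if (is.null(panel))
      stop("per-cage intake input needs the diet panel for ordering",
           call. = FALSE)
    per_cage <- intake
    means <- intake_means(intake, panel)
  } else if (all(c("mean_aa_mmol", "mean_c_mmol") %in% names(intake))) {
    means <- intake
  } else if (all(c("aa", "c") %in% names(intake))) {
    means <- data.frame(
      diet_id = if ("diet_id" %in% names(intake)) intake$diet_id
                else as.character(seq_len(nrow(intake))),
      mean_aa_mmol = intake$aa, se_aa = NA_real_,
      mean_c_mmol = intake$c, se_c = NA_real_)
  } else {
    stop("unrecognised intake input; see ?fit_intake_array", call. = FALSE)
  }

  ok <- is.finite(means$mean_aa_mmol) & is.finite(means$mean_c_mmol)
  means <- means[ok, , drop = FALSE]
  n_diets <- nrow(means)
  if (n_diets < 3)
    stop("slope fitting needs >= 3 diets with finite mean intakes",
         call. = FALSE)

  if (use == "cages") {
    if (is.null(per_cage))
      stop("use = 'cages' requires per-cage intake input", call. = FALSE)
    dat <- data.frame(aa = per_cage$aa_mmol_per_bee,
                      c = per_cage$c_mmol_per_bee)
  } else {
    dat <- data.frame(aa = means$mean_aa_mmol, c = means$mean_c_mmol)
  }
  if (diff(range(dat$aa)) == 0)
    stop("undefined slope: all amino-acid means are identical (vertical array)",
         call. = FALSE)

  fit <- stats::lm(c ~ aa, data = dat)
  cf <- stats::coef(fit)
  # exact (noiseless) fits are legitimate here: SE 0 is handled downstream
  sm <- withCallingHandlers(
    summary(fit)$coefficients,
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  slope_se <- if (nrow(sm) >= 2) sm["aa", "Std. Error"] else NA_real_

  structure(list(
    points = means,
    fit = fit,
    coefficients = c(intercept = unname(cf[1L]), slope = unname(cf[2L])),
    slope = unname(cf[2L]),
    intercept = unname(cf[1L]),
    slope_se = unname(slope_se),
    n_diets = n_diets,
    n_points = nrow(dat),
    use = use,
    call = match.call()
  ), class = "intake_array")
}

#' @export
print.intake_array <- function(x, digits = 4, ...) {
  cat("Intake array (", x$n_diets, " diets",
      if (x$use == "cages") paste0(", ", x$n_points, " cages"), ")\n", sep = "")
  cat(sprintf("  slope: %s (SE %s), intercept: %s mmol\n",
              format(x$slope, digits = digits),
              format(x$slope_se, digits = digits),
              format(x$intercept, digits = digits)))
  invisible(x)
}

#' @export
coef.intake_array <- function(object, ...) object$coefficients

#' @export
residuals.intake_array <- function(object, ...) stats::residuals(object$fit)

#' @export
fitted.intake_array <- function(object, ...) stats::fitted(object$fit)

#' @param newdata Optional numeric vector of amino-acid intakes (mmol) at
#'   which to predict mean carbohydrate intake; defaults to the fitted points.
#' @rdname fit_intake_array
#' @export
predict.intake_array <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(stats::fitted(object$fit))
  stats::predict(object$fit, newdata = data.frame(aa = newdata), ...)
}

#' @export
summary.intake_array <- function(object, beta_h = c(-1, 0), ...) {
  structure(list(array = object,
                 tests = slope_test(object, beta_h = beta_h)),
            class = "summary.intake_array")
}

#' @export
print.summary.intake_array <- function(x, ...) {
  print(x$array)
  cat("\nPer-diet mean intakes (mmol per individual):\n")
  print(x$array$points, row.names = FALSE, digits = 4)
  cat("\nSlope tests against hypothetical rules of compromise:\n")
  print(x$tests, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @param x An `intake_array`.
#' @param se Draw +/- 1 SE error bars on the per-diet means.
#' @param ... Further arguments passed to [graphics::plot()].
#' @rdname fit_intake_array
#' @export
plot.intake_array <- function(x, se = TRUE, ...) {
  p <- x$points
  graphics::plot(p$mean_aa_mmol, p$mean_c_mmol,
                 xlab = "AA intake (mmol per individual)",
                 ylab = "Carbohydrate intake (mmol per individual)",
                 pch = 19, ...)
  if (se && any(is.finite(p$se_aa))) {
    graphics::arrows(p$mean_aa_mmol, p$mean_c_mmol - p$se_c,
                     p$mean_aa_mmol, p$mean_c_mmol + p$se_c,
                     angle = 90, code = 3, length = 0.03)
    graphics::arrows(p$mean_aa_mmol - p$se_aa, p$mean_c_mmol,
                     p$mean_aa_mmol + p$se_aa, p$mean_c_mmol,
                     angle = 90, code = 3, length = 0.03)
  }
  graphics::lines(p$mean_aa_mmol, p$mean_c_mmol, lty = 3)
  graphics::abline(x$intercept, x$slope, col = "grey40")
  invisible(x)
}

#' Test an intake-array slope against a hypothetical rule slope
#'
#' Compares the fitted array slope `beta_a` with a hypothetical slope
#' `beta_h` using `t = (beta_a - beta_h) / SE(beta_a)`, referred to a
#' t distribution with `n - 2` degrees of freedom (`n` = number of diet
#' means). `beta_h = -1` is the equal-distance diagnostic, `beta_h = 0` the
#' carbohydrate-prioritising no-interaction diagnostic. P-values are
#' two-tailed.
#'
#' When the fit is exact (`SE = 0`), the test degenerates: `p` is reported
#' as 0 with an `exact_fit` flag if the slopes differ, and as 1 if they
#' agree.
#'
#' @param array An [fit_intake_array()] object, or a fitted slope (numeric)
#'   when calling the low-level form with `se` and `n_diets` supplied.
#' @param beta_h Hypothetical slope(s) to test against.
#' @param se Slope standard error (low-level form only).
#' @param n_diets Number of diet means behind the slope (low-level form
#'   only).
#' @return Data frame of class `slope_test`: `beta_h`, `slope`, `se`,
#'   `t_stat`, `df`, `p_two_tailed`, `exact_fit`.
#' @examples
#' slope_test(-0.127, beta_h = 0, se = 1.05, n_diets = 7)  # t = -0.121
#' @export
slope_test <- function(array, beta_h = c(-1, 0), se = NULL, n_diets = NULL) {
  if (inherits(array, "intake_array")) {
    beta_a <- array$slope
    se <- array$slope_se
    n_diets <- array$n_diets
  } else {
    beta_a <- array
    if (is.null(se) || is.null(n_diets))
      stop("low-level slope_test needs 'se' and 'n_diets'", call. = FALSE)
  }
  if (n_diets < 3) stop("slope test needs >= 3 diets", call. = FALSE)
  df <- n_diets - 2L

  one <- function(bh) {
    if (se == 0) {
      if (beta_a == bh)
        return(data.frame(beta_h = bh, slope = beta_a, se = se, t_stat = 0,
                          df = df, p_two_tailed = 1, exact_fit = TRUE))
      return(data.frame(beta_h = bh, slope = beta_a, se = se,
                        t_stat = sign(beta_a - bh) * Inf, df = df,
                        p_two_tailed = 0, exact_fit = TRUE))
    }
    t <- (beta_a - bh) / se
    data.frame(beta_h = bh, slope = beta_a, se = se, t_stat = t, df = df,
               p_two_tailed = 2 * stats::pt(-abs(t), df = df),
               exact_fit = FALSE)
  }
  out <- do.call(rbind, lapply(beta_h, one))
  rownames(out) <- NULL
  class(out) <- c("slope_test", "data.frame")
  out
}
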