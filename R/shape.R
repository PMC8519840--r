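#' Smooth an intake array as a function-valued trait
#'
#' Fits a cubic smoothing spline to per-diet mean carbohydrate intake as a
#' function of diet amino-acid molarity, the first step in characterising
#' the non-linear shape of an intake array (peak, height, tolerance,
#' strength). Smoothing is chosen by generalised cross-validation unless a
#' `lambda` or `spar` is supplied; `lambda` near zero gives the
#' interpolating limit.
#'
#' @param x Per-diet amino-acid molarities (mol/L), at least 4 distinct
#'   values; duplicates are an error.
#' @param y Per-diet mean cumulative carbohydrate intakes (mmol per
#'   individual).
#' @param lambda,spar Optional smoothing parameters passed to
#'   [stats::smooth.spline()]; if both `NULL`, GCV chooses.
#' @return An object of class `intake_smooth`: list with `fun` (vectorised
#'   evaluator), `domain` (range of `x`), and `spline` (the underlying
#'   `smooth.spline` fit).
#' @examples
#' f <- fit_smooth(seq(0, 0.05, length.out = 7),
#'                 3 - 100 * (seq(0, 0.05, length.out = 7) - 0.02)^2)
#' f$fun(0.02)
#' @export
fit_smooth <- function(x, y, lambda = NULL, spar = NULL) {
  if (anyDuplicated(x))
    stop("duplicated x values: one mean response per diet molarity",
         call. = FALSE)
  if (length(unique(x)) < 4)
    stop("insufficient data: smoothing needs >= 4 distinct x values",
         call. = FALSE)
  if (length(x) != length(y)) stop("x and y lengths differ", call. = FALSE)

  args <- list(x = x, y = y, all.knots = TRUE, keep.data = FALSE)
  if (!is.null(lambda)) args$lambda <- lambda
  else if (!is.null(spar)) args$spar <- spar
  else args$cv <- FALSE  # GCV
  sp <- do.call(stats::smooth.spline, args)

  structure(list(
    fun = function(z) stats::predict(sp, z)$y,
    domain = range(x),
    spline = sp
  ), class = "intake_smooth")
}

#' @export
print.intake_smooth <- function(x, ...) {
  cat(sprintf("Smoothed intake array on [%.4g, %.4g] (lambda %.3g, %d points)\n",
              x$domain[1L], x$domain[2L], x$spline$lambda,
              length(x$spline$x)))
  invisible(x)
}

# Accept an intake_smooth or a bare function + domain.
as_shape_fun <- function(f, domain) {
  if (inherits(f, "intake_smooth")) return(list(fun = f$fun, domain = f$domain))
  if (is.function(f)) {
    if (is.null(domain) || length(domain) != 2 || domain[2L] <= domain[1L])
      stop("a bare function needs a domain c(lo, hi)", call. = FALSE)
    return(list(fun = f, domain = as.numeric(domain)))
  }
  stop("'f' must be an intake_smooth or a function", call. = FALSE)
}

#' Peak and height of a smoothed response
#'
#' Locates the maximum of a smoothed response over its domain: a 1000-point
#' dense grid scan refined by [stats::optimize()] around the best grid
#' point. Boundary maxima are allowed and flagged; a flat (constant)
#' function resolves to the leftmost x by the documented tie-break.
#'
#' @param f An `intake_smooth` or a bare function.
#' @param domain Domain `c(lo, hi)` (required for a bare function).
#' @param n_grid Dense-grid size.
#' @return List with `peak_x`, `height`, and `boundary` (`TRUE` when the
#'   maximum sits at a domain end).
#' @export
peak_and_height <- function(f, domain = NULL, n_grid = 1000) {
  fd <- as_shape_fun(f, domain)
  xs <- seq(fd$domain[1L], fd$domain[2L], length.out = n_grid)
  ys <- fd$fun(xs)
  i <- which.max(ys)
  if (i > 1 && i < n_grid) {
    opt <- stats::optimize(fd$fun, lower = xs[i - 1L], upper = xs[i + 1L],
                           maximum = TRUE, tol = 1e-10)
    # keep the grid point when refinement does not improve (flat regions)
    if (opt$objective >= ys[i]) {
      peak_x <- opt$maximum
      height <- opt$objective
    } else {
      peak_x <- xs[i]
      height <- ys[i]
    }
    boundary <- FALSE
  } else {
    peak_x <- xs[i]
    height <- ys[i]
    boundary <- TRUE
  }
  list(peak_x = peak_x, height = height, boundary = boundary)
}

#' Tolerance: width of the response at a relative elevation
#'
#' The width of the x-interval around the peak over which the response stays
#' above `height * (1 - drop_fraction)` — the connected component of the
#' super-level set containing the peak. Crossings are located by
#' [stats::uniroot()] between bracketing grid points; components truncated
#' by a domain end are flagged.
#'
#' @param f An `intake_smooth` or a bare function.
#' @param peak_x,height Peak location and height from [peak_and_height()].
#' @param drop_fraction Relative drop defining the elevation, in (0, 1);
#'   default 1/3.
#' @param domain Domain for a bare function.
#' @param n_grid Dense-grid size used to bracket crossings.
#' @return List with `width`, `lower`, `upper`, `truncated` (`TRUE` when the
#'   component touches a domain end).
#' @export
tolerance <- function(f, peak_x, height, drop_fraction = 1/3, domain = NULL,
                      n_grid = 1000) {
  if (drop_fraction <= 0 || drop_fraction >= 1)
    stop("drop_fraction must be in (0, 1)", call. = FALSE)
  fd <- as_shape_fun(f, domain)
  thr <- height * (1 - drop_fraction)
  g <- function(x) fd$fun(x) - thr
  xs <- seq(fd$domain[1L], fd$domain[2L], length.out = n_grid)
  above <- g(xs) >= 0
  ip <- max(1L, min(n_grid, findInterval(peak_x, xs)))
  if (!above[ip]) ip <- which.min(abs(xs - peak_x))

  truncated <- FALSE
  # walk left from the peak to the last grid point still above threshold
  lo_i <- ip
  while (lo_i > 1L && above[lo_i - 1L]) lo_i <- lo_i - 1L
  if (lo_i == 1L) {
    lower <- xs[1L]
    truncated <- TRUE
  } else {
    lower <- stats::uniroot(g, lower = xs[lo_i - 1L], upper = xs[lo_i],
                            tol = 1e-12)$root
  }
  hi_i <- ip
  while (hi_i < n_grid && above[hi_i + 1L]) hi_i <- hi_i + 1L
  if (hi_i == n_grid) {
    upper <- xs[n_grid]
    truncated <- TRUE
  } else {
    upper <- stats::uniroot(g, lower = xs[hi_i], upper = xs[hi_i + 1L],
                            tol = 1e-12)$root
  }
  list(width = upper - lower, lower = lower, upper = upper,
       truncated = truncated)
}

#' Strength: degree of fall-off from the peak
#'
#' One minus the ratio of the domain-average response (trapezoid rule on a
#' dense grid) to the peak height. A flat response has strength 0; a needle
#' peak over a near-zero baseline approaches 1. Scale-invariant in y.
#'
#' @param f An `intake_smooth` or a bare function.
#' @param height Peak height (> 0).
#' @param domain Domain for a bare function.
#' @param n_grid Dense-grid size for the trapezoid mean.
#' @return Strength in \[0, 1\].
#' @export
strength <- function(f, height, domain = NULL, n_grid = 1000) {
  if (!is.finite(height) || height <= 0)
    stop("undefined strength: peak height must be > 0", call. = FALSE)
  fd <- as_shape_fun(f, domain)
  xs <- seq(fd$domain[1L], fd$domain[2L], length.out = n_grid)
  ys <- fd$fun(xs)
  h <- diff(fd$domain) / (n_grid - 1)
  mean_y <- (sum(ys) - (ys[1L] + ys[n_grid]) / 2) * h / diff(fd$domain)
  1 - mean_y / height
}

#' Characterise intake-array shape: peak, height, tolerance, strength
#'
#' Summarises the non-linear shape of an intake array as a function-valued
#' trait: carbohydrate intake as a smooth function of diet amino-acid
#' molarity, reduced to (a) the x of maximal response (peak), (b) the
#' response there (height), (c) the width of the function at an elevation
#' `1 - drop_fraction` relative to the peak (tolerance), and (d) the degree
#' to which the response falls away from the peak (strength).
#'
#' By default x is the diet's amino-acid molarity (mol/L). Setting
#' `axis = "aa_intake"` instead uses the observed mean amino-acid intake
#' (mmol) as the x axis, for comparison with conventions that express the
#' peak in consumed amino acid.
#'
#' @param means Per-diet summary from [intake_means()] (or a data frame with
#'   `diet_id` and `mean_c_mmol`, plus `mean_aa_mmol` if `axis =
#'   "aa_intake"`).
#' @param panel The `diet_panel` (source of per-diet molarities).
#' @param drop_fraction Relative drop defining tolerance; default 1/3.
#' @param axis `"molarity"` (default) or `"aa_intake"`.
#' @param lambda,spar Optional smoothing overrides, see [fit_smooth()].
#' @param n_grid Dense-grid size for the searches.
#' @return An object of class `shape_summary`: `peak_x`, `height`,
#'   `tolerance`, `strength`, `drop_fraction`, `axis`, flags
#'   (`peak_at_boundary`, `tolerance_truncated`), and the `smooth` fit.
#' @examples
#' sim <- simulate_trial(sim_config(n_cages_per_diet = 3, seed = 1))
#' intake <- compute_intake(sim$feeding_records, sim$controls, sim$panel)
#' array_shape(intake_means(intake, sim$panel), sim$panel)
#' @export
array_shape <- function(means, panel, drop_fraction = 1/3,
                        axis = c("molarity", "aa_intake"),
                        lambda = NULL, spar = NULL, n_grid = 1000) {
  axis <- match.arg(axis)
  stopifnot(inherits(panel, "diet_panel"),
            all(c("diet_id", "mean_c_mmol") %in% names(means)))
  x <- if (axis == "molarity") {
    vapply(means$diet_id, function(id) panel[[id]]$aa_total_molarity,
           numeric(1))
  } else {
    means$mean_aa_mmol
  }
  ord <- order(x)
  sm <- fit_smooth(x[ord], means$mean_c_mmol[ord], lambda = lambda,
                   spar = spar)
  pk <- peak_and_height(sm, n_grid = n_grid)
  tol <- tolerance(sm, pk$peak_x, pk$height, drop_fraction = drop_fraction,
                   n_grid = n_grid)
  stg <- strength(sm, pk$height, n_grid = n_grid)
  structure(list(
    peak_x = pk$peak_x, height = pk$height, tolerance = tol$width,
    strength = stg, drop_fraction = drop_fraction, axis = axis,
    peak_at_boundary = pk$boundary, tolerance_truncated = tol$truncated,
    smooth = sm
  ), class = "shape_summary")
}

#' @export
print.shape_summary <- function(x, ...) {
  unit <- if (x$axis == "molarity") "mol/L" else "mmol AA"
  cat("Intake-array shape summary\n")
  cat(sprintf("  peak:      %.4g %s%s\n", x$peak_x, unit,
              if (x$peak_at_boundary) " (at domain boundary)" else ""))
  cat(sprintf("  height:    %.4g mmol C\n", x$height))
  cat(sprintf("  tolerance: %.4g %s at drop %.3g%s\n", x$tolerance, unit,
              x$drop_fraction,
              if (x$tolerance_truncated) " (truncated at domain end)" else ""))
  cat(sprintf("  strength:  %.4g\n", x$strength))
  invisible(x)
}
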