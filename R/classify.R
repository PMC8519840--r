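#' Classify the rule of compromise behind an observed intake array
#'
#' Operationalises the visual comparison of an observed intake array with the
#' arrays predicted by each rule of compromise. For every candidate rule, the
#' intake target is estimated by minimising the sum of squared Euclidean
#' distances (SSE, mmol^2) between the observed per-diet mean intakes and the
#' rule's projected points on the corresponding rails — a coarse log-spaced
#' grid search followed by local refinement with [stats::optim()]. Rules are
#' then ranked by their minimised SSE.
#'
#' Rails on which a rule is undefined (regulating amino acids on a
#' sucrose-only rail) are excluded from that rule's SSE, with a note. SSE
#' ties are broken by a fixed, documented preference order:
#' `equal_distance`, `closest_distance`, `no_interaction_c`,
#' `no_interaction_aa`.
#'
#' All geometry is computed in cumulative mmol-per-individual space without
#' axis rescaling. The equal-distance rule is unit-dependent; an optional
#' per-axis scaling (`scale = c(aa, c)` divides each axis before projection)
#' is available but off by default.
#'
#' @param observed An [fit_intake_array()] object, or a data frame of
#'   per-diet means (`diet_id`, `mean_aa_mmol`, `mean_c_mmol`).
#' @param panel The `diet_panel` whose rails the observations sit on.
#' @param rules Candidate rules; default all of [compromise_rules()].
#' @param grid_n Points per axis of the log-spaced target search grid.
#' @param grid_span Multiplicative span of the grid relative to the range of
#'   positive observed intakes on each axis (default 0.25x to 4x).
#' @param refine Run Nelder-Mead refinement from the best grid point.
#' @param scale Optional positive length-2 vector of per-axis divisors
#'   applied before projection (`NULL`: no scaling).
#' @return An object of class `rule_fit`: list with `ranking` (data frame
#'   `rule`, `sse`, `target_aa`, `target_c`, `n_rails_used`, `rank`),
#'   `predicted` (per-rule data frames of projected points), `observed`,
#'   and `best_rule`.
#' @examples
#' panel <- build_diet_panel()
#' truth <- predict_rule_points("equal_distance", c(aa = 1, c = 4), panel)
#' obs <- data.frame(diet_id = truth$diet_id, mean_aa_mmol = truth$aa_mmol,
#'                   mean_c_mmol = truth$c_mmol)
#' fit <- classify_rule(obs, panel, grid_n = 40)
#' fit$best_rule  # "equal_distance", SSE ~ 0
#' @export
classify_rule <- function(observed, panel, rules = compromise_rules(),
                          grid_n = 200, grid_span = c(0.25, 4),
                          refine = TRUE, scale = NULL) {
  if (inherits(observed, "intake_array")) observed <- observed$points
  stopifnot(all(c("diet_id", "mean_aa_mmol", "mean_c_mmol") %in% names(observed)))
  if (!inherits(panel, "diet_panel")) stop("'panel' must be a diet_panel",
                                           call. = FALSE)
  rules <- match.arg(rules, compromise_rules(), several.ok = TRUE)
  if (grid_n < 2 || any(grid_span <= 0) || grid_span[2L] <= grid_span[1L])
    stop("invalid target search grid configuration", call. = FALSE)
  if (nrow(observed) < 3)
    stop("rule classification needs >= 3 diets", call. = FALSE)

  rails <- rails_from_panel(panel)[observed$diet_id]
  if (anyNA(names(rails)))
    stop("observed diets absent from panel", call. = FALSE)
  U <- t(vapply(rails, `[[`, numeric(2), "direction"))
  if (anyDuplicated(round(U / sqrt(rowSums(U^2)), 12)))
    stop("duplicated rail directions: diets must have distinct AA:C ratios",
         call. = FALSE)
  M <- cbind(observed$mean_aa_mmol, observed$mean_c_mmol)
  if (is.null(scale)) scale <- c(1, 1)
  if (length(scale) != 2 || any(scale <= 0))
    stop("'scale' must be two positive divisors", call. = FALSE)
  Us <- sweep(U, 2, scale, "/")
  Ms <- sweep(M, 2, scale, "/")

  # Each rule's projection scalar is linear in the target: s = a*T_aa + b*T_c.
  rule_coefs <- function(rule) {
    a <- b <- numeric(nrow(Us))
    valid <- rep(TRUE, nrow(Us))
    for (i in seq_len(nrow(Us))) {
      u <- Us[i, ]
      co <- switch(rule,
        no_interaction_aa = if (u[1L] > 0) c(1 / u[1L], 0) else NA,
        no_interaction_c = if (u[2L] > 0) c(0, 1 / u[2L]) else NA,
        equal_distance = c(1, 1) / sum(u),
        closest_distance = u / sum(u^2))
      if (anyNA(co)) valid[i] <- FALSE else { a[i] <- co[1L]; b[i] <- co[2L] }
    }
    list(a = a, b = b, valid = valid)
  }

  # grid of candidate targets (original units), log-spaced per axis
  grid_axis <- function(v) {
    pos <- v[v > 0]
    if (!length(pos))
      stop("cannot build target grid: no positive observed intakes on an axis",
           call. = FALSE)
    exp(seq(log(grid_span[1L] * min(pos)), log(grid_span[2L] * max(pos)),
            length.out = grid_n))
  }
  A <- grid_axis(M[, 1L])
  C <- grid_axis(M[, 2L])
  As <- A / scale[1L]
  Cs <- C / scale[2L]

  fit_one <- function(rule) {
    co <- rule_coefs(rule)
    if (!all(co$valid))
      message("rule '", rule, "' undefined on rail(s) ",
              paste(observed$diet_id[!co$valid], collapse = ", "),
              "; excluded from its SSE")
    idx <- which(co$valid)
    if (length(idx) < 2)
      return(list(sse = Inf, target = c(NA_real_, NA_real_),
                  n_rails = length(idx)))

    sse_grid <- matrix(0, grid_n, grid_n)
    for (i in idx) {
      S <- outer(co$a[i] * As, co$b[i] * Cs, "+")
      sse_grid <- sse_grid + (S * Us[i, 1L] - Ms[i, 1L])^2 +
                             (S * Us[i, 2L] - Ms[i, 2L])^2
    }
    best <- arrayInd(which.min(sse_grid), dim(sse_grid))
    target <- c(A[best[1L]], C[best[2L]])

    sse_fun <- function(logT) {
      Tt <- exp(logT) / scale
      s <- co$a[idx] * Tt[1L] + co$b[idx] * Tt[2L]
      sum((s * Us[idx, 1L] - Ms[idx, 1L])^2 +
          (s * Us[idx, 2L] - Ms[idx, 2L])^2)
    }
    if (refine) {
      opt <- stats::optim(log(target), sse_fun, method = "Nelder-Mead",
                          control = list(reltol = 1e-12, maxit = 500))
      target <- exp(opt$par)
      sse <- opt$value
    } else {
      sse <- sse_fun(log(target))
    }
    list(sse = sse, target = target, n_rails = length(idx))
  }

  fits <- lapply(rules, fit_one)
  ranking <- data.frame(
    rule = rules,
    sse = vapply(fits, `[[`, numeric(1), "sse"),
    target_aa = vapply(fits, function(f) f$target[1L], numeric(1)),
    target_c = vapply(fits, function(f) f$target[2L], numeric(1)),
    n_rails_used = vapply(fits, `[[`, numeric(1), "n_rails"),
    row.names = NULL)
  tie_pref <- match(ranking$rule, c("equal_distance", "closest_distance",
                                    "no_interaction_c", "no_interaction_aa"))
  ord <- order(ranking$sse, tie_pref)
  ranking <- ranking[ord, , drop = FALSE]
  ranking$rank <- seq_len(nrow(ranking))
  rownames(ranking) <- NULL

  predicted <- lapply(stats::setNames(rules, rules), function(rule) {
    i <- which(ranking$rule == rule)
    tg <- c(aa = ranking$target_aa[i], c = ranking$target_c[i])
    if (anyNA(tg)) return(NULL)
    predict_rule_points(rule, tg, rails)
  })

  structure(list(ranking = ranking, predicted = predicted,
                 observed = observed, best_rule = ranking$rule[1L],
                 scale = scale),
            class = "rule_fit")
}

#' @export
print.rule_fit <- function(x, ...) {
  cat("Rule-of-compromise classification (best: ", x$best_rule, ")\n",
      sep = "")
  print(x$ranking, row.names = FALSE, digits = 4)
  invisible(x)
}
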