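#' Nutrient rails
#'
#' In the geometric framework of nutrition, any intake of one fixed-
#' composition diet lies on a "nutrient rail": the line through the origin of
#' (AA, C) intake space with direction proportional to the diet's nutrient
#' concentrations. A rail's direction is taken directly as
#' `(aa_total_molarity, sucrose_molarity)`, so a consumed volume `v` (ml)
#' sits at `v * direction` (mmol).
#'
#' @param diet A [diet()].
#' @return An object of class `rail`: list with `diet_id` and `direction`
#'   (named numeric `c(aa, c)`).
#' @examples
#' rail_from_diet(diet(1, 10))   # direction (0.05, 0.5): C = 10 x AA
#' @export
rail_from_diet <- function(diet) {
  stopifnot(inherits(diet, "diet"))
  u <- c(aa = diet$aa_total_molarity, c = diet$sucrose_molarity)
  if (all(u == 0))
    stop("degenerate diet: zero amino acid and zero sucrose", call. = FALSE)
  structure(list(diet_id = diet$id, direction = u), class = "rail")
}

#' @export
print.rail <- function(x, ...) {
  cat(sprintf("Rail %s: direction (aa = %.4g, c = %.4g)\n",
              x$diet_id, x$direction["aa"], x$direction["c"]))
  invisible(x)
}

rails_from_panel <- function(panel) {
  stopifnot(inherits(panel, "diet_panel"))
  lapply(panel, rail_from_diet)
}

check_target <- function(target) {
  target <- c(aa = unname(target[["aa"]] %||% target[[1L]]),
              c = unname(target[["c"]] %||% target[[2L]]))
  if (anyNA(target) || any(target <= 0))
    stop("intake target coordinates must be positive", call. = FALSE)
  target
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Rule-of-compromise projections of an intake target onto a rail
#'
#' An animal confined to one imbalanced rail cannot reach its intake target
#' `T`; each "rule of compromise" picks a different feeding point on the rail:
#'
#' * **no-interaction** (`project_no_interaction()`): the animal regulates one
#'   nutrient only, eating until that coordinate matches the target
#'   (`s = T_reg / u_reg`); undefined when the rail carries none of the
#'   regulated nutrient (returned as `NA`, not an error).
#' * **equal-distance** (`project_equal_distance()`): the deficit in one
#'   nutrient exactly balances the surplus in the other
#'   (`s = (T_aa + T_c) / (u_aa + u_c)`); the point lies on the slope -1 line
#'   through `T`. This rule is unit-dependent: it trades millimoles of one
#'   nutrient one-for-one against the other.
#' * **closest-distance** (`project_closest()`): the orthogonal projection
#'   `s = (T . u) / (u . u)`, the rail point of minimum Euclidean distance to
#'   the target.
#'
#' All three return a point `s * u` on the rail (collinearity to within
#' machine precision).
#'
#' @param target Intake target, named numeric `c(aa = , c = )`, both > 0
#'   (mmol per individual).
#' @param rail A [rail_from_diet()] rail.
#' @param regulated For the no-interaction rule: which nutrient is regulated,
#'   `"aa"` or `"c"`.
#' @return Named numeric `c(aa = , c = )`: the predicted intake point, or
#'   `c(NA, NA)` when the no-interaction projection is undefined.
#' @examples
#' r <- structure(list(diet_id = "demo", direction = c(aa = 1, c = 2)),
#'                class = "rail")
#' project_no_interaction(c(aa = 2, c = 2), r, "c")  # (1, 2)
#' project_equal_distance(c(aa = 2, c = 2), r)       # (4/3, 8/3)
#' project_closest(c(aa = 2, c = 2), r)              # (1.2, 2.4)
#' @name rule_projections
NULL

#' @rdname rule_projections
#' @export
project_no_interaction <- function(target, rail, regulated = c("c", "aa")) {
  regulated <- match.arg(regulated)
  target <- check_target(target)
  u <- rail$direction
  if (u[[regulated]] == 0) return(c(aa = NA_real_, c = NA_real_))
  s <- target[[regulated]] / u[[regulated]]
  s * u
}

#' @rdname rule_projections
#' @export
project_equal_distance <- function(target, rail) {
  target <- check_target(target)
  u <- rail$direction
  if (sum(u) <= 0) stop("degenerate rail", call. = FALSE)
  s <- (target[["aa"]] + target[["c"]]) / (u[["aa"]] + u[["c"]])
  s * u
}

#' @rdname rule_projections
#' @export
project_closest <- function(target, rail) {
  target <- check_target(target)
  u <- rail$direction
  uu <- sum(u * u)
  if (uu <= 0) stop("degenerate rail", call. = FALSE)
  s <- sum(target * u) / uu
  s * u
}

#' The rules of compromise recognised by the package
#' @return Character vector of rule labels.
#' @export
compromise_rules <- function() {
  c("no_interaction_aa", "no_interaction_c", "equal_distance",
    "closest_distance")
}

# Dispatch a rule label to its projection. Returns c(NA, NA) where undefined.
project_rule <- function(rule, target, rail) {
  switch(rule,
    no_interaction_aa = project_no_interaction(target, rail, "aa"),
    no_interaction_c = project_no_interaction(target, rail, "c"),
    equal_distance = project_equal_distance(target, rail),
    closest_distance = project_closest(target, rail),
    stop("unknown rule '", rule, "'", call. = FALSE))
}

#' Predicted intake points of a rule across a diet panel
#'
#' Projects one intake target onto every rail of a panel under a given rule.
#' Rails where the rule is undefined (regulating amino acids on a sucrose-only
#' rail) yield `NA` rows.
#'
#' @param rule One of [compromise_rules()].
#' @param target Intake target `c(aa = , c = )`, mmol per individual.
#' @param rails List of rails (or a `diet_panel`, converted internally).
#' @return Data frame: `diet_id`, `aa_mmol`, `c_mmol`.
#' @export
predict_rule_points <- function(rule, target, rails) {
  if (inherits(rails, "diet_panel")) rails <- rails_from_panel(rails)
  pts <- t(vapply(rails, function(r) project_rule(rule, target, r),
                  numeric(2)))
  data.frame(diet_id = vapply(rails, `[[`, character(1), "diet_id"),
             aa_mmol = pts[, 1L], c_mmol = pts[, 2L], row.names = NULL)
}
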