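#' Mean daily evaporative loss per diet
#'
#' Feeding tubes lose mass passively; bee-free control cages holding the same
#' diet measure that loss. Daily consumption is corrected by subtracting the
#' arithmetic mean of a diet's control losses (one control series per diet,
#' typically one value per trial day).
#'
#' @param controls Data frame with columns `diet_id`, `day`, `mass_loss_g`.
#'   Individual losses may be negative (weighing noise).
#' @param diet_id Diet label to average over; if `NULL`, a named vector of
#'   means for every diet present is returned.
#' @return Mean mass loss in grams/day.
#' @export
evaporation_mean <- function(controls, diet_id = NULL) {
  stopifnot(all(c("diet_id", "mass_loss_g") %in% names(controls)))
  if (is.null(diet_id)) {
    means <- tapply(controls$mass_loss_g, controls$diet_id, mean)
    return(stats::setNames(as.numeric(means), names(means)))
  }
  loss <- controls$mass_loss_g[controls$diet_id == diet_id]
  if (!length(loss))
    stop("missing control: no evaporation records for diet '", diet_id, "'",
         call. = FALSE)
  mean(loss)
}

#' Evaporation-corrected mass consumed in one cage-day
#'
#' Sums the mass change of both feeding tubes and subtracts the diet's mean
#' evaporative loss. The result can be negative when the correction exceeds
#' the measured change (weighing noise on a low-consumption day); negative
#' values are returned as-is with a warning, since flooring them would bias
#' cumulative intake upward.
#'
#' @param rec One feeding record: a list or one-row data frame with
#'   `tube1_pre_g`, `tube1_post_g`, `tube2_pre_g`, `tube2_post_g`.
#' @param evap Mean evaporative loss for the cage's diet, grams/day.
#' @return Consumed mass in grams (possibly negative).
#' @export
daily_consumption_mass <- function(rec, evap) {
  m <- (rec$tube1_pre_g - rec$tube1_post_g) +
       (rec$tube2_pre_g - rec$tube2_post_g) - evap
  if (m < 0)
    warning("evaporation correction exceeds measured mass change (",
            format(m), " g); retaining negative value", call. = FALSE)
  m
}

#' Per-individual consumed volume
#'
#' Divides a cage-day's consumed mass by the number of individuals alive
#' during that 24 h and converts mass to volume by the solution density.
#'
#' @param mass_g Consumed mass, grams.
#' @param n_alive Individuals alive during the preceding 24 h (>= 1; a
#'   cage-day with zero survivors contributes no intake and should be
#'   skipped upstream).
#' @param density Solution density, g/ml. Default 1.06 for all diets.
#' @return Volume in ml per individual.
#' @export
per_bee_volume <- function(mass_g, n_alive, density = 1.06) {
  if (n_alive < 1) stop("n_alive must be >= 1", call. = FALSE)
  if (density <= 0) stop("density must be > 0", call. = FALSE)
  (mass_g / n_alive) / density
}

#' Nutrient intake from a consumed volume
#'
#' Millilitres times mol/L gives millimoles, so a consumed volume maps onto
#' the diet's nutrient rail as `(volume * aa_molarity, volume * sucrose_molarity)`.
#'
#' @param volume_ml Consumed volume, ml.
#' @param diet A [diet()].
#' @return Named numeric `c(aa_mmol, c_mmol)`.
#' @export
nutrient_intake <- function(volume_ml, diet) {
  stopifnot(inherits(diet, "diet"))
  c(aa_mmol = volume_ml * diet$aa_total_molarity,
    c_mmol = volume_ml * diet$sucrose_molarity)
}

#' Cumulative per-individual intake of one cage
#'
#' Converts a cage's daily tube masses into an evaporation-corrected,
#' per-individual cumulative intake point. Each day's consumed mass is scaled
#' by that day's count of survivors *before* summing, so a death mid-trial
#' changes only the divisor of subsequent days. Days with zero survivors are
#' skipped (with a message); gaps in the day sequence trigger a warning but
#' the remaining days are still summed.
#'
#' @param records Data frame of the cage's feeding records: columns `day`,
#'   `tube1_pre_g`, `tube1_post_g`, `tube2_pre_g`, `tube2_post_g`, `n_alive`
#'   (plus `cage_id`, `diet_id`).
#' @param controls Control data frame (see [evaporation_mean()]).
#' @param diet The cage's [diet()].
#' @param density Solution density, g/ml.
#' @param floor_negative If `TRUE`, negative corrected daily masses are set
#'   to zero before summing; the default keeps them (unbiased).
#' @return One-row data frame of class `intake_point`: `cage_id`, `diet_id`,
#'   `volume_ml_per_bee`, `aa_mmol_per_bee`, `c_mmol_per_bee`.
#' @export
cumulative_intake <- function(records, controls, diet, density = 1.06,
                              floor_negative = FALSE) {
  stopifnot(inherits(diet, "diet"), nrow(records) >= 1)
  records <- records[order(records$day), , drop = FALSE]
  days <- records$day
  if (length(days) > 1 && any(diff(days) != 1))
    warning("gap in day sequence for cage '", records$cage_id[1L], "' (days ",
            paste(days, collapse = ","), ")", call. = FALSE)
  evap <- evaporation_mean(controls, diet$id)

  vol <- 0
  for (i in seq_len(nrow(records))) {
    rec <- records[i, ]
    if (rec$n_alive < 1) {
      message("cage '", rec$cage_id, "' day ", rec$day,
              ": no survivors, day skipped")
      next
    }
    m <- daily_consumption_mass(rec, evap)
    if (floor_negative && m < 0) m <- 0
    vol <- vol + per_bee_volume(m, rec$n_alive, density)
  }
  if (vol < 0)
    warning("negative cumulative volume for cage '", records$cage_id[1L],
            "'; retained", call. = FALSE)
  mmol <- nutrient_intake(vol, diet)
  structure(
    data.frame(cage_id = records$cage_id[1L], diet_id = diet$id,
               volume_ml_per_bee = vol,
               aa_mmol_per_bee = unname(mmol["aa_mmol"]),
               c_mmol_per_bee = unname(mmol["c_mmol"]),
               row.names = NULL),
    class = c("intake_point", "data.frame"))
}

#' Per-cage cumulative intakes for a whole trial
#'
#' Applies [cumulative_intake()] to every cage in a feeding-record table.
#'
#' @param feeding Data frame of feeding records for all cages (columns as in
#'   [cumulative_intake()], plus `cage_id` and `diet_id`).
#' @param controls Control data frame.
#' @param panel The trial's `diet_panel`.
#' @param density Solution density, g/ml.
#' @param floor_negative Passed to [cumulative_intake()].
#' @return Data frame with one row per cage: `cage_id`, `diet_id`,
#'   `volume_ml_per_bee`, `aa_mmol_per_bee`, `c_mmol_per_bee`.
#' @examples
#' sim <- simulate_trial(sim_config(n_cages_per_diet = 2, seed = 1))
#' head(compute_intake(sim$feeding_records, sim$controls, sim$panel))
#' @export
compute_intake <- function(feeding, controls, panel, density = 1.06,
                           floor_negative = FALSE) {
  stopifnot(inherits(panel, "diet_panel"))
  need <- c("cage_id", "diet_id", "day", "tube1_pre_g", "tube1_post_g",
            "tube2_pre_g", "tube2_post_g", "n_alive")
  miss <- setdiff(need, names(feeding))
  if (length(miss))
    stop("feeding records lack columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  unknown <- setdiff(unique(feeding$diet_id), names(panel))
  if (length(unknown))
    stop("feeding records reference diets absent from the panel: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  rows <- lapply(split(feeding, feeding$cage_id), function(recs) {
    cumulative_intake(recs, controls, panel[[recs$diet_id[1L]]],
                      density = density, floor_negative = floor_negative)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-diet mean intake with standard errors
#'
#' Collapses per-cage intake points to per-diet means and standard errors,
#' ordered as the panel. These means are the points of the intake array and
#' the descriptive total-intake comparison across diets.
#'
#' @param intake Per-cage intake data frame from [compute_intake()].
#' @param panel The `diet_panel` (fixes ordering).
#' @return Data frame: `diet_id`, `n_cages`, `mean_volume_ml`, `se_volume_ml`,
#'   `mean_aa_mmol`, `se_aa`, `mean_c_mmol`, `se_c`.
#' @export
intake_means <- function(intake, panel) {
  stopifnot(inherits(panel, "diet_panel"))
  se <- function(x) if (length(x) > 1) stats::sd(x) / sqrt(length(x)) else NA_real_
  rows <- lapply(names(panel), function(id) {
    sub <- intake[intake$diet_id == id, , drop = FALSE]
    if (!nrow(sub)) return(NULL)
    data.frame(diet_id = id, n_cages = nrow(sub),
               mean_volume_ml = mean(sub$volume_ml_per_bee),
               se_volume_ml = se(sub$volume_ml_per_bee),
               mean_aa_mmol = mean(sub$aa_mmol_per_bee),
               se_aa = se(sub$aa_mmol_per_bee),
               mean_c_mmol = mean(sub$c_mmol_per_bee),
               se_c = se(sub$c_mmol_per_bee),
               row.names = NULL)
  })
  do.call(rbind, rows)
}
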