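#' Amino-acid mixes
#'
#' An `aa_mix` is a named set of amino-acid proportions summing to one. It
#' fixes *which* amino acids a diet contains and in what molar ratio relative
#' to one another; the diet's AA:C ratio then sets how much of the mix goes
#' into solution. Two mixes are of practical interest: an equimolar blend of
#' the ten essential amino acids, and a "pollen" blend whose proportions
#' mirror those measured in bee-collected pollen (supplied by the user as
#' configuration, see [read_mix_file()]).
#'
#' @param proportions Named numeric vector of per-amino-acid fractions. Must
#'   be non-negative and sum to 1 (tolerance `1e-9`).
#' @param name Label for the mix.
#' @return An object of class `aa_mix`: a list with elements `name` and
#'   `proportions`.
#' @seealso [normalize_proportions()] to build a valid mix from raw weights.
#' @examples
#' aa_mix(c(A = 0.5, B = 0.5), name = "demo")
#' equimolar_mix()
#' @export
aa_mix <- function(proportions, name = "custom") {
  if (length(proportions) < 1L)
    stop("an amino-acid mix needs at least one amino acid", call. = FALSE)
  if (is.null(names(proportions)) || any(!nzchar(names(proportions))))
    stop("all proportions must be named by amino acid", call. = FALSE)
  if (anyNA(proportions) || any(proportions < 0))
    stop("proportions must be non-negative and non-missing", call. = FALSE)
  if (abs(sum(proportions) - 1) > 1e-9)
    stop("proportions must sum to 1 (got ", format(sum(proportions)),
         "); use normalize_proportions()", call. = FALSE)
  structure(list(name = name, proportions = proportions), class = "aa_mix")
}

#' @export
print.aa_mix <- function(x, ...) {
  cat("Amino-acid mix '", x$name, "' (", length(x$proportions), " AAs)\n",
      sep = "")
  print(round(x$proportions, 4))
  invisible(x)
}

# The ten amino acids essential for bee growth and survival.
EAA10 <- c("arginine", "histidine", "isoleucine", "leucine", "lysine",
           "methionine", "phenylalanine", "threonine", "tryptophan", "valine")

#' @param amino_acids Character vector of amino-acid names for the equimolar
#'   mix; defaults to the ten essential amino acids.
#' @rdname aa_mix
#' @export
equimolar_mix <- function(amino_acids = EAA10) {
  k <- length(amino_acids)
  aa_mix(stats::setNames(rep(1 / k, k), amino_acids), name = "equimolar")
}

#' Normalize raw amino-acid weights into a mix
#'
#' Rescales arbitrary non-negative weights (e.g. measured pollen proportions
#' covering only a subset of amino acids) so they sum to one.
#'
#' @param raw Named numeric vector of non-negative weights, at least one
#'   positive.
#' @param name Label for the resulting mix.
#' @return An [aa_mix()].
#' @examples
#' normalize_proportions(c(A = 2, B = 3, C = 5))
#' @export
normalize_proportions <- function(raw, name = "custom") {
  if (anyNA(raw) || any(raw < 0))
    stop("invalid mix: negative or missing weights", call. = FALSE)
  total <- sum(raw)
  if (!length(raw) || total <= 0)
    stop("invalid mix: weights are all zero", call. = FALSE)
  aa_mix(raw / total, name = name)
}

#' Total amino-acid molarity implied by an AA:C molar ratio
#'
#' Diets are built at a fixed sucrose molarity; the AA:C ratio is molar, so
#' the total amino-acid molarity is `sucrose_molarity * ratio_aa / ratio_c`.
#' A 1:10 diet at 0.5 mol/L sucrose therefore carries 0.05 mol/L total AA.
#'
#' @param ratio_aa Non-negative molar parts of amino acid.
#' @param ratio_c Positive molar parts of carbohydrate.
#' @param sucrose_molarity Sucrose concentration in mol/L (> 0).
#' @return Total amino-acid molarity in mol/L.
#' @examples
#' aa_total_molarity(1, 10, 0.5)  # 0.05
#' @export
aa_total_molarity <- function(ratio_aa, ratio_c, sucrose_molarity) {
  if (any(ratio_c <= 0)) stop("invalid ratio: ratio_c must be > 0", call. = FALSE)
  if (any(ratio_aa < 0)) stop("invalid ratio: ratio_aa must be >= 0", call. = FALSE)
  if (any(sucrose_molarity <= 0))
    stop("sucrose molarity must be > 0", call. = FALSE)
  sucrose_molarity * ratio_aa / ratio_c
}

#' Per-amino-acid concentrations of a diet
#'
#' Splits a total amino-acid molarity across the amino acids of a mix. An
#' equimolar ten-AA mix at 0.1 mol/L total puts each amino acid at 0.01 mol/L.
#'
#' @param total Total amino-acid molarity (mol/L, >= 0).
#' @param mix An [aa_mix()].
#' @return Named numeric vector of per-amino-acid molarities summing to
#'   `total`.
#' @export
per_aa_concentrations <- function(total, mix) {
  stopifnot(inherits(mix, "aa_mix"))
  if (total < 0) stop("total molarity must be >= 0", call. = FALSE)
  total * mix$proportions
}

ratio_id <- function(ratio_aa, ratio_c) paste0(ratio_aa, ":", ratio_c)

parse_ratio <- function(x) {
  if (is.character(x)) {
    parts <- strsplit(x, ":", fixed = TRUE)[[1L]]
    if (length(parts) != 2L) stop("ratio string must look like '1:10'", call. = FALSE)
    x <- as.numeric(parts)
  }
  if (length(x) != 2L || anyNA(x))
    stop("a ratio is a pair (ratio_aa, ratio_c)", call. = FALSE)
  x
}

#' Build a diet
#'
#' @param ratio_aa,ratio_c The AA:C molar ratio as an integer pair (kept as
#'   parts, never pre-divided, so diet ids stay exact).
#' @param sucrose_molarity Sucrose concentration, mol/L.
#' @param mix An [aa_mix()] fixing the relative amino-acid proportions.
#' @return An object of class `diet`: id, ratio, sucrose and total-AA
#'   molarity, and per-amino-acid molarities.
#' @export
diet <- function(ratio_aa, ratio_c, sucrose_molarity = 0.5,
                 mix = equimolar_mix()) {
  total <- aa_total_molarity(ratio_aa, ratio_c, sucrose_molarity)
  structure(list(
    id = ratio_id(ratio_aa, ratio_c),
    ratio_aa = ratio_aa,
    ratio_c = ratio_c,
    sucrose_molarity = sucrose_molarity,
    aa_total_molarity = total,
    per_aa_molarity = per_aa_concentrations(total, mix),
    mix_name = mix$name
  ), class = "diet")
}

#' @export
print.diet <- function(x, ...) {
  cat(sprintf("Diet %s: %.4g M sucrose, %.4g M total AA (mix '%s')\n",
              x$id, x$sucrose_molarity, x$aa_total_molarity, x$mix_name))
  invisible(x)
}

#' The seven AA:C ratios of the reference feeding trial
#'
#' `0:1, 1:250, 1:100, 1:75, 1:50, 1:25, 1:10`, ordered from sucrose-only to
#' most amino-acid rich.
#'
#' @return A list of integer pairs `c(ratio_aa, ratio_c)`.
#' @export
default_ratios <- function() {
  list(c(0, 1), c(1, 250), c(1, 100), c(1, 75), c(1, 50), c(1, 25), c(1, 10))
}

#' Build the experimental diet panel
#'
#' Creates one [diet()] per AA:C ratio at a common sucrose molarity and
#' amino-acid mix. Note the total solute (AA + C) deliberately varies across
#' the panel: the carbohydrate concentration is held constant while the
#' amino-acid portion changes, so richer ratios carry more total nutrient.
#'
#' @param ratios List of ratio pairs `c(ratio_aa, ratio_c)` or strings
#'   `"1:10"`; must be unique. Defaults to [default_ratios()].
#' @param sucrose_molarity Sucrose concentration, mol/L.
#' @param mix An [aa_mix()].
#' @return An object of class `diet_panel` (a named list of `diet` objects,
#'   ordered as given).
#' @examples
#' panel <- build_diet_panel()
#' as.data.frame(panel)
#' @export
build_diet_panel <- function(ratios = default_ratios(), sucrose_molarity = 0.5,
                             mix = equimolar_mix()) {
  if (!length(ratios)) stop("ratio list must be non-empty", call. = FALSE)
  ratios <- lapply(ratios, parse_ratio)
  ids <- vapply(ratios, function(r) ratio_id(r[1L], r[2L]), character(1))
  if (anyDuplicated(ids))
    stop("duplicate ratios in diet panel: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  diets <- lapply(ratios, function(r) diet(r[1L], r[2L], sucrose_molarity, mix))
  names(diets) <- ids
  structure(diets, class = "diet_panel")
}

#' @export
print.diet_panel <- function(x, ...) {
  cat("Diet panel (", length(x), " diets, mix '", x[[1L]]$mix_name, "'):\n",
      sep = "")
  print(as.data.frame(x), row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.diet_panel <- function(x, ...) {
  data.frame(
    diet_id = vapply(x, `[[`, character(1), "id"),
    ratio_aa = vapply(x, `[[`, numeric(1), "ratio_aa"),
    ratio_c = vapply(x, `[[`, numeric(1), "ratio_c"),
    sucrose_molarity_M = vapply(x, `[[`, numeric(1), "sucrose_molarity"),
    aa_total_molarity_M = vapply(x, `[[`, numeric(1), "aa_total_molarity"),
    mix_name = vapply(x, `[[`, character(1), "mix_name"),
    row.names = NULL
  )
}

#' Experimental design bookkeeping for a diet panel
#'
#' Tallies cages and individuals for a panel-wide design with a fixed number
#' of micro-colonies per diet and individuals per micro-colony. The reference
#' trial ran 15 micro-colonies of 5 bees on each of 7 diets for the pollen
#' mix (525 bees) and 5 micro-colonies per diet for the equimolar mix
#' (175 bees).
#'
#' @param panel A `diet_panel`.
#' @param n_cages_per_diet Micro-colonies allocated to each diet.
#' @param n_bees Individuals per micro-colony.
#' @return A list with `n_diets`, `n_cages`, `n_bees_per_cage` and
#'   `n_bees_total`.
#' @examples
#' panel_design(build_diet_panel(), n_cages_per_diet = 15, n_bees = 5)
#' @export
panel_design <- function(panel, n_cages_per_diet, n_bees) {
  stopifnot(inherits(panel, "diet_panel"),
            n_cages_per_diet >= 1, n_bees >= 1)
  n_diets <- length(panel)
  list(n_diets = n_diets,
       n_cages = n_cages_per_diet * n_diets,
       n_bees_per_cage = n_bees,
       n_bees_total = n_cages_per_diet * n_bees * n_diets)
}
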