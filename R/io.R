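#' Read an amino-acid mix file
#'
#' A mix file is a two-column delimited table (`amino_acid`, `proportion`);
#' proportions are rescaled to sum to one, so raw measured weights are
#' accepted. A synthetic example ships in
#' `system.file("extdata", "pollen_mix_synthetic.tsv", package = "nutrigeo")`.
#'
#' @param path Path to the table (TSV or CSV; delimiter sniffed from the
#'   extension).
#' @param name Mix label; default the file name without extension.
#' @return An [aa_mix()].
#' @export
read_mix_file <- function(path, name = NULL) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  if (!all(c("amino_acid", "proportion") %in% names(tab)))
    stop("mix file needs columns 'amino_acid' and 'proportion'",
         call. = FALSE)
  if (is.null(name))
    name <- sub("\\.[^.]+$", "", basename(path))
  normalize_proportions(
    stats::setNames(tab$proportion, tab$amino_acid), name = name)
}

#' Read a diet-panel configuration
#'
#' A YAML (or JSON-as-YAML) file with keys `sucrose_molarity`, `ratios`
#' (list of `"aa:c"` strings) and optionally `mix_file` (path to a mix
#' table, resolved relative to the config file) or `mix: equimolar`.
#'
#' @param path Path to the configuration file.
#' @return A `diet_panel`.
#' @export
read_diet_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$ratios) || is.null(cfg$sucrose_molarity))
    stop("diet config needs 'ratios' and 'sucrose_molarity'", call. = FALSE)
  mix <- if (!is.null(cfg$mix_file)) {
    mp <- cfg$mix_file
    if (!file.exists(mp)) mp <- file.path(dirname(path), cfg$mix_file)
    read_mix_file(mp)
  } else {
    equimolar_mix()
  }
  build_diet_panel(as.list(cfg$ratios), cfg$sucrose_molarity, mix)
}

#' Write the standard CSV outputs of a simulated trial
#'
#' Emits `feeding_records.csv`, `controls.csv` and `truth.csv` into a
#' directory, in the schemas consumed by [compute_intake()].
#'
#' @param sim A [simulate_trial()] output.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_trial_csv <- function(sim, dir) {
  stopifnot(inherits(sim, "feeding_sim"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    feeding_records = file.path(dir, "feeding_records.csv"),
    controls = file.path(dir, "controls.csv"),
    truth = file.path(dir, "truth.csv"))
  utils::write.csv(sim$feeding_records, paths["feeding_records"],
                   row.names = FALSE)
  utils::write.csv(sim$controls, paths["controls"], row.names = FALSE)
  utils::write.csv(sim$truth, paths["truth"], row.names = FALSE)
  invisible(paths)
}

#' Write a diet panel to CSV
#'
#' @param panel A `diet_panel`.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_diet_panel <- function(panel, path) {
  utils::write.csv(as.data.frame(panel), path, row.names = FALSE)
  invisible(path)
}
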