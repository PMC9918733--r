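# Run configuration: every stage parameter with its default, overridable from
# a YAML file for the command-line interface. Defaults are the assay's
# published operating points.

#' Default run configuration
#'
#' Returns the nested list of all stage parameters at their default values:
#' cell calling (`total_read_multiplier = 8`, `completeness_fraction = 0.8`,
#' `working_amplicon_factor = 0.2`), genotyping (`min_depth = 5`,
#' `min_alt = 3`, VAF bins at 20/80), strict variant filtering
#' (`strict_min_depth = 10`, `strict_min_alt = 5`,
#' `max_missing_fraction = 0.75`, `min_prevalence = 0.005`), germline SNP
#' selection and ADO, depth planning, and ploidy (`good_cell_rank = 10`,
#' `good_cell_fraction = 0.1`, `homdel_ploidy_max = 0.5`).
#'
#' @param seed Integer random seed recorded in the configuration.
#' @return A named list of parameter groups.
#' @export
default_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    cell_calling = unclass(cell_calling_params()),
    genotyping = unclass(genotype_params()),
    variant_filter = unclass(variant_filter_params()),
    snp_selection = unclass(snp_selection_params()),
    ado = list(min_depth = 5L),
    depth_plan = list(target_depth = 100, frac_reads_to_cells = 0.5),
    ploidy = unclass(ploidy_params())
  )
}

#' Load a run configuration from a YAML file
#'
#' Values present in the file override the defaults; anything omitted keeps
#' its default. Thresholds are validated by the stage constructors when used.
#'
#' @param path Path to a YAML configuration file, or `NULL` for pure defaults.
#' @param seed Seed used when the file does not set one.
#' @return A configuration list as from [default_config()].
#' @export
load_config <- function(path = NULL, seed = 1L) {
  cfg <- default_config(seed)
  if (is.null(path)) return(cfg)
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  user <- yaml::read_yaml(path)
  utils::modifyList(cfg, user)
}
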