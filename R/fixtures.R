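# Published summary tables of the field trial, shipped as packaged CSV
# fixtures. These are the study's reported endpoints: per-stage WSI with row
# (per-variety) and column (per-stage) means, stem-elongation WCI with its
# printed dispersion, and the harvest yield components. They drive the
# reproduction mode of the pipeline and anchor the correlation analysis.

extdata_path <- function(file) {
  p <- system.file("extdata", file, package = "thermowheat")
  if (p == "") {
    # during development (package loaded from source tree)
    p <- file.path("inst", "extdata", file)
  }
  if (!file.exists(p))
    stop("packaged fixture not found: ", file, call. = FALSE)
  p
}

#' Published per-stage WSI table
#'
#' Stage-level Wheat Stress Index values for the nine varieties of one
#' species across the four monitored phenological stages, with the published
#' per-variety mean (`wsi_m`). All published values carry a stated maximum
#' error of +/- 0.01.
#'
#' @param species `"durum"` or `"common"`.
#' @return data.frame with columns `variety`, the four stage columns,
#'   `wsi_m` and `is_modern`.
#' @export
reference_wsi_table <- function(species = c("durum", "common")) {
  species <- match.arg(species)
  tab <- utils::read.csv(extdata_path(paste0("wsi_stage_", species, ".csv")),
                         stringsAsFactors = FALSE)
  tab$is_modern <- tab$variety %in% modern_varieties(species)
  tab
}

#' Published stem-elongation WCI table
#'
#' Mean Wheat Cover Index per variety estimated from the stem-elongation
#' thermal frames, with the published dispersion (`wci_pm`, the +/- value).
#'
#' @inheritParams reference_wsi_table
#' @return data.frame with columns `variety`, `wci_m`, `wci_pm`, `is_modern`.
#' @export
reference_wci_table <- function(species = c("durum", "common")) {
  species <- match.arg(species)
  tab <- utils::read.csv(extdata_path(paste0("wci_", species, ".csv")),
                         stringsAsFactors = FALSE)
  tab$is_modern <- tab$variety %in% modern_varieties(species)
  tab
}

#' Published yield-component table
#'
#' Harvest measurements per variety: grain yield and total above-ground
#' biomass (t/ha), culm and spike densities (per m^2), each with its
#' published dispersion (`*_pm` columns).
#'
#' @inheritParams reference_wsi_table
#' @return A `yield_table` data.frame (see [read_yield_table()]).
#' @export
reference_yield_table <- function(species = c("durum", "common")) {
  species <- match.arg(species)
  read_yield_table(extdata_path(paste0("yield_", species, ".csv")), species)
}

#' All published reference tables
#'
#' @return Named list with elements `wsi`, `wci` and `yield`, each a list
#'   with `durum` and `common` data.frames.
#' @export
reference_tables <- function() {
  list(
    wsi = list(durum = reference_wsi_table("durum"),
               common = reference_wsi_table("common")),
    wci = list(durum = reference_wci_table("durum"),
               common = reference_wci_table("common")),
    yield = list(durum = reference_yield_table("durum"),
                 common = reference_yield_table("common"))
  )
}
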