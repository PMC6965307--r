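#' Pipeline configuration
#'
#' One object drives the whole chain: scenario (or input paths),
#' dispersion, interpolation, dasymetric weights, risk normalization,
#' classification and hotspot/apportionment settings.  Analysis-scale
#' defaults (receptor stride 10 cells, 100 m line-source segments for the
#' annual field, 2000-value Jenks subsample) keep a full county run at
#' desk scale; each is an explicit field serialized with the manifest.
#'
#' @param seed Integer seed for the synthetic scenario and any sampling.
#' @param out_dir Output directory for [run_pipeline()] artifacts.
#' @param scenario A [scenario_config()] (default: the standard synthetic
#'   county built with `rng_seed = seed`), or a directory path holding a
#'   written scenario ([write_scenario()] layout).
#' @param receptor_stride Receptor subsampling stride in cells.
#' @param seg_len Line-source discretization (m) for the annual field.
#' @param calm_threshold Calm wind cut-off (m/s).
#' @param idw_power,idw_k IDW exponent and neighbourhood size.
#' @param fractions Land-use [class_fractions()].
#' @param risk_unit `"extent"` (county-wide normalization, the default)
#'   or `"per-block"`.
#' @param hotspot_fraction Top fraction for hotspot masks.
#' @param jenks_sample Subsample cap for natural-breaks classification.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, out_dir = NULL,
                            scenario = NULL,
                            receptor_stride = 10L,
                            seg_len = 100,
                            calm_threshold = 0.5,
                            idw_power = 2, idw_k = 12L,
                            fractions = default_class_fractions(),
                            risk_unit = c("extent", "per-block"),
                            hotspot_fraction = 0.10,
                            jenks_sample = 2000L) {
  risk_unit <- match.arg(risk_unit)
  if (is.null(scenario)) scenario <- scenario_config(rng_seed = seed)
  if (is.character(scenario) && !dir.exists(scenario))
    stop_config("scenario directory does not exist: %s", scenario)
  if (receptor_stride < 1 || seg_len <= 0 || idw_k < 1 || hotspot_fraction <= 0)
    stop_config("invalid pipeline parameters")
  structure(list(seed = as.integer(seed), out_dir = out_dir,
                 scenario = scenario,
                 receptor_stride = as.integer(receptor_stride),
                 seg_len = seg_len, calm_threshold = calm_threshold,
                 idw_power = idw_power, idw_k = as.integer(idw_k),
                 fractions = fractions, risk_unit = risk_unit,
                 hotspot_fraction = hotspot_fraction,
                 jenks_sample = as.integer(jenks_sample)),
            class = "pipeline_config")
}

#' Run the analysis chain in memory
#'
#' Executes dispersion -> interpolation -> dasymetric mapping -> relative
#' risk -> hotspot and apportionment analyses on a scenario and returns
#' every intermediate product, without touching the file system.
#'
#' @param scenario A `synthetic_scenario` (from [generate_scenario()] or
#'   [read_scenario()]).
#' @param config A [pipeline_config()].
#' @return List with `rose`, `receptors`, `field`, `conc` (3 rasters),
#'   `cell_map`, `pop` (7 rasters), `risk` (21 rasters), `hotspots`,
#'   `apportionment`.
#' @export
run_analysis <- function(scenario, config = pipeline_config()) {
  grid <- scenario$grid
  rose <- build_wind_rose(scenario$met, calm_threshold = config$calm_threshold)
  receptors <- receptor_grid(grid, config$receptor_stride)
  field <- annual_mean_field(scenario$inventory, rose, receptors,
                             seg_len = config$seg_len)
  conc <- lapply(c(industrial = "industrial", vehicle = "vehicle",
                   combined = "combined"), function(s)
    idw(data.frame(x = field$x, y = field$y, value = field[[s]]),
        grid, power = config$idw_power, k_neighbors = config$idw_k))
  cell_map <- assign_cells_to_blocks(scenario$blocks, grid)
  pop <- dasymetric_map(scenario$blocks, scenario$landuse, config$fractions,
                        grid, cell_map = cell_map)
  unit <- if (config$risk_unit == "per-block") cell_map else NULL
  risk <- risk_stack(pop, conc, unit = unit)
  hotspots <- hotspot_table(conc, risk, fraction = config$hotspot_fraction)
  apportionment <- apportion_risks(risk, pop)
  list(rose = rose, receptors = receptors, field = field, conc = conc,
       cell_map = cell_map, pop = pop, risk = risk,
       hotspots = hotspots, apportionment = apportionment)
}

#' Run the full pipeline and write its artifact set
#'
#' Four steps in order — dispersion to discrete receptors, interpolation
#' onto the analysis grid, dasymetric population mapping, relative-risk
#' surfaces — followed by natural-breaks legends, the hotspot
#' centroid-shift table and the apportionment table.  Every artifact is
#' listed in `manifest.tsv` with an MD5 content hash; runs are fully
#' deterministic given the seed.  A stage failure aborts with the stage
#' name and leaves the partial manifest with a `FAILED` marker.
#'
#' @param config A [pipeline_config()] with `out_dir` set.
#' @return The manifest data.frame (file, md5, bytes), invisibly the
#'   in-memory products as attribute `products`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  if (is.null(out)) stop_config("pipeline_config needs an out_dir")
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  stage <- "configuration"
  emit <- function(path) written <<- c(written, path)
  finish_manifest <- function(failed = NULL) {
    man <- data.frame(file = basename(written),
                      md5 = unname(tools::md5sum(written)),
                      bytes = file.size(written))
    if (!is.null(failed))
      man <- rbind(man, data.frame(file = sprintf("FAILED:%s", failed),
                                   md5 = "", bytes = NA))
    write.table(man, file.path(out, "manifest.tsv"), sep = "\t",
                row.names = FALSE, quote = FALSE)
    man
  }
  result <- tryCatch({
    cfg_json <- config
    cfg_json$out_dir <- NULL  # provenance must not depend on where a run landed
    cfg_json$scenario <- if (is.character(config$scenario)) config$scenario else
      unclass(config$scenario)
    writeLines(jsonlite::toJSON(unclass(cfg_json), auto_unbox = TRUE,
                                digits = NA, null = "null", pretty = TRUE),
               file.path(out, "config.json"))
    emit(file.path(out, "config.json"))

    stage <- "scenario"
    scenario <- if (is.character(config$scenario)) read_scenario(config$scenario)
      else generate_scenario(config$scenario)
    for (p in write_scenario(scenario, out)) emit(p)

    stage <- "dispersion"
    rose <- build_wind_rose(scenario$met, calm_threshold = config$calm_threshold)
    receptors <- receptor_grid(scenario$grid, config$receptor_stride)
    field <- annual_mean_field(scenario$inventory, rose, receptors,
                               seg_len = config$seg_len)
    emit(write_concentration_field(field, file.path(out, "conc_receptors.tsv")))

    stage <- "interpolation"
    conc <- list()
    for (s in c("industrial", "vehicle", "combined")) {
      conc[[s]] <- idw(data.frame(x = field$x, y = field$y, value = field[[s]]),
                       scenario$grid, power = config$idw_power,
                       k_neighbors = config$idw_k)
      emit(write_ascii_grid(conc[[s]], file.path(out, sprintf("conc_%s.asc", s))))
    }

    stage <- "dasymetric"
    cell_map <- assign_cells_to_blocks(scenario$blocks, scenario$grid)
    pop <- dasymetric_map(scenario$blocks, scenario$landuse, config$fractions,
                          scenario$grid, cell_map = cell_map)
    for (g in DEMO_GROUPS)
      emit(write_ascii_grid(pop[[g]], file.path(out, sprintf("pop_%s.asc", g))))

    stage <- "risk"
    unit <- if (config$risk_unit == "per-block") cell_map else NULL
    risk <- risk_stack(pop, conc, unit = unit)
    for (nm in names(risk))
      emit(write_ascii_grid(risk[[nm]], file.path(out, sprintf("%s.asc", nm))))

    stage <- "classification"
    legends <- list()
    for (s in names(conc)) {
      sch <- try_jenks(as.vector(conc[[s]]$values), 4, config$jenks_sample)
      if (!is.null(sch))
        legends[[length(legends) + 1L]] <-
          cbind(field = sprintf("conc_%s", s), scheme_legend(sch))
    }
    for (nm in names(risk)) {
      sch <- try_jenks(as.vector(risk[[nm]]$values), 6, config$jenks_sample)
      if (!is.null(sch))
        legends[[length(legends) + 1L]] <- cbind(field = nm, scheme_legend(sch))
    }
    write.table(do.call(rbind, legends), file.path(out, "legends.tsv"),
                sep = "\t", row.names = FALSE, quote = FALSE)
    emit(file.path(out, "legends.tsv"))

    stage <- "hotspot"
    hs <- hotspot_table(conc, risk, fraction = config$hotspot_fraction)
    write.table(hs, file.path(out, "hotspots.tsv"), sep = "\t",
                row.names = FALSE, quote = FALSE)
    emit(file.path(out, "hotspots.tsv"))

    stage <- "apportionment"
    ap <- apportion_risks(risk, pop)
    emit(write_apportionment(ap, file.path(out, "apportionment.tsv")))

    man <- finish_manifest()
    attr(man, "products") <- list(rose = rose, field = field, conc = conc,
                                  pop = pop, risk = risk, hotspots = hs,
                                  apportionment = ap)
    man
  }, error = function(e) {
    finish_manifest(failed = stage)
    stop_config("pipeline stage '%s' failed: %s", stage, conditionMessage(e))
  })
  invisible(result)
}

# Jenks with a graceful skip when a field is too degenerate to classify
# (e.g. an all-zero risk surface from an empty source category).
try_jenks <- function(values, k, sample_n) {
  tryCatch(jenks_breaks(values, k, sample_n = sample_n),
           error = function(e) NULL)
}
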