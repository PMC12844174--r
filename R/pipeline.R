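PIPELINE_STAGES <- c("simulate", "rarefy", "diversity", "decay",
                     "assembly", "drivers")

#' Configuration for a full pipeline run
#'
#' Either a synthetic scenario (`scenario`) or the three input paths
#' (`table_path`, `tree_path`, `metadata_path`) must be supplied.  One
#' master `seed` deterministically spawns per-stage seeds
#' (child i = (seed + i * 1000003) mod (2^31 - 1), stage order as in the
#' manifest), so any stage can be rerun in isolation.
#'
#' @param out_dir output directory; stage outputs land in `out_dir/<stage>/`.
#' @param seed master integer seed (mandatory).
#' @param scenario optional `scenario_config` for synthetic mode.
#' @param table_path,tree_path,metadata_path input files for real-data mode.
#' @param depth rarefaction depth; NULL = minimum sample sum.
#' @param n_null null replicates for the assembly stage.
#' @param n_perm permutations for Mantel/PERMANOVA/ANOSIM/decay tests.
#' @param unit_km scale-unit width for the scale-dependence analysis.
#' @param min_pairs minimum pairs per scale unit.
#' @param weighted abundance-weighted beta-MNTD (default) or presence-based.
#' @param stages subset of stages to run (in pipeline order).
#' @return object of class `run_config`.
#' @export
run_config <- function(out_dir, seed, scenario = NULL, table_path = NULL,
                       tree_path = NULL, metadata_path = NULL, depth = NULL,
                       n_null = 999, n_perm = 999, unit_km = 60,
                       min_pairs = 5, weighted = TRUE,
                       stages = PIPELINE_STAGES) {
  if (missing(seed)) stop_("seed is mandatory", class = "invalid_argument")
  stages <- match.arg(stages, PIPELINE_STAGES, several.ok = TRUE)
  if (is.null(scenario) &&
      (is.null(table_path) || is.null(metadata_path)))
    stop_("supply a scenario or input paths", class = "invalid_argument")
  if (!is.null(scenario) && !inherits(scenario, "scenario_config"))
    stop_("scenario must come from scenario_config()", class = "invalid_argument")
  structure(list(
    out_dir = out_dir, seed = check_count_(seed, "seed", -.Machine$integer.max),
    scenario = scenario, table_path = table_path, tree_path = tree_path,
    metadata_path = metadata_path, depth = depth,
    n_null = check_count_(n_null, "n_null"),
    n_perm = check_count_(n_perm, "n_perm"),
    unit_km = unit_km, min_pairs = check_count_(min_pairs, "min_pairs"),
    weighted = isTRUE(weighted),
    stages = PIPELINE_STAGES[PIPELINE_STAGES %in% stages]
  ), class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys are `run_config()` arguments; an optional `scenario`
#' mapping holds `scenario_config()` arguments.
#'
#' @param path YAML file.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  if (!is.null(vals$scenario))
    vals$scenario <- do.call(scenario_config, vals$scenario)
  do.call(run_config, vals)
}

write_stage_csv_ <- function(df, dir, name) {
  path <- file.path(dir, name)
  write.csv(format(df, digits = 15, trim = TRUE, scientific = FALSE),
            path, row.names = FALSE, quote = FALSE)
  path
}

#' Run the full cryoconite biogeography pipeline
#'
#' Executes the requested stages in order — simulate (or load), rarefy,
#' diversity, decay, assembly, drivers — writing each stage's outputs under
#' `out_dir/<stage>/` and a JSON manifest (stages, parameters, seeds,
#' output md5 sums, wall times) at `out_dir/manifest.json`.  Reruns with an
#' identical configuration produce byte-identical outputs.
#'
#' @param config a `run_config`.
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "run_config"))
    stop_("config must come from run_config()", class = "invalid_argument")
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  seeds <- setNames(spawn_seeds_(config$seed, length(PIPELINE_STAGES)),
                    PIPELINE_STAGES)
  manifest <- list(package = "cryoassembly",
                   version = as.character(utils::packageVersion("cryoassembly")),
                   seed = config$seed,
                   parameters = list(depth = config$depth, n_null = config$n_null,
                                     n_perm = config$n_perm,
                                     unit_km = config$unit_km,
                                     min_pairs = config$min_pairs,
                                     weighted = config$weighted),
                   stages = list())
  outputs <- character(0)
  state <- new.env(parent = emptyenv())

  run_stage <- function(name, fun) {
    if (!name %in% config$stages) return(invisible())
    t0 <- proc.time()[["elapsed"]]
    dir <- file.path(config$out_dir, name)
    dir.create(dir, showWarnings = FALSE)
    files <- tryCatch(fun(dir, seeds[[name]]), error = function(e)
      stop_("stage '%s' failed: %s", name, conditionMessage(e),
            class = "stage_failure"))
    manifest$stages[[name]] <<- list(
      seed = seeds[[name]],
      elapsed_s = round(proc.time()[["elapsed"]] - t0, 3),
      outputs = as.character(files))
    outputs <<- c(outputs, as.character(files))
    message(sprintf("[%s] done in %.1fs", name,
                    proc.time()[["elapsed"]] - t0))
  }

  run_stage("simulate", function(dir, seed) {
    if (!is.null(config$scenario)) {
      sc <- config$scenario
      sc$seed <- seed          # master seed governs synthetic mode
      ds <- simulate_metacommunity(sc)
      state$dataset <- ds
      write_dataset(ds, dir)
    } else {
      for (p in c(config$table_path, config$tree_path, config$metadata_path))
        if (!is.null(p) && !file.exists(p))
          stop_("input file not found: %s", p, class = "io_error")
      state$dataset <- list(
        table = read_feature_table(config$table_path),
        tree = if (is.null(config$tree_path)) NULL
               else ape::read.tree(config$tree_path),
        metadata = read_sample_metadata(config$metadata_path))
      validate_dataset(state$dataset$table, state$dataset$tree,
                       state$dataset$metadata)
      character(0)
    }
  })

  run_stage("rarefy", function(dir, seed) {
    ds <- state$dataset
    depth <- if (is.null(config$depth)) min(rowSums(ds$table)) else config$depth
    rt <- rarefy(ds$table, depth = depth, seed = seed)
    dropped <- attr(rt, "dropped")
    state$dataset$table <- rt
    state$dataset$metadata <-
      ds$metadata[ds$metadata$sample_id %in% rownames(rt), ]
    writeLines(c(sprintf("depth\t%d", depth),
                 sprintf("dropped\t%s", paste(dropped, collapse = ","))),
               file.path(dir, "rarefaction_report.tsv"))
    write_feature_table(rt, file.path(dir, "feature_table_rarefied.tsv"))
    file.path(dir, c("rarefaction_report.tsv", "feature_table_rarefied.tsv"))
  })

  run_stage("diversity", function(dir, seed) {
    ds <- state$dataset
    alpha <- alpha_diversity(ds$table)
    state$alpha <- alpha
    state$bray <- bray_curtis(ds$table)
    state$sorensen <- sorensen(ds$table)
    ord <- pcoa(state$sorensen, k = 2)
    groups <- setNames(ds$metadata$continent, ds$metadata$sample_id)
    kw <- kruskal_wallis_dunn(alpha$richness, groups[alpha$sample_id])
    files <- c(
      write_stage_csv_(alpha, dir, "alpha_diversity.csv"),
      { write_distance_matrix(state$bray, file.path(dir, "bray_curtis.tsv")) },
      { write_distance_matrix(state$sorensen, file.path(dir, "sorensen.tsv")) },
      write_stage_csv_(data.frame(sample_id = rownames(ord$coordinates),
                                  ord$coordinates), dir, "pcoa_coordinates.csv"),
      write_stage_csv_(data.frame(
        statistic = c("H", "df", "p_value"),
        value = c(kw$H, kw$df, kw$p_value)), dir, "kruskal_wallis_richness.csv"))
    files
  })

  run_stage("decay", function(dir, seed) {
    ds <- state$dataset
    state$geo <- geographic_distance_matrix(ds$metadata)
    groups <- setNames(ds$metadata$continent, ds$metadata$sample_id)
    fits <- distance_decay(state$bray, state$geo, groups,
                           n_perm = config$n_perm, seed = seed)
    c(write_distance_matrix(state$geo, file.path(dir, "geographic_km.tsv")),
      write_stage_csv_(fits, dir, "distance_decay.csv"))
  })

  run_stage("assembly", function(dir, seed) {
    ds <- state$dataset
    if (is.null(ds$tree))
      stop_("assembly stage requires a phylogenetic tree", class = "io_error")
    pairs <- assembly_pairs(ds$table, ds$tree, ds$metadata,
                            n_null = config$n_null, seed = seed,
                            weighted = config$weighted)
    groups <- setNames(ds$metadata$continent, ds$metadata$sample_id)
    frac <- process_fractions(pairs, groups)
    trend <- scale_trend(pairs, unit_km = config$unit_km,
                         min_pairs = config$min_pairs)
    ps <- pnst(ds$table, ds$tree, groups, n_null = config$n_null,
               seed = spawn_seeds_(seed, 3L)[[3L]], weighted = config$weighted)
    state$pairs <- pairs
    c(write_stage_csv_(pairs, dir, "assembly_pairs.csv"),
      write_stage_csv_(frac, dir, "process_fractions.csv"),
      write_stage_csv_(trend$units, dir, "scale_units.csv"),
      write_stage_csv_(trend$fits, dir, "scale_fits.csv"),
      write_stage_csv_(ps, dir, "pnst.csv"))
  })

  run_stage("drivers", function(dir, seed) {
    ds <- state$dataset
    seeds5 <- spawn_seeds_(seed, 5L)
    gl <- aggregate_to_glaciers(state$bray, ds$metadata)
    factors <- c("lat", "lon", "hdi", "u", "msr", "mmt", "tmp", "vp")
    mt <- mantel_factors(gl$dm, gl$metadata, factors,
                         n_perm = config$n_perm, seed = seeds5[[1L]])
    groups <- setNames(ds$metadata$continent, ds$metadata$sample_id)
    pmv <- permanova_test(state$bray, groups, n_perm = config$n_perm,
                          seed = seeds5[[2L]])
    ano <- anosim_test(state$bray, groups, n_perm = config$n_perm,
                       seed = seeds5[[3L]])
    db <- dbrda_fit(gl$dm, gl$metadata[, factors], n_perm = config$n_perm,
                    seed = seeds5[[4L]])
    rf <- rf_importance(db$site_scores[, 1L], gl$metadata[, factors],
                        seed = seeds5[[5L]])
    fits <- diversity_factor_fits(state$alpha, ds$metadata)
    summary_df <- data.frame(
      statistic = c("anosim_R", "anosim_p", "permanova_R2", "permanova_p",
                    "dbrda_constrained_prop", "dbrda_adj_R2", "dbrda_p",
                    "rf_R2", "richness_lat_R2", "richness_lat_vertex",
                    "richness_hdi_R2", "richness_hdi_slope"),
      value = c(ano$R, ano$p_value, pmv$r_squared, pmv$p_value,
                db$constrained_proportion, db$adj_r_squared, db$p_value,
                rf$r_squared, fits$latitude$r_squared, fits$latitude$vertex,
                fits$hdi$r_squared, fits$hdi$slope))
    c(write_stage_csv_(mt, dir, "mantel.csv"),
      write_stage_csv_(rf$importance, dir, "importance.csv"),
      write_stage_csv_(data.frame(sample_id = rownames(db$site_scores),
                                  db$site_scores), dir, "dbrda_axes.csv"),
      write_stage_csv_(summary_df, dir, "driver_summary.csv"))
  })

  manifest$output_md5 <- as.list(tools::md5sum(outputs[file.exists(outputs)]))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
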