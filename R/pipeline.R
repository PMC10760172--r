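# Configuration-driven orchestration of the full analysis:
# simulate/ingest -> prep -> select -> fit -> overlap -> test -> report.

#' Pipeline configuration
#'
#' Builds the nested configuration consumed by [run_pipeline()].  Exactly one
#' of `synthetic` (simulate the inputs) or `input` (read them from disk) must
#' be non-`NULL`.  Per-stage seeds are derived from `master_seed` with
#' [derive_seed()], so adding a stage never perturbs earlier stages'
#' randomness.
#'
#' The synthetic defaults describe a three-group hybrid-zone scenario at
#' desk scale: a 80 x 80 planar-km landscape with four spatially
#' autocorrelated continuous layers (pairwise correlation 0.3) and one
#' 5-class categorical layer, groups separated by 4 niche breadths, 1500 raw
#' records per group and a 4000-record all-species pool for target-group
#' background selection.
#'
#' @param synthetic Synthetic-scenario block (see defaults) or `NULL`.
#' @param input List with `occurrences` (CSV path; see [read_occurrences()])
#'   and `rasters` (directory; see [read_rasters()]) or `NULL`.
#' @param filter A [filter_config()].  The default drops the geographic
#'   bounding box because synthetic planar coordinates are in km.
#' @param thin A [thin_config()].
#' @param n_balance Records per group after balancing.
#' @param n_background Target-group background points.
#' @param vif List with `threshold` and `r_threshold`.
#' @param maxent List of maxent settings: `classes`, `beta_multiplier`,
#'   `n_replicates`, `test_fraction`, `max_iter`, `tolerance`.
#' @param test List with `n_iter` and `alpha` for the permutation tests.
#' @param master_seed Integer master seed.
#' @return A `pipeline_config` object.
#' @export
pipeline_config <- function(synthetic = list(), input = NULL,
                            filter = filter_config(bbox = NULL),
                            thin = thin_config(),
                            n_balance = 400, n_background = 1500,
                            vif = list(threshold = 10, r_threshold = 0.9),
                            maxent = list(classes = c("linear", "quadratic"),
                                          beta_multiplier = 1,
                                          n_replicates = 10,
                                          test_fraction = 0.2,
                                          max_iter = 500, tolerance = 1e-7),
                            test = list(n_iter = 100, alpha = 0.05),
                            master_seed = 1) {
  synth_default <- list(
    grid = list(n_rows = 80, n_cols = 80, origin_x = 0, origin_y = 0,
                cell_size = 1, crs = "planar"),
    layers = list(
      list(name = "env1", kind = "continuous", autocorr_length = 6),
      list(name = "env2", kind = "continuous", autocorr_length = 6),
      list(name = "env3", kind = "continuous", autocorr_length = 6),
      list(name = "env4", kind = "continuous", autocorr_length = 6),
      list(name = "landcover", kind = "categorical", autocorr_length = 8,
           n_classes = 5)),
    correlation_offdiag = 0.3,
    scenario = list(kind = "three_group", separation = 4, sigma = 1),
    n_per_group_raw = 1500,
    n_all_species = 4000,
    fail_fraction = 0.05,
    jitter = "uniform")
  if (!is.null(synthetic) && !is.null(input))
    stop("exactly one of `synthetic` or `input` must be given", call. = FALSE)
  if (is.null(synthetic) && is.null(input))
    stop("one of `synthetic` or `input` is required", call. = FALSE)
  if (!is.null(synthetic)) {
    layers_override <- synthetic$layers  # unnamed list: replace, never merge
    synthetic$layers <- NULL
    synthetic <- utils::modifyList(synth_default, synthetic)
    if (!is.null(layers_override)) synthetic$layers <- layers_override
  }
  structure(list(synthetic = synthetic, input = input, filter = filter,
                 thin = thin, n_balance = n_balance,
                 n_background = n_background, vif = vif, maxent = maxent,
                 test = test, master_seed = master_seed),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the arguments of [pipeline_config()]; unspecified
#' values keep their defaults.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  if (!is.null(y$synthetic)) args$synthetic <- y$synthetic
  if (!is.null(y$input)) { args$input <- y$input; args$synthetic <- NULL }
  if (!is.null(y$filter)) args$filter <- do.call(filter_config, y$filter)
  if (!is.null(y$thin)) args$thin <- do.call(thin_config, y$thin)
  for (k in c("n_balance", "n_background", "vif", "maxent", "test",
              "master_seed"))
    if (!is.null(y[[k]])) args[[k]] <- y[[k]]
  do.call(pipeline_config, args)
}

# Subset environmental columns, preserving the kind attribute.
env_subset <- function(env, vars) {
  out <- as.data.frame(env)[, vars, drop = FALSE]
  attr(out, "kind") <- env_kinds(env)[vars]
  out
}

.simulate_inputs <- function(cfg, log) {
  sy <- cfg$synthetic
  g <- sy$grid
  grid <- grid_spec(g$n_rows, g$n_cols, g$origin_x %||% 0, g$origin_y %||% 0,
                    g$cell_size %||% 1, g$crs %||% "planar")
  layers <- lapply(sy$layers, function(l)
    layer_spec(l$name, l$kind %||% "continuous", l$autocorr_length %||% 5,
               l$n_classes))
  k <- length(layers)
  corr <- matrix(sy$correlation_offdiag %||% 0, k, k); diag(corr) <- 1
  stack <- generate_landscape(grid, layers, corr,
                              seed = derive_seed(cfg$master_seed, "landscape"))
  sc <- sy$scenario
  cont_names <- vapply(Filter(function(l) l$kind == "continuous", layers),
                       `[[`, "", "name")
  cat_layers <- Filter(function(l) l$kind == "categorical", layers)
  scenario <- make_scenario(sc$kind, sc$separation %||% 0,
                            layer_names = cont_names, sigma = sc$sigma %||% 1)
  if (length(cat_layers)) {
    cw <- lapply(cat_layers, function(l)
      matrix(1, length(scenario$groups), l$n_classes,
             dimnames = list(scenario$groups, NULL)))
    names(cw) <- vapply(cat_layers, `[[`, "", "name")
    scenario <- niche_scenario(scenario$groups, scenario$optima,
                               scenario$breadths, class_weights = cw)
  }
  occ <- list()
  for (grp in scenario$groups) {
    suit <- gaussian_niche_suitability(scenario, grp, stack)
    tab <- sample_occurrences(suit, sy$n_per_group_raw, group = grp,
                              jitter = sy$jitter %||% "uniform",
                              seed = derive_seed(cfg$master_seed,
                                                 paste0("occ_", grp)))
    occ[[grp]] <- attach_checklist_metadata(
      tab, fail_fraction = sy$fail_fraction %||% 0,
      seed = derive_seed(cfg$master_seed, paste0("meta_", grp)))
  }
  # all-species pool: uniform over valid cells (survey effort, not niche)
  uni <- suitability_grid(grid, matrix(1, grid$n_rows, grid$n_cols),
                          mask = stack$mask)
  all_species <- sample_occurrences(uni, sy$n_all_species,
                                    group = "all_species",
                                    jitter = sy$jitter %||% "uniform",
                                    seed = derive_seed(cfg$master_seed,
                                                       "occ_all"))
  all_species <- attach_checklist_metadata(
    all_species, fail_fraction = sy$fail_fraction %||% 0,
    seed = derive_seed(cfg$master_seed, "meta_all"))
  log("simulate", sprintf("%d group(s) x %d raw records, %d all-species",
                          length(occ), sy$n_per_group_raw, sy$n_all_species))
  list(stack = stack, occ = occ, all_species = all_species,
       scenario = scenario)
}

.ingest_inputs <- function(cfg, log) {
  stack <- read_rasters(cfg$input$rasters)
  cs <- if (stack$grid$crs == "lonlat") "lonlat" else "planar"
  tab <- read_occurrences(cfg$input$occurrences, coord_system = cs)
  occ <- lapply(split(seq_len(nrow(tab)), tab$group),
                function(i) occ_rebuild(tab[i, , drop = FALSE], tab))
  all_species <- if (!is.null(cfg$input$all_species))
    read_occurrences(cfg$input$all_species, coord_system = cs) else NULL
  if (is.null(all_species))
    stop("`input$all_species` is required for background selection",
         call. = FALSE)
  log("ingest", sprintf("%d records in %d group(s)", nrow(tab), length(occ)))
  list(stack = stack, occ = occ, all_species = all_species, scenario = NULL)
}

#' Run the full niche-divergence analysis
#'
#' Executes every stage for each group: occurrence simulation (or ingestion),
#' checklist filtering, spatial thinning, balancing, target-group background
#' selection, VIF variable selection, maxent fitting with replicated AUC
#' validation and variable importance, pairwise niche-overlap statistics, and
#' pairwise identity and blob range-breaking permutation tests.  The run is a
#' pure function of the configuration (identical master seed, identical
#' report).
#'
#' @param config A [pipeline_config()].
#' @param outdir Optional output directory; when given, the report JSON,
#'   occurrence CSVs and suitability maps (ESRI ASCII) are written there.
#' @return A `run_report` list with per-stage counts, retained variables and
#'   VIFs, per-group AUC summaries and importances, pairwise overlaps and
#'   permutation-test results.
#' @export
run_pipeline <- function(config, outdir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  logs <- list()
  log <- function(stage, msg) {
    logs[[length(logs) + 1]] <<- list(stage = stage, message = msg)
    message(sprintf("[%s] %s", stage, msg))
  }
  stage <- "init"
  result <- tryCatch({
    stage <- if (is.null(config$input)) "simulate" else "ingest"
    inputs <- if (is.null(config$input)) .simulate_inputs(config, log)
              else .ingest_inputs(config, log)
    stack <- inputs$stack
    groups <- names(inputs$occ)

    stage <- "prep"
    prep_counts <- list()
    filtered <- list()
    for (grp in c(groups, ".all_species")) {
      tab <- if (grp == ".all_species") inputs$all_species else inputs$occ[[grp]]
      f <- filter_records(tab, config$filter)
      rej <- attr(f, "rejections")
      th_cfg <- config$thin
      th_cfg$seed <- derive_seed(config$master_seed, paste0("thin_", grp))
      t <- thin_spatial(f, th_cfg)
      prep_counts[[grp]] <- list(input = nrow(tab), filtered = nrow(f),
                                 rejected = as.list(rej), thinned = nrow(t))
      filtered[[grp]] <- t
      log("prep", sprintf("%s: %d -> %d filtered -> %d thinned",
                          grp, nrow(tab), nrow(f), nrow(t)))
    }
    all_species <- filtered$.all_species
    filtered$.all_species <- NULL
    balanced <- balance_groups(filtered, config$n_balance,
                               seed = derive_seed(config$master_seed,
                                                  "balance"))
    background <- target_group_background(
      all_species, config$n_background,
      seed = derive_seed(config$master_seed, "background"))
    log("prep", sprintf("balanced to %d per group; %d background points",
                        config$n_balance, config$n_background))

    stage <- "select"
    by_group <- split(seq_len(nrow(balanced)), balanced$group)
    env_pool <- extract_env(stack, balanced)
    sel <- select_variables(env_pool, config$vif$threshold %||% 10,
                            config$vif$r_threshold %||% 0.9)
    log("select", paste("retained:", paste(sel$retained, collapse = ", ")))

    stage <- "enm"
    env_bg <- env_subset(extract_env(stack, background), sel$retained)
    sub_stack <- raster_stack(stack$grid, stack$layers[sel$retained],
                              kind = stack$kind[sel$retained],
                              mask = stack$mask)
    mx <- config$maxent
    enm <- list(); maps <- list()
    for (grp in groups) {
      occ_grp <- occ_rebuild(balanced[by_group[[grp]], , drop = FALSE],
                             balanced)
      env_p <- env_subset(extract_env(stack, occ_grp), sel$retained)
      feats <- build_features(env_p, env_bg,
                              classes = mx$classes %||% c("linear", "quadratic"))
      ev <- crossvalidate(feats, mx$n_replicates %||% 10,
                          mx$test_fraction %||% 0.2,
                          mx$beta_multiplier %||% 1,
                          mx$max_iter %||% 500, mx$tolerance %||% 1e-7,
                          seed = derive_seed(config$master_seed,
                                             paste0("cv_", grp)))
      fit <- fit_maxent(feats, mx$beta_multiplier %||% 1,
                        mx$max_iter %||% 500, mx$tolerance %||% 1e-7)
      contrib <- percent_contribution(fit)
      perm <- permutation_importance(fit, feats,
                                     seed = derive_seed(config$master_seed,
                                                        paste0("imp_", grp)))
      maps[[grp]] <- predict_suitability(fit, sub_stack, output = "raw")
      enm[[grp]] <- list(auc = list(mean = ev$mean, sd = ev$sd,
                                    replicates = ev$auc),
                         converged = fit$converged, gain = fit$gain,
                         percent_contribution = as.list(contrib),
                         permutation_importance = as.list(perm))
      log("enm", sprintf("%s: mean AUC %.3f (SD %.3f), gain %.3f",
                         grp, ev$mean, ev$sd, fit$gain))
    }

    stage <- "overlap"
    pairs <- utils::combn(groups, 2)
    overlaps <- list()
    for (j in seq_len(ncol(pairs))) {
      a <- pairs[1, j]; b <- pairs[2, j]
      ov <- overlap_stats(maps[[a]], maps[[b]])
      overlaps[[paste(a, b, sep = "_vs_")]] <- ov
      log("overlap", sprintf("%s vs %s: D = %.3f, I = %.3f", a, b, ov$D, ov$I))
    }

    stage <- "test"
    tests <- list()
    for (j in seq_len(ncol(pairs))) {
      a <- pairs[1, j]; b <- pairs[2, j]
      occ_a <- occ_rebuild(balanced[by_group[[a]], , drop = FALSE], balanced)
      occ_b <- occ_rebuild(balanced[by_group[[b]], , drop = FALSE], balanced)
      for (kind in c("identity", "blob")) {
        tcfg <- test_config(
          n_iter = config$test$n_iter %||% 100,
          alpha = config$test$alpha %||% 0.05,
          seed = derive_seed(config$master_seed,
                             paste0(kind, "_", a, "_", b)),
          beta_multiplier = mx$beta_multiplier %||% 1,
          classes = mx$classes %||% c("linear", "quadratic"),
          max_iter = mx$max_iter %||% 500,
          tolerance = mx$tolerance %||% 1e-7)
        res <- if (kind == "identity")
          identity_test(occ_a, occ_b, sub_stack, background, tcfg)
        else blob_range_break_test(occ_a, occ_b, sub_stack, background, tcfg)
        tests[[paste(kind, a, b, sep = "_")]] <- list(
          kind = kind, groups = c(a, b), observed = res$observed,
          p = res$p, n_excluded = res$n_excluded,
          null = list(D = res$null$D, I = res$null$I))
        log("test", sprintf("%s %s vs %s: D = %.3f (p_lower = %.3f)",
                            kind, a, b, res$observed$D,
                            res$p$D[["lower"]]))
      }
    }

    stage <- "report"
    report <- list(
      package = "nichekit",
      version = as.character(utils::packageVersion("nichekit")),
      master_seed = config$master_seed,
      groups = groups,
      counts = prep_counts,
      balanced_per_group = config$n_balance,
      n_background = config$n_background,
      variable_selection = list(
        retained = sel$retained,
        vifstep = if (!is.null(sel$step)) list(
          retained = sel$step$retained, dropped = sel$step$dropped,
          vif = as.list(sel$step$vif)) else NULL,
        vifcor = if (!is.null(sel$cor)) list(
          retained = sel$cor$retained, dropped = sel$cor$dropped,
          vif = as.list(sel$cor$vif)) else NULL),
      enm = enm,
      overlap = overlaps,
      tests = tests,
      config = list(
        filter = unclass(config$filter), thin = unclass(config$thin),
        n_balance = config$n_balance, n_background = config$n_background,
        vif = config$vif, maxent = config$maxent, test = config$test,
        synthetic = config$synthetic),
      log = logs)
    class(report) <- "run_report"
    if (!is.null(outdir)) {
      if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
      write_run_report(report, file.path(outdir, "report.json"))
      write_occurrences(balanced, file.path(outdir, "occurrences_balanced.csv"))
      for (grp in groups)
        write_asc(maps[[grp]]$values, stack$grid,
                  file.path(outdir, paste0("suitability_", grp, ".asc")),
                  mask = stack$mask)
    }
    report
  }, error = function(e) {
    stop(sprintf("pipeline failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  result
}

#' Write a run report as JSON
#'
#' Deterministic serialization: the same report always produces the same
#' bytes.
#'
#' @param report A `run_report` from [run_pipeline()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_run_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = 10,
                       pretty = TRUE, force = TRUE, null = "null")
  invisible(path)
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> nichekit %s, master seed %s\n", x$version,
              x$master_seed))
  cat("groups:", paste(x$groups, collapse = ", "), "\n")
  for (nm in names(x$overlap))
    cat(sprintf("  %s: D = %.3f, I = %.3f\n", nm, x$overlap[[nm]]$D,
                x$overlap[[nm]]$I))
  for (nm in names(x$tests))
    cat(sprintf("  %s: p_lower(D) = %.3f\n", nm, x$tests[[nm]]$p$D[["lower"]]))
  invisible(x)
}
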