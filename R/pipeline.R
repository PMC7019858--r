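#' Assemble a pipeline configuration
#'
#' The pipeline chains the analysis stages in dependency order:
#' `simulate` (synthetic panel, weather, scorings, genotypes) ->
#' `canopy` (senescence fits and canopy traits) -> `blues` (mixed model,
#' adjusted means, heritability) -> `progress` (sliding-window gain) ->
#' `gwas` (QC, kinship, structure, scan). Stages can be toggled; disabled
#' upstream stages require their input files to exist already.
#'
#' @param out_dir output directory (created if absent).
#' @param stages character subset of
#'   `c("simulate", "canopy", "blues", "progress", "gwas")`.
#' @param seed integer root seed for the stochastic stages.
#' @param panel a [panel_config()] (simulate stage).
#' @param geno a [geno_sim_config()] or `NULL` to skip genotype simulation.
#' @param canopy_trait trait carrying canopy duration (simulate/canopy).
#' @param scoring_noise_sd visual-score noise (percent points).
#' @param window_size,year_start,year_end,segmented progress-stage options.
#' @param gwas_trait,alpha,fdr_rate,k_groups,max_missing,min_maf
#'   association-stage options.
#' @param files named list of input file paths for stages whose upstream
#'   stage is disabled (`phenotypes`, `weather`, `scorings`, `genotypes`,
#'   `map`, `blues`).
#' @param log_level one of DEBUG/INFO/WARNING/ERROR.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir,
                            stages = c("simulate", "canopy", "blues",
                                       "progress", "gwas"),
                            seed = 1L,
                            panel = panel_config(seed = seed),
                            geno = geno_sim_config(seed = seed),
                            canopy_trait = "gcd",
                            scoring_noise_sd = 5,
                            window_size = 10L,
                            year_start = 1970, year_end = 2010,
                            segmented = FALSE,
                            gwas_trait = "gcd",
                            alpha = 0.05, fdr_rate = 0.10, k_groups = 5L,
                            max_missing = 0.10, min_maf = 0.05,
                            files = list(),
                            log_level = "INFO") {
  stages <- match.arg(stages, several.ok = TRUE)
  structure(list(out_dir = out_dir, stages = stages, seed = as.integer(seed),
                 panel = panel, geno = geno, canopy_trait = canopy_trait,
                 scoring_noise_sd = scoring_noise_sd,
                 window_size = window_size,
                 year_start = year_start, year_end = year_end,
                 segmented = segmented, gwas_trait = gwas_trait,
                 alpha = alpha, fdr_rate = fdr_rate, k_groups = k_groups,
                 max_missing = max_missing, min_maf = min_maf,
                 files = files, log_level = log_level),
            class = "pipeline_config")
}

#' @noRd
pipe_path <- function(cfg, name) file.path(cfg$out_dir, name)

#' @noRd
pipe_input <- function(cfg, key, default_name) {
  cfg$files[[key]] %||% pipe_path(cfg, default_name)
}

#' Run the analysis pipeline
#'
#' Executes the enabled stages in dependency order, writes every output
#' with a JSON manifest (stage inputs, parameters, seed, package version),
#' and halts with the stage name on failure. Reruns with the same
#' configuration are bit-identical for the deterministic stages.
#'
#' @param config a [pipeline_config()] or path to a JSON file accepted by
#'   [read_config()].
#' @return invisibly, a named list of per-stage outputs.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- config_from_list(read_config(config))
  stopifnot(inherits(config, "pipeline_config"))
  cfg <- config
  old <- options(staygreen.log_level = cfg$log_level)
  on.exit(options(old))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)

  # pre-flight: inputs for stages whose producer is disabled must exist
  preflight <- list(
    canopy = c("scorings", "weather"),
    blues = "phenotypes",
    progress = "blues",
    gwas = c("blues", "genotypes", "map"))
  producers <- list(scorings = "simulate", weather = "simulate",
                    phenotypes = "simulate", genotypes = "simulate",
                    map = "simulate", blues = "blues")
  defaults <- c(scorings = "scorings.csv", weather = "weather.csv",
                phenotypes = "phenotypes.csv", genotypes = "genotypes.tsv",
                map = "marker_map.csv", blues = "blues.csv")
  for (st in cfg$stages) {
    for (key in preflight[[st]]) {
      if (!(producers[[key]] %in% cfg$stages)) {
        p <- pipe_input(cfg, key, defaults[[key]])
        if (!file.exists(p)) {
          stop_sg("stage '%s' needs input '%s' but %s does not exist",
                  st, key, p)
        }
      }
    }
  }

  results <- list()
  manifest <- list(package = "staygreen",
                   version = as.character(packageVersion("staygreen")),
                   seed = cfg$seed, stages = list())
  run_stage <- function(name, fun) {
    sg_log("INFO", name, "stage started")
    out <- tryCatch(fun(), error = function(e) {
      stop_sg("stage '%s' failed: %s", name, conditionMessage(e))
    })
    sg_log("INFO", name, "stage finished")
    out
  }

  if ("simulate" %in% cfg$stages) {
    results$simulate <- run_stage("simulate", function() {
      panel <- simulate_panel(cfg$panel)
      geno <- NULL
      if (!is.null(cfg$geno)) {
        geno <- simulate_genotypes(cfg$geno, panel)
        if (length(attr(geno, "truth")$causal_markers) > 0L) {
          panel <- apply_causal_effect(panel, geno)
        }
        write_genotypes(geno, pipe_path(cfg, "genotypes.tsv"),
                        pipe_path(cfg, "marker_map.csv"))
      }
      weather <- simulate_weather(seed = cfg$seed)
      write_weather(weather, pipe_path(cfg, "weather.csv"))
      truths <- simulate_senescence_truths(panel, trait = cfg$canopy_trait,
                                           seed = cfg$seed)
      scorings <- simulate_scoring_table(panel, truths,
                                         trait = cfg$canopy_trait,
                                         noise_sd = cfg$scoring_noise_sd,
                                         seed = cfg$seed)
      write_phenotypes(panel, pipe_path(cfg, "phenotypes.csv"))
      write.csv(scorings$scorings, pipe_path(cfg, "scorings.csv"),
                row.names = FALSE, quote = FALSE)
      write.csv(scorings$plot_info, pipe_path(cfg, "plot_info.csv"),
                row.names = FALSE, quote = FALSE)
      manifest$stages$simulate <<- list(
        n_cultivars = cfg$panel$n_cultivars,
        n_markers = if (is.null(cfg$geno)) 0L else cfg$geno$n_markers,
        outputs = c("phenotypes.csv", "weather.csv", "scorings.csv",
                    "plot_info.csv",
                    if (!is.null(cfg$geno)) c("genotypes.tsv",
                                              "marker_map.csv")))
      list(panel = panel, geno = geno, truths = truths)
    })
  }

  if ("canopy" %in% cfg$stages) {
    results$canopy <- run_stage("canopy", function() {
      scorings <- read.csv(pipe_input(cfg, "scorings", "scorings.csv"),
                           stringsAsFactors = FALSE)
      plot_info <- read.csv(pipe_input(cfg, "plot_info", "plot_info.csv"),
                            stringsAsFactors = FALSE)
      ct <- canopy_trait_table(scorings, plot_info)
      ct <- merge(plot_info[c("plot", "cultivar", "season", "rep",
                              "subgroup")], ct, by = "plot")
      write.csv(ct, pipe_path(cfg, "canopy_traits.csv"), row.names = FALSE,
                quote = FALSE)
      manifest$stages$canopy <<- list(
        n_plots = nrow(ct), n_converged = sum(ct$converged),
        outputs = "canopy_traits.csv")
      ct
    })
  }

  if ("blues" %in% cfg$stages) {
    results$blues <- run_stage("blues", function() {
      phen <- read_phenotypes(pipe_input(cfg, "phenotypes",
                                         "phenotypes.csv"))
      if ("canopy" %in% cfg$stages && !is.null(results$canopy)) {
        # replace the directly-simulated canopy trait by the curve-fitted one
        ct <- results$canopy
        ok <- ct$converged & !is.na(ct$gcd)
        extra <- data.frame(cultivar = ct$cultivar[ok],
                            season = as.character(ct$season[ok]),
                            rep = ct$rep[ok], subgroup = ct$subgroup[ok],
                            trait = cfg$canopy_trait, value = ct$gcd[ok],
                            stringsAsFactors = FALSE)
        yr <- phen$year_of_release[match(extra$cultivar, phen$cultivar)]
        extra$year_of_release <- yr
        phen <- phen[phen$trait != cfg$canopy_trait, ]
        phen <- rbind(phen[names(extra)], extra)
      }
      traits <- unique(phen$trait)
      blues <- NULL
      vc_rows <- NULL
      for (tr in traits) {
        m <- fit_mixed_model(phen, tr)
        b <- estimate_blues(m, by = "both")
        blues <- rbind(blues, b)
        vc <- variance_components(phen, tr)
        h2 <- heritability(vc)
        vc_rows <- rbind(vc_rows,
                         data.frame(trait = tr, sigma2_C = vc[["C"]],
                                    sigma2_CY = vc[["CY"]],
                                    sigma2_e = vc[["e"]], H2 = h2,
                                    n_env = attr(vc, "n_env"),
                                    n_reps = attr(vc, "n_reps")))
      }
      write_blues(blues, pipe_path(cfg, "blues.csv"))
      write.csv(vc_rows, pipe_path(cfg, "variance_components.csv"),
                row.names = FALSE, quote = FALSE)
      manifest$stages$blues <<- list(
        traits = traits, outputs = c("blues.csv",
                                     "variance_components.csv"))
      list(blues = blues, varcomp = vc_rows)
    })
  }

  if ("progress" %in% cfg$stages) {
    results$progress <- run_stage("progress", function() {
      blues <- if (!is.null(results$blues)) {
        results$blues$blues
      } else {
        read_blues(pipe_input(cfg, "blues", "blues.csv"))
      }
      rep_tab <- progress_report(blues, window_size = cfg$window_size,
                                 year_start = cfg$year_start,
                                 year_end = cfg$year_end,
                                 segmented = cfg$segmented)
      write.csv(rep_tab, pipe_path(cfg, "progress_report.csv"),
                row.names = FALSE, quote = FALSE)
      ws_all <- NULL
      for (tr in rep_tab$trait) {
        ws <- sliding_window(blues, trait = tr,
                             window_size = cfg$window_size)
        ws_all <- rbind(ws_all,
                        data.frame(trait = tr,
                                   ws[c("window", "mean_year", "mean",
                                        "sd")]))
      }
      write.csv(ws_all, pipe_path(cfg, "window_series.csv"),
                row.names = FALSE, quote = FALSE)
      manifest$stages$progress <<- list(
        window_size = cfg$window_size,
        outputs = c("progress_report.csv", "window_series.csv"))
      rep_tab
    })
  }

  if ("gwas" %in% cfg$stages) {
    results$gwas <- run_stage("gwas", function() {
      blues <- if (!is.null(results$blues)) {
        results$blues$blues
      } else {
        read_blues(pipe_input(cfg, "blues", "blues.csv"))
      }
      geno <- if (!is.null(results$simulate$geno)) {
        results$simulate$geno
      } else {
        read_genotypes(pipe_input(cfg, "genotypes", "genotypes.tsv"),
                       pipe_input(cfg, "map", "marker_map.csv"))
      }
      gq <- marker_qc(geno, cfg$max_missing, cfg$min_maf)
      K <- kinship(gq)
      ps <- population_structure(gq, k = cfg$k_groups, seed = cfg$seed)
      res <- association_scan(blues, gq, K, ps, trait = cfg$gwas_trait)
      thr <- significance_thresholds(sum(!is.na(res$p_value)),
                                     alpha = cfg$alpha,
                                     fdr_rate = cfg$fdr_rate,
                                     pvalues = res$p_value)
      write_association(res, pipe_path(cfg, "association_results.csv"))
      qc_rep <- attr(gq, "qc_report")
      jsonlite::write_json(
        list(qc = qc_rep,
             thresholds = list(bonferroni_p = thr$bonferroni_p,
                               bonferroni_log10 = thr$bonferroni_log10,
                               fdr_cutoff_p = thr$fdr_cutoff_p,
                               n_rejected_fdr = thr$n_rejected_fdr)),
        pipe_path(cfg, "gwas_summary.json"), auto_unbox = TRUE,
        digits = NA, pretty = TRUE)
      manifest$stages$gwas <<- list(
        trait = cfg$gwas_trait, n_markers = nrow(res),
        outputs = c("association_results.csv", "gwas_summary.json"))
      list(result = res, thresholds = thr, qc = qc_rep, structure = ps)
    })
  }

  manifest$config <- config_to_list(cfg)
  jsonlite::write_json(manifest, pipe_path(cfg, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(results)
}

#' Simulate the visual scoring table for every plot of a panel
#'
#' One scoring course per cultivar x season x replicate, at a fortnightly
#' thermal-time cadence bracketing the cultivar's senescence window, on
#' top of the cultivar's true curve (per-plot canopy-duration deviations
#' from the panel's planted G x E and residual draws are reflected by
#' shifting GLA50 accordingly).
#'
#' @param panel a [simulate_panel()] table.
#' @param truths a [simulate_senescence_truths()] table.
#' @param trait canopy-duration trait name in the panel.
#' @param noise_sd scoring noise (percent points).
#' @param seed integer seed.
#' @return list with `scorings` (`plot`, `tt`, `green_pct`) and
#'   `plot_info` (`plot`, `cultivar`, `season`, `rep`, `subgroup`,
#'   `tt_heading`, `tt_harvest`, `lai_max`, `gla50_true`).
#' @export
simulate_scoring_table <- function(panel, truths, trait = "gcd",
                                   noise_sd = 5, seed = 1L) {
  rows <- panel[panel$trait == trait, , drop = FALSE]
  if (nrow(rows) == 0L) stop_sg("trait '%s' not in panel", trait)
  ti <- match(rows$cultivar, truths$cultivar)
  # per-plot gla50: heading TT plus the plot's realised canopy duration
  gla50 <- truths$tt_heading[ti] + rows$value
  plot_id <- sprintf("%s_%s_%s", rows$cultivar, rows$season, rows$rep)
  tts <- seq(0.55, 1.45, by = 0.1) # scoring grid relative to true GLA50
  noise <- with_stream(seed, "scoring_noise",
                       matrix(rnorm(length(plot_id) * length(tts), 0,
                                    noise_sd), ncol = length(tts)))
  sc <- lapply(seq_along(plot_id), function(i) {
    tt <- gla50[i] * tts
    y <- senescence_curve(tt, gla50[i], truths$s[ti[i]])
    data.frame(plot = plot_id[i], tt = tt,
               green_pct = pmin(pmax(y + noise[i, ], 0), 100),
               stringsAsFactors = FALSE)
  })
  scorings <- do.call(rbind, sc)
  plot_info <- data.frame(plot = plot_id, cultivar = rows$cultivar,
                          season = rows$season, rep = rows$rep,
                          subgroup = rows$subgroup,
                          tt_heading = truths$tt_heading[ti],
                          tt_harvest = truths$tt_heading[ti] + 900,
                          lai_max = truths$lai_max[ti],
                          gla50_true = gla50, stringsAsFactors = FALSE)
  list(scorings = scorings, plot_info = plot_info)
}

#' @noRd
config_to_list <- function(cfg) {
  out <- unclass(cfg)
  pl <- unclass(out$panel)
  # named vectors must become JSON objects, not arrays, to keep their names
  pl$trait_means <- as.list(pl$trait_means)
  pl$trait_slopes <- as.list(pl$trait_slopes)
  pl$var_components <- lapply(pl$var_components, as.list)
  out$panel <- pl
  if (!is.null(out$geno)) out$geno <- unclass(out$geno)
  out
}

#' @noRd
config_from_list <- function(lst) {
  unlist_fields <- function(x, fields) {
    for (f in intersect(fields, names(x))) x[[f]] <- unlist(x[[f]])
    x
  }
  panel <- if (!is.null(lst$panel)) {
    pl <- unlist_fields(lst$panel, c("trait_means", "trait_slopes",
                                     "release_span", "chromosomes"))
    pl$var_components <- lapply(pl$var_components, unlist)
    if (!is.null(pl$season_effects)) {
      pl$season_effects <- lapply(pl$season_effects, unlist)
    }
    do.call(panel_config, pl)
  }
  geno <- if (!is.null(lst$geno)) {
    gl <- unlist_fields(lst$geno, c("maf_range", "chromosomes"))
    if (!is.null(gl$causal_region)) {
      gl$causal_region <- lapply(gl$causal_region, unlist)
    }
    do.call(geno_sim_config, gl)
  }
  args <- lst[setdiff(names(lst), c("panel", "geno"))]
  args <- unlist_fields(args, "stages")
  if (!is.null(args$files)) args$files <- as.list(args$files)
  args$panel <- panel %||% panel_config(seed = lst$seed %||% 1L)
  args$geno <- geno
  do.call(pipeline_config, args)
}
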