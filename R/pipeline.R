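## End-to-end orchestration: configuration, staged execution, deterministic
## text outputs, and the paired ITC-like / HC-like demo.

PIPELINE_STAGES <- c("simulate", "screen", "assemble", "vigor", "decode",
                     "fit_tuning", "threshold_sweep", "plane")

#' Pipeline run configuration
#'
#' Bundles the seed, region setup, problem sizes, analysis windows and
#' resampling counts for [run_pipeline()]. Stage toggles must be
#' prefix-closed: every stage consumes the outputs of the previous ones.
#'
#' @param seed Root seed; all stage randomness derives from it.
#' @param region `"ITC-like"` or `"HC-like"` (selects [itc_config()] /
#'   [hc_config()]).
#' @param n_images,n_units Problem sizes.
#' @param nback_levels,nback_core n-back targets (see [nback_spec()]); the
#'   core count defaults to a feasible fraction of `n_images`.
#' @param mb_bins Memorability bins for pseudopopulation alignment.
#' @param vigor_window,decode_window,plane_window Analysis windows in ms.
#' @param n_folds,n_perm,n_boot Resampling controls.
#' @param theta_step Rotation-sweep resolution in degrees.
#' @param stages Which pipeline stages to run (prefix of the full list).
#' @return A `run_config` list.
#' @export
run_config <- function(seed = 1, region = "ITC-like", n_images = 120,
                       n_units = 120,
                       nback_levels = c(1, 2, 4, 8, 16, 32),
                       nback_core = NULL, mb_bins = 10,
                       vigor_window = c(300, 500),
                       decode_window = c(300, 500),
                       plane_window = c(100, 500),
                       n_folds = 5, n_perm = 1000, n_boot = 500,
                       theta_step = 2, stages = PIPELINE_STAGES) {
  if (!all(stages %in% PIPELINE_STAGES)) abort("unknown stage name.")
  nback_core <- nback_core %null%
    max(2, floor(0.75 * n_images / max(1, length(nback_levels) - 1)))
  stages <- PIPELINE_STAGES[PIPELINE_STAGES %in% stages]
  if (!identical(stages, PIPELINE_STAGES[seq_along(stages)])) {
    abort("stages must form a prefix of the pipeline (each stage feeds the next).")
  }
  structure(
    list(seed = seed, region = region, n_images = n_images, n_units = n_units,
         nback_levels = nback_levels, nback_core = nback_core,
         mb_bins = mb_bins, vigor_window = vigor_window,
         decode_window = decode_window, plane_window = plane_window,
         n_folds = n_folds, n_perm = n_perm, n_boot = n_boot,
         theta_step = theta_step, stages = stages),
    class = "run_config"
  )
}

config_hash <- function(config) rlang::hash(unclass_config(config))

region_from_name <- function(name) {
  switch(name, "ITC-like" = itc_config(), "HC-like" = hc_config(),
         abort(sprintf("unknown region '%s'", name)))
}

#' Run the full simulation-and-analysis pipeline
#'
#' Executes simulate, screen, assemble, vigor, decode, tuning-fit,
#' threshold-sweep and plane stages on seeded synthetic data, writing CSV
#' and JSON outputs (each carrying the config hash) into `out_dir`.
#' Identical config and seed yield byte-identical outputs. Only the stages
#' toggled in the config run; they must form a prefix of the pipeline.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if missing). `NULL` skips file
#'   output and returns results only.
#' @return Invisibly, a named list of stage results plus `summary`.
#' @export
run_pipeline <- function(config = run_config(), out_dir = NULL) {
  hash <- config_hash(config)
  seed <- config$seed
  res <- list(config = config, hash = hash)
  want <- function(s) s %in% config$stages
  emit <- function(x, name) {
    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      readr::write_csv(dplyr::mutate(tibble::as_tibble(x), config_hash = hash),
                       file.path(out_dir, paste0(name, ".csv")))
    }
  }

  stage <- function(name, code) {
    tryCatch(code, error = function(e) {
      abort(sprintf("stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }

  finish <- function(res) {
    res$summary <- pipeline_summary(res)
    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      jsonlite::write_json(res$summary, file.path(out_dir, "summary.json"),
                           auto_unbox = TRUE, digits = NA)
      write_config_yaml(config, file.path(out_dir, "config.yaml"))
    }
    invisible(res)
  }

  # -- simulate ------------------------------------------------------------
  if (!want("simulate")) return(finish(res))
  rc <- region_from_name(config$region)
  res$simulate <- stage("simulate", {
    images <- gen_images(config$n_images, seed = seed)
    sequence <- gen_sequence(
      images,
      nback_spec(config$nback_levels, core_count = config$nback_core),
      seed = seed)
    units <- gen_units(rc, config$n_units, images, seed = seed)
    session <- simulate_session(units, sequence, images, rc, seed = seed)
    choices <- simulate_behavior(sequence, images, seed = seed)
    list(images = images, sequence = sequence, units = units,
         session = session, choices = choices)
  })
  emit(res$simulate$images, "images")
  emit(res$simulate$choices, "trials")

  # -- screen --------------------------------------------------------------
  if (!want("screen")) return(finish(res))
  res$screen <- stage("screen", {
    resp <- responsiveness_filter(res$simulate$session)
    stab <- stability_filter(res$simulate$session)
    session <- apply_screen(res$simulate$session, resp)
    inform(sprintf("screen: %d/%d units responsive; session %s",
                   sum(resp$include), nrow(resp),
                   if (stab$stable) "stable" else "UNSTABLE"))
    list(responsiveness = resp, stability = stab, session = session)
  })
  emit(res$screen$responsiveness, "screen_responsiveness")
  if (!is.null(out_dir)) {
    write_screen_json(res$screen$responsiveness,
                      file.path(out_dir, "screen_report.json"))
  }

  # -- assemble ------------------------------------------------------------
  if (!want("assemble")) return(finish(res))
  res$assemble <- stage("assemble", {
    assemble_pseudopopulation(res$screen$session, mb_bins = config$mb_bins,
                              seed = seed)
  })

  pop <- res$assemble

  # -- vigor ---------------------------------------------------------------
  if (!want("vigor")) return(finish(res))
  res$vigor <- stage("vigor", {
    tb <- gmfr(pop, window = config$vigor_window)
    list(
      gmfr = tb,
      cor_novel = memorability_correlation(tb, "novel"),
      cor_repeated = memorability_correlation(tb, "repeated"),
      reg_novel = gmfr_regression(tb, "novel"),
      reg_repeated = gmfr_regression(tb, "repeated"),
      suppression = suppression_stats(tb),
      scaling = suppression_scaling(tb, n_boot = config$n_boot, seed = seed)
    )
  })
  emit(res$vigor$gmfr, "gmfr")

  # -- decode --------------------------------------------------------------
  if (!want("decode")) return(finish(res))
  res$decode <- stage("decode", {
    list(
      dprime = unit_dprime(pop, window = config$decode_window),
      fld = cv_performance(pop, "fld", window = config$decode_window,
                           n_folds = config$n_folds, seed = seed,
                           shuffle_alignment_flag = TRUE),
      rs = cv_performance(pop, "rs", window = config$decode_window,
                          n_folds = config$n_folds, seed = seed)
    )
  })
  emit(res$decode$dprime, "dprime")
  emit(res$decode$fld, "cv_fld")

  # -- fit_tuning ----------------------------------------------------------
  if (!want("fit_tuning")) return(finish(res))
  res$fit_tuning <- stage("fit_tuning", fit_tuning(pop, window = config$plane_window))
  emit(dplyr::select(res$fit_tuning, "unit_id", "a_novel", "a_repeated",
                     "alpha", "converged"), "tuning_fits")

  # -- threshold_sweep -----------------------------------------------------
  if (!want("threshold_sweep")) return(finish(res))
  res$threshold_sweep <- stage("threshold_sweep", {
    threshold_sweep(res$fit_tuning, fractions = seq(0, 1, by = 0.1),
                    n_folds = config$n_folds, n_boot = config$n_boot,
                    seed = seed)
  })
  emit(res$threshold_sweep, "threshold_sweep")

  # -- plane ---------------------------------------------------------------
  if (!want("plane")) return(finish(res))
  res$plane <- stage("plane", {
    behav <- behavior_by_quartile(
      dplyr::semi_join(res$simulate$choices,
                       tibble::tibble(image_id = unlist(pop$pseudoimages$images)),
                       by = "image_id"),
      res$simulate$images)
    theta_sweep(pop, behav,
                theta = seq(0, 179, by = config$theta_step),
                window = config$plane_window, n_folds = config$n_folds,
                seed = seed)
  })
  emit(dplyr::select(res$plane, "theta", "pq_novel", "pq_repeated", "pq",
                     "accuracy"), "theta_sweep")

  finish(res)
}

pipeline_summary <- function(res) {
  s <- list(config_hash = res$hash, region = res$config$region,
            seed = res$config$seed)
  if (!is.null(res$vigor)) {
    s$cor_repeated_r <- res$vigor$cor_repeated$r
    s$cor_novel_r <- res$vigor$cor_novel$r
    s$slope_repeated <- res$vigor$reg_repeated$slope
    s$slope_novel <- res$vigor$reg_novel$slope
    s$mean_suppression_percent <- res$vigor$suppression$mean_percent
    s$suppression_exponent <- res$vigor$scaling$exponent
  }
  if (!is.null(res$decode)) {
    s$fld_accuracy <- mean(res$decode$fld$accuracy)
    s$rs_accuracy <- mean(res$decode$rs$accuracy)
  }
  if (!is.null(res$plane)) {
    s$best_theta <- attr(res$plane, "best_theta")
    s$best_pq <- max(res$plane$pq)
    s$gamma <- attr(res$plane, "gamma")
  }
  s
}

#' Paired ITC-like / HC-like demo run
#'
#' Runs the pipeline once per region on a shared seed, then compares the
#' memorability-vs-GMFR slopes between the two regions with the permutation
#' slope test.
#'
#' @param seed Root seed.
#' @param out_dir Optional output directory (per-region subdirectories).
#' @param n_images,n_units Problem sizes shared by both regions.
#' @param n_perm Permutations for the slope-difference test.
#' @return List with both runs and a `comparison` summary.
#' @export
run_demo <- function(seed = 1, out_dir = NULL, n_images = 120, n_units = 120,
                     n_perm = 1000) {
  runs <- lapply(c("ITC-like", "HC-like"), function(region) {
    cfg <- run_config(seed = seed, region = region, n_images = n_images,
                      n_units = n_units, n_perm = n_perm)
    run_pipeline(cfg, out_dir = if (is.null(out_dir)) NULL else
      file.path(out_dir, gsub("-like", "", region)))
  })
  names(runs) <- c("itc", "hc")
  cmp <- lapply(c("novel", "repeated"), function(cc) {
    pt <- permutation_slope_test(runs$itc$vigor$gmfr, runs$hc$vigor$gmfr,
                                 novelty = cc, n_perm = n_perm, seed = seed)
    list(novelty = cc,
         slope_itc = gmfr_regression(runs$itc$vigor$gmfr, cc)$slope,
         slope_hc = gmfr_regression(runs$hc$vigor$gmfr, cc)$slope,
         permutation_p = pt$p)
  })
  names(cmp) <- c("novel", "repeated")
  out <- list(itc = runs$itc, hc = runs$hc, comparison = cmp)
  if (!is.null(out_dir)) {
    jsonlite::write_json(
      list(itc = runs$itc$summary, hc = runs$hc$summary, comparison = cmp),
      file.path(out_dir, "demo_summary.json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(out)
}
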