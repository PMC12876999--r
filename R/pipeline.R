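write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Default run configuration
#'
#' A small synthetic-cohort pipeline configuration, suitable as a template
#' and for smoke tests. Every field can be overridden; the same structure is
#' accepted from a YAML file by [run_pipeline()].
#'
#' @param seed Master seed.
#' @param out_dir Output directory.
#' @return Nested list understood by [run_pipeline()].
#' @export
demo_config <- function(seed = 1L, out_dir = tempfile("scanpathr-run-")) {
  list(
    seed = as.integer(seed),
    out_dir = out_dir,
    input = NULL,  # NULL -> synthetic cohort; else list(fixation_report = path)
    geometry = list(width_px = 1920L, height_px = 1080L, distance_mm = 855,
                    calib_deg = 5, calib_px = 270),
    synthetic = list(n_participants = 6L, n_trials = 6L, n_fixations = 25L,
                     n_anchors = 8L, encoding_coupling = 0.7),
    preprocess = list(min_ms = 100, max_ms = 5000),
    rqa = list(radius_deg = 2.5, l_min = 2L),
    similarity = list(amp_threshold_frac = 0.10, dir_threshold_deg = 45,
                      dur_threshold_ms = 300),
    contrasts = list(
      list(measure = "recurrence_rate", a = "MI", b = "FP"),
      list(measure = "determinism", a = "MI", b = "FP"),
      list(measure = "laminarity", a = "MI", b = "FP")),
    n_boot = 1000L)
}

load_run_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  base <- demo_config()
  for (nm in names(config)) base[[nm]] <- config[[nm]]
  base
}

pipeline_geometry <- function(config) {
  g <- config$geometry
  screen_geometry(g$width_px, g$height_px, g$distance_mm, g$calib_deg, g$calib_px)
}

# group label for contrasts: imagery collapses to MI, encoding to its condition
condition_group <- function(phase, condition) {
  ifelse(phase == "imagery", "MI", condition)
}

rqa_table <- function(scanpaths, config, geometry) {
  cfg <- rqa_config(config$rqa$radius_deg, config$rqa$l_min)
  rows <- lapply(scanpaths, function(sp) {
    if (nrow(sp$fixations) < 2) return(NULL)
    r <- rqa(sp, cfg)
    data.frame(participant = sp$participant, trial = sp$trial,
               phase = sp$phase, condition = sp$condition,
               category = sp$category, n = r$n, rec_count = r$rec_count,
               recurrence_rate = r$recurrence_rate,
               determinism = r$determinism, laminarity = r$laminarity,
               fixation_spread = r$fixation_spread)
  })
  do.call(rbind, rows)
}

similarity_table <- function(scanpaths, config, geometry) {
  key <- vapply(scanpaths, function(sp) paste(sp$participant, sp$trial), "")
  rows <- list()
  for (k in unique(key)) {
    group <- scanpaths[key == k]
    phases <- vapply(group, `[[`, "", "phase")
    img <- group[phases == "imagery"]
    enc <- group[phases != "imagery"]
    if (!length(img) || !length(enc)) next
    for (e in enc) {
      if (nrow(img[[1]]$fixations) < 2 || nrow(e$fixations) < 2) next
      prof <- similarity_profile(img[[1]], e, geometry = geometry,
                                 amp_threshold_frac = config$similarity$amp_threshold_frac,
                                 dir_threshold_deg = config$similarity$dir_threshold_deg,
                                 dur_threshold_ms = config$similarity$dur_threshold_ms)
      for (dim in c("shape", "length", "direction", "position", "duration")) {
        rows[[length(rows) + 1L]] <- data.frame(
          participant = e$participant, trial = e$trial,
          comparison = paste0("MI-", e$condition), dimension = dim,
          similarity = prof[[dim]])
      }
    }
  }
  do.call(rbind, rows)
}

lan_table <- function(scanpaths) {
  key <- vapply(scanpaths, function(sp) paste(sp$participant, sp$trial), "")
  enc_profiles <- list(); img_profiles <- list(); labels <- list()
  for (k in unique(key)) {
    group <- scanpaths[key == k]
    phases <- vapply(group, `[[`, "", "phase")
    img <- group[phases == "imagery"]
    enc <- group[phases == "encoding"]
    if (!length(img) || !length(enc)) next
    enc_profiles[[length(enc_profiles) + 1L]] <- aoi_profile(enc[[1]])
    img_profiles[[length(img_profiles) + 1L]] <- aoi_profile(img[[1]])
    labels[[length(labels) + 1L]] <- data.frame(
      participant = enc[[1]]$participant, trial = enc[[1]]$trial,
      condition = enc[[1]]$condition)
  }
  list(encoding = enc_profiles, imagery = img_profiles,
       labels = do.call(rbind, labels))
}

#' Run the full gaze-analysis pipeline
#'
#' Orchestrates generate-or-read, preprocessing, per-trial recurrence
#' measures, imagery-vs-encoding scanpath similarity, the looking-at-nothing
#' association, condition contrasts and the behavioural summary, writing each
#' stage's table into `out_dir` together with a manifest (config echo, config
#' hash, seed, package version). Re-running into a non-empty output directory
#' requires `overwrite = TRUE`; earlier stages' outputs are retained when a
#' later stage fails.
#'
#' @param config A configuration list (see [demo_config()]) or the path of a
#'   YAML file with the same structure.
#' @param overwrite Allow writing into an existing output directory.
#' @return Invisibly, a list with the stage outputs and output paths.
#' @export
run_pipeline <- function(config = demo_config(), overwrite = FALSE) {
  config <- load_run_config(config)
  out <- config$out_dir
  if (dir.exists(out) && file.exists(file.path(out, "manifest.json")) &&
      !overwrite)
    stop("output directory already holds a run (use overwrite = TRUE): ", out)
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  geometry <- pipeline_geometry(config)
  stage <- "input"
  result <- list(out_dir = out)
  withCallingHandlers({
    # ---- data ----
    if (!is.null(config$input)) {
      path <- config$input$fixation_report
      if (is.null(path) || !file.exists(path))
        stop("input fixation report not found: ",
             if (is.null(path)) "(unset)" else path)
      scanpaths <- read_fixation_report(path, geometry)
      behaviour <- NULL
      if (!is.null(config$input$behaviour) && file.exists(config$input$behaviour))
        behaviour <- utils::read.table(config$input$behaviour, header = TRUE,
                                       sep = "\t", stringsAsFactors = FALSE)
    } else {
      syn <- config$synthetic
      ccfg <- cohort_config(
        n_participants = syn$n_participants, n_trials = syn$n_trials,
        n_fixations = syn$n_fixations, n_anchors = syn$n_anchors,
        encoding_coupling = syn$encoding_coupling, seed = config$seed,
        geometry = geometry)
      cohort <- generate_cohort(ccfg)
      behaviour <- cohort$behaviour
      write_fixation_report(cohort$scanpaths, file.path(out, "fixations.tsv"))
      write_tsv(cohort$truth, file.path(out, "truth.tsv"))
      write_tsv(behaviour, file.path(out, "behaviour.tsv"))
      # analyse the archived representation, so re-running from the written
      # report reproduces this run exactly (positions are stored at 2 decimals)
      scanpaths <- read_fixation_report(file.path(out, "fixations.tsv"), geometry)
    }

    # ---- preprocess ----
    stage <- "preprocess"
    filtered <- lapply(scanpaths, filter_fixations,
                       min_ms = config$preprocess$min_ms,
                       max_ms = config$preprocess$max_ms)
    scanpaths <- lapply(filtered, `[[`, "scanpath")
    report <- combine_reports(lapply(filtered, `[[`, "report"))
    jsonlite::write_json(unclass(report), file.path(out, "preprocess_report.json"),
                         auto_unbox = TRUE)
    qc <- qc_summary(scanpaths)
    write_tsv(qc, file.path(out, "qc_summary.tsv"))

    # ---- per-trial RQA ----
    stage <- "rqa"
    rqa_tab <- rqa_table(scanpaths, config, geometry)
    write_tsv(rqa_tab, file.path(out, "rqa.tsv"))

    # ---- scanpath similarity ----
    stage <- "similarity"
    sim_tab <- similarity_table(scanpaths, config, geometry)
    if (!is.null(sim_tab)) write_tsv(sim_tab, file.path(out, "similarity.tsv"))

    # ---- looking-at-nothing ----
    stage <- "lan"
    lan <- lan_table(scanpaths)
    lan_fit <- NULL
    if (length(lan$encoding) >= 2) {
      lan_fit <- lan_association(lan$encoding, lan$imagery)
      write_tsv(lan_fit$points, file.path(out, "lan_points.tsv"))
    }

    # ---- contrasts ----
    stage <- "contrast"
    contrasts <- NULL
    if (!is.null(rqa_tab) && length(config$contrasts)) {
      ctab <- rqa_tab
      ctab$condition <- condition_group(ctab$phase, ctab$condition)
      rows <- lapply(config$contrasts, function(cs) {
        cr <- condition_contrast(ctab, cs$measure, cs$a, cs$b,
                                 n_boot = config$n_boot, seed = config$seed)
        data.frame(measure = cr$measure, contrast = cr$contrast,
                   point_estimate = cr$point_estimate, ci_low = cr$ci_low,
                   ci_high = cr$ci_high, n_boot = cr$n_boot, seed = cr$seed)
      })
      contrasts <- do.call(rbind, rows)
      write_tsv(contrasts, file.path(out, "contrasts.tsv"))
    }

    # ---- behaviour ----
    stage <- "behaviour"
    beh <- NULL
    if (!is.null(behaviour)) {
      beh <- behavioural_summary(behaviour)
      jsonlite::write_json(beh, file.path(out, "behavioural_summary.json"),
                           auto_unbox = TRUE, digits = NA, dataframe = "rows")
    }

    # ---- manifest ----
    stage <- "manifest"
    cfg_path <- file.path(out, "config.json")
    jsonlite::write_json(config, cfg_path, auto_unbox = TRUE, null = "null")
    # content hash over the config without the (volatile) output location
    hashable <- config[setdiff(names(config), "out_dir")]
    hash_file <- tempfile()
    jsonlite::write_json(hashable, hash_file, auto_unbox = TRUE, null = "null")
    manifest <- list(
      package = "scanpathr",
      version = as.character(utils::packageVersion("scanpathr")),
      seed = config$seed,
      config_md5 = unname(tools::md5sum(hash_file)),
      n_scanpaths = length(scanpaths),
      lan_slope = if (!is.null(lan_fit)) lan_fit$slope else NULL,
      files = list.files(out))
    jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    result$scanpaths <- scanpaths
    result$preprocess_report <- report
    result$rqa <- rqa_tab
    result$similarity <- sim_tab
    result$lan_fit <- lan_fit
    result$contrasts <- contrasts
    result$behaviour <- beh
    result$manifest <- manifest
  }, error = function(e) {
    message(sprintf("[%s] pipeline stage '%s' failed: %s",
                    format(Sys.time(), "%H:%M:%S"), stage,
                    conditionMessage(e)))
  })
  class(result) <- "pipeline_result"
  invisible(result)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>", x$out_dir, "\n")
  if (!is.null(x$rqa))
    cat(sprintf("  %d scanpaths, %d RQA rows\n", length(x$scanpaths),
                nrow(x$rqa)))
  if (!is.null(x$lan_fit))
    cat(sprintf("  LAN slope %.3f\n", x$lan_fit$slope))
  invisible(x)
}
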