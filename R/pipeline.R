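#' Configure a batch quantification run
#'
#' @param mode `"synthetic"` generates a graded series of scenes from a
#'   fraction grid; `"directory"` reads images (and mask-PNG node ROIs
#'   named `<image>_node_mask.png`) from `input_dir`.
#' @param fractions fluorescent-fraction grid for synthetic mode.
#' @param n_negative_controls extra zero-fraction scenes appended in
#'   synthetic mode.
#' @param thresholds threshold names/objects to quantify under.
#' @param median_radius median-filter radius. The synthetic default is 0
#'   because scattered-subset scenes are exact ground truth that a median
#'   filter would, by design, erase; for photographic input use 1 or more.
#' @param region_mode fluorescent-region geometry for synthetic scenes; see
#'   [scene_spec()].
#' @param score_threshold threshold whose surface percentage is scored.
#' @param kappa_scheme weight scheme for the weighted-kappa report.
#' @param input_dir image directory for `"directory"` mode.
#' @param background_area_px area of the fixed background circle.
#' @param scene_args named list of extra [scene_spec()] arguments (canvas
#'   size, node geometry, intensity statistics) applied to every synthetic
#'   scene.
#' @param seed master seed; per-image seeds are derived from it.
#' @param out_dir where run artifacts (CSVs, JSON summary, log) are
#'   written; `NULL` for in-memory results only.
#' @return a `run_config` list.
#' @export
run_config <- function(mode = c("synthetic", "directory"),
                       fractions = seq(0, 1, by = 0.1),
                       n_negative_controls = 0L,
                       thresholds = c("A", "T2", "T3"),
                       median_radius = if (mode[1] == "synthetic") 0L else 1L,
                       region_mode = "subset",
                       score_threshold = "A",
                       kappa_scheme = "linear",
                       input_dir = NULL,
                       background_area_px = 5806L,
                       scene_args = list(),
                       seed = 1L, out_dir = NULL) {
  mode <- match.arg(mode)
  lapply(thresholds, resolve_threshold)  # validate early
  if (mode == "directory" && is.null(input_dir))
    stop_fq("directory mode requires input_dir")
  structure(list(
    mode = mode, fractions = fractions,
    n_negative_controls = as.integer(n_negative_controls),
    thresholds = thresholds, median_radius = as.integer(median_radius),
    region_mode = region_mode, score_threshold = score_threshold,
    kappa_scheme = kappa_scheme, input_dir = input_dir,
    background_area_px = as.integer(background_area_px),
    scene_args = scene_args,
    seed = as.integer(seed), out_dir = out_dir
  ), class = "run_config")
}

#' Run the end-to-end quantification workflow
#'
#' Synthesizes or ingests specimen images, measures each under the
#' configured color thresholds, assigns the semi-quantitative score and
#' dichotomous status, and - when ground truth or a second rating source is
#' available - runs the validation battery: weighted and simple kappa of
#' measured-vs-true scores and statuses, the empirical ROC of mean
#' intensity against true status, and the Spearman association between
#' intensity and surface percentage. Identical config and seed give
#' identical outputs.
#'
#' @param config a [run_config()].
#' @return invisibly, a list with `quant` (per-image per-threshold rows
#'   with score/status columns), `truth` (per-image ground truth, synthetic
#'   mode), `agreement`, `roc`, `correlation`, and `paths` of any files
#'   written.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  log_lines <- character()
  logf <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, line)
    message(line)
  }
  logf("run_pipeline: mode=%s seed=%d thresholds=%s", config$mode,
       config$seed, paste(vapply(config$thresholds,
         function(t) resolve_threshold(t)$name, character(1)),
         collapse = ","))

  items <- list()
  if (config$mode == "synthetic") {
    fr <- c(config$fractions, rep(0, config$n_negative_controls))
    for (i in seq_along(fr)) {
      sc <- generate_node_image(do.call(scene_spec, c(
        list(fraction = fr[i], region_mode = config$region_mode,
             seed = config$seed + i),
        config$scene_args
      )))
      items[[sprintf("scene_%02d", i)]] <- sc
    }
  } else {
    files <- list.files(config$input_dir, pattern = "\\.(png|tif|tiff)$",
                        ignore.case = TRUE, full.names = TRUE)
    files <- files[!grepl("_mask\\.", files)]
    if (!length(files)) stop_fq("no input images found")
    for (f in files) {
      id <- tools::file_path_sans_ext(basename(f))
      mask_path <- file.path(dirname(f), paste0(id, "_node_mask.png"))
      if (!file.exists(mask_path)) {
        logf("skipping %s: missing node mask %s", id, basename(mask_path))
        next
      }
      items[[id]] <- list(image = read_image(f),
                          truth = list(node_mask = read_mask(mask_path)))
    }
    if (!length(items)) stop_fq("no input image had a node mask")
  }

  quant_rows <- list(); truth_rows <- list()
  for (id in names(items)) {
    it <- items[[id]]
    node <- roi_from_mask(it$truth$node_mask)
    dims <- dim(it$truth$node_mask)
    bg <- tryCatch(
      place_background_circle(node, dims, config$background_area_px),
      error = function(e) {
        logf("image %s: %s (background term set to 0)", id, conditionMessage(e))
        NULL
      })
    q <- quantify_image(it$image, node, bg, config$thresholds,
                        config$median_radius, image_id = id)
    sc <- score_image(q, config$score_threshold)
    q$score <- sc$score
    q$score_label <- sc$label
    q$status <- sc$status
    quant_rows[[id]] <- q
    if (!is.null(it$truth$fluor_mask)) {
      truth_rows[[id]] <- data.frame(
        image_id = id,
        true_fraction = it$truth$realized_fraction,
        true_pct = 100 * it$truth$realized_fraction,
        true_mean_intensity = it$truth$realized_mean_intensity,
        true_score = assign_score(100 * it$truth$realized_fraction),
        stringsAsFactors = FALSE
      )
    }
  }
  quant <- do.call(rbind, c(quant_rows, list(make.row.names = FALSE)))
  truth <- if (length(truth_rows))
    do.call(rbind, c(truth_rows, list(make.row.names = FALSE))) else NULL

  agreement <- roc <- correlation <- NULL
  scored <- quant[quant$threshold ==
                    resolve_threshold(config$score_threshold)$name, ]
  if (!is.null(truth) && nrow(truth) >= 2L) {
    m <- merge(scored, truth, by = "image_id")
    if (length(unique(c(m$score, m$true_score))) >= 2L) {
      agreement <- list(
        score = cohens_kappa(m$true_score, m$score, weighted = TRUE,
                             scheme = config$kappa_scheme, levels = 0:4),
        status = tryCatch(
          cohens_kappa(dichotomize(m$true_score), m$status, levels = 0:1),
          error = function(e) {
            logf("status kappa unavailable: %s", conditionMessage(e))
            NULL
          })
      )
    }
    fi_names <- unique(quant$threshold)
    fi_pick <- c(intersect(c("T2", "T3", "T1"), fi_names), fi_names)[1]
    fi_col <- quant[quant$threshold == fi_pick, ]
    true_status <- dichotomize(truth$true_score[
      match(fi_col$image_id, truth$image_id)])
    if (length(unique(true_status)) == 2L)
      roc <- fi_logistic_roc(fi_col$mean_fi_au, true_status)
    if (nrow(scored) >= 3L && stats::sd(scored$mean_fi_au) > 0 &&
        stats::sd(scored$surface_fluorescence_pct) > 0)
      correlation <- spearman_assoc(scored$mean_fi_au,
                                    scored$surface_fluorescence_pct)
  }

  paths <- character()
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    qp <- file.path(config$out_dir, "quant_results.csv")
    utils::write.csv(quant, qp, row.names = FALSE)
    paths["quant"] <- qp
    if (!is.null(truth)) {
      tp <- file.path(config$out_dir, "ground_truth.csv")
      utils::write.csv(truth, tp, row.names = FALSE)
      paths["truth"] <- tp
    }
    summary <- list(
      seed = config$seed, mode = config$mode,
      config_hash = config_hash(config),
      n_images = length(items),
      r_version = as.character(getRversion()),
      package_version = as.character(utils::packageVersion("fluoroquant")),
      agreement = if (!is.null(agreement)) list(
        weighted_kappa_score = agreement$score$kappa,
        simple_kappa_status = if (!is.null(agreement$status))
          agreement$status$kappa else NA
      ),
      roc = if (!is.null(roc)) list(
        auc = roc$auc, cutpoint_au = roc$cutpoint_au,
        sensitivity_pct = roc$sensitivity_pct,
        specificity_pct = roc$specificity_pct
      ),
      correlation = if (!is.null(correlation)) correlation
    )
    sp <- file.path(config$out_dir, "run_summary.json")
    jsonlite::write_json(summary, sp, auto_unbox = TRUE, digits = NA,
                         null = "null")
    paths["summary"] <- sp
    lp <- file.path(config$out_dir, "run.log")
    writeLines(log_lines, lp)
    paths["log"] <- lp
  }

  invisible(list(quant = quant, truth = truth, agreement = agreement,
                 roc = roc, correlation = correlation, paths = paths))
}

# Stable fingerprint of the configuration for the run log; output paths do
# not alter what is computed, so they are excluded.
config_hash <- function(config) {
  keep <- setdiff(names(config), c("out_dir", "input_dir"))
  s <- jsonlite::toJSON(config[sort(keep)], auto_unbox = TRUE,
                        null = "null", digits = NA)
  # small polynomial rolling hash over the serialized config; enough to
  # detect config drift in the run log
  bytes <- utils::head(as.integer(charToRaw(as.character(s))), 10000L)
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2^31
  sprintf("%08x", h)
}

#' Compare measured results with ground truth
#'
#' Joins per-image measurements with the generator's ground truth and
#' reports absolute errors of the surface percentage and (for a chosen
#' intensity threshold) the mean intensity.
#'
#' @param quant quantification rows (one threshold's rows are selected).
#' @param truth ground-truth rows as produced by [run_pipeline()].
#' @param threshold threshold name to compare on; default `"A"`.
#' @return list with the per-image `table` (including `pct_error` and
#'   `fi_error` columns) and `max_pct_error`, `mean_pct_error`,
#'   `max_fi_error`, `mean_fi_error`.
#' @export
validate_against_truth <- function(quant, truth, threshold = "A") {
  q <- quant[quant$threshold == threshold, ]
  if (!setequal(q$image_id, truth$image_id))
    stop_fq("measured and truth image ids do not match")
  m <- merge(q, truth, by = "image_id")
  m$pct_error <- abs(m$surface_fluorescence_pct - m$true_pct)
  m$fi_error <- abs(m$mean_fi_au - m$true_mean_intensity)
  list(table = m,
       max_pct_error = max(m$pct_error),
       mean_pct_error = mean(m$pct_error),
       max_fi_error = max(m$fi_error),
       mean_fi_error = mean(m$fi_error))
}
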