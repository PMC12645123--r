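#' Configure an end-to-end pipeline run
#'
#' @param cohort A [cohort_spec()] describing the synthetic cohort (the
#'   real-data path instead takes a prebuilt table via `table`).
#' @param table Optional [depthbin_table()]; when supplied, simulation is
#'   skipped and the table is analyzed as-is.
#' @param level `"table"` (table-level fast path), `"rd"` (image-level
#'   scalar volumes), or `"dwi"` (full simulated acquisitions with tensor
#'   fitting).
#' @param metric `"RD"`, `"AD"`, `"MD"`, `"FA"`, or `"thickness"`.
#' @param mode Depth mode (see [build_table()]).
#' @param k Bin index for `mode = "single_bin_k"`.
#' @param screen_threshold FDR threshold for the screening mask (default
#'   0.025 per direction).
#' @param combine_threshold FDR threshold for the combined-percentile mask
#'   (default 0.0025); must not exceed `screen_threshold`.
#' @param reference_groups Two group numbers used as normal/dementia
#'   references (default 1 and 4).
#' @param ridge Ridge penalty of the logistic fits.
#' @param test,fdr_family Passed to [run_group_analysis()].
#' @param out_dir Optional output directory for TSV/JSON artifacts.
#' @param seed Root seed; overrides the cohort spec's seed.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_spec(), table = NULL,
                            level = c("table", "rd", "dwi"),
                            metric = "RD",
                            mode = c("bins8", "single_bin_k", "bin_10_90",
                                     "voxel", "thickness"),
                            k = NULL,
                            screen_threshold = 0.025,
                            combine_threshold = 0.0025,
                            reference_groups = c(1L, 4L),
                            ridge = 1e-4,
                            test = "welch",
                            fdr_family = "per_direction",
                            out_dir = NULL, seed = 1L) {
  level <- match.arg(level)
  mode <- match.arg(mode)
  stopifnot(screen_threshold > 0, screen_threshold <= 1,
            combine_threshold > 0, combine_threshold <= 1,
            length(reference_groups) == 2L)
  if (combine_threshold > screen_threshold) {
    stop("combine_threshold must not exceed screen_threshold")
  }
  if (metric == "thickness") mode <- "thickness"
  if (metric %in% c("AD", "MD", "FA") && level != "dwi" && is.null(table)) {
    stop(sprintf("metric '%s' requires level = 'dwi'", metric))
  }
  structure(
    list(cohort = cohort, table = table, level = level, metric = metric,
         mode = mode, k = k, screen_threshold = screen_threshold,
         combine_threshold = combine_threshold,
         reference_groups = as.integer(reference_groups), ridge = ridge,
         test = test, fdr_family = fdr_family, out_dir = out_dir,
         seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

# Stable hash of the analysis-relevant configuration fields.
config_hash <- function(config) {
  fields <- config[c("level", "metric", "mode", "k", "screen_threshold",
                     "combine_threshold", "reference_groups", "ridge",
                     "test", "fdr_family", "seed")]
  fields$cohort <- unclass(config$cohort)
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(fields, auto_unbox = TRUE, digits = NA,
                              null = "null"), tmp)
  unname(tools::md5sum(tmp))
}

# Direction of interest per metric: diffusivities are elevated in the
# dementia reference, thickness and (typically) FA are reduced.
metric_direction <- function(metric) {
  if (metric %in% c("thickness", "FA")) "a_greater" else "b_greater"
}

#' Run the full pipeline
#'
#' Executes the stages in their canonical order: simulate (or accept) a
#' cohort, derive the participant x ROI x depth-bin table, run the
#' directional group analysis between the reference groups with FDR
#' screening, and score every participant with the logistic percentile
#' model (frozen masks, leave-one-out reference fits). Artifacts are
#' written as TSV plus a JSON run manifest when `out_dir` is set.
#'
#' @param config A [pipeline_config()].
#' @return A list (`pipeline_run`) with `config`, `hash`, `table`,
#'   `result`, `mask_025`, `mask_0025`, `scores`, `r2_all`, `r2_group2`,
#'   `summary`, `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- Sys.time()
  spec <- config$cohort
  spec$seed <- config$seed
  cohort <- NULL

  table <- config$table
  if (is.null(table)) {
    if (config$level == "table") {
      table <- make_depthbin_table(spec)
      if (config$mode != "bins8") {
        table <- collapse_table(table, config$mode, config$k)
      }
    } else {
      cohort <- simulate_cohort(spec, level = if (config$level == "dwi")
        "dwi" else "rd")
      table <- build_table(cohort, metric = config$metric,
                           mode = config$mode, k = config$k)
    }
  }

  ref_a <- group_ids(table, config$reference_groups[1])
  ref_b <- group_ids(table, config$reference_groups[2])
  result <- run_group_analysis(table, ref_a, ref_b, test = config$test,
                               fdr_family = config$fdr_family)
  direction <- metric_direction(config$metric)
  mask_025 <- select_significant(result, config$screen_threshold, direction)
  mask_0025 <- select_significant(result, config$combine_threshold, direction)

  scores <- NULL
  r2_all <- r2_group2 <- NA_real_
  if (nrow(mask_025) > 0L) {
    scores <- score_cohort(table, mask_025, mask_0025, ref_a, ref_b,
                           ridge = config$ridge)
    r2_all <- suppressWarnings(
      correlate_with_biomarker(scores$summary$combined,
                               scores$summary$abeta_ratio))
    r2_group2 <- suppressWarnings(
      correlate_with_biomarker(scores$summary$combined,
                               scores$summary$abeta_ratio,
                               subset = scores$summary$group == 2L))
  }
  summary <- summarize_selection(mask_025,
                                 n_bins = length(unique(result$bin)))

  files <- character(0)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    fp <- function(name) file.path(config$out_dir, name)
    files <- c(
      write_depthbin_tsv(table, fp("depthbin_table.tsv")),
      write_group_result_tsv(result, fp("group_result.tsv")),
      write_mask_tsv(mask_025, fp("mask_025.tsv")),
      write_mask_tsv(mask_0025, fp("mask_0025.tsv"))
    )
    if (!is.null(scores)) {
      files <- c(files, write_scores_tsv(scores, fp("scores")))
    }
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("laminaRD")),
    hash = config_hash(config), seed = config$seed,
    started = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    n_selected_025 = nrow(mask_025), n_selected_0025 = nrow(mask_0025),
    n_degenerate = attr(result, "n_degenerate"),
    n_skipped = attr(result, "n_skipped"),
    files = files
  )
  if (!is.null(config$out_dir)) {
    writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE),
               file.path(config$out_dir, "manifest.json"))
  }

  structure(
    list(config = config, hash = manifest$hash, cohort = cohort,
         table = table, result = result, mask_025 = mask_025,
         mask_0025 = mask_0025, scores = scores, r2_all = r2_all,
         r2_group2 = r2_group2, summary = summary, manifest = manifest),
    class = "pipeline_run"
  )
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat(sprintf("<pipeline_run> %s/%s: %d screened, %d combined; hash %s\n",
              x$config$metric, x$config$mode, nrow(x$mask_025),
              nrow(x$mask_0025), substr(x$hash, 1, 8)))
  if (!is.null(x$scores)) {
    print(x$scores$group_summary, row.names = FALSE)
  }
  invisible(x)
}

#' Run the secondary-analysis variants
#'
#' Recomputes each participant's combined percentile under the secondary
#' analyses and tabulates them against the primary analysis: combining
#' percentiles within one depth bin at a time (reusing the primary
#' percentiles), a single wide 10-90% depth bin, voxel-based regional
#' averaging, the axial/mean diffusivity and fractional anisotropy
#' metrics, and cortical thickness. Variants whose high-confidence mask is
#' empty are reported as all-`NA` columns. Metric and voxel/thickness
#' variants require an image-level (`"dwi"` for the metric ones) primary
#' run and are skipped otherwise, with a message.
#'
#' @param primary A [run_pipeline()] result.
#' @return List with `comparison` (data.frame: participant, group, one
#'   column per variant) and `runs` (the variant pipeline runs).
#' @export
run_variants <- function(primary) {
  stopifnot(inherits(primary, "pipeline_run"))
  config <- primary$config
  out <- data.frame(participant = primary$table$participants$id,
                    group = primary$table$participants$group)
  out$primary <- variant_combined(primary)
  runs <- list()

  # percentiles combined within one depth bin at a time
  if (!is.null(primary$scores) && config$mode == "bins8") {
    for (k in 1:8) {
      out[[paste0("combine_bin_", k)]] <- vapply(
        primary$scores$reports, function(r) {
          sel <- r$combos$in_combined & r$combos$bin == k
          if (any(sel)) mean(r$combos$percentile[sel]) else NA_real_
        }, numeric(1))
    }
  }

  rerun <- function(metric, mode, k = NULL) {
    cfg <- config
    cfg$metric <- metric
    cfg$mode <- mode
    cfg$k <- k
    cfg$table <- NULL
    cfg$out_dir <- NULL
    run_pipeline(cfg)
  }

  runs$bin_10_90 <- rerun(config$metric, "bin_10_90")
  out$bin_10_90 <- variant_combined(runs$bin_10_90)

  if (config$level %in% c("rd", "dwi")) {
    runs$voxel <- rerun(config$metric, "voxel")
    out$voxel <- variant_combined(runs$voxel)
    runs$thickness <- rerun("thickness", "thickness")
    out$thickness <- variant_combined(runs$thickness)
  } else {
    message("voxel and thickness variants require an image-level run; skipped")
  }
  if (config$level == "dwi") {
    for (m in c("AD", "MD", "FA")) {
      runs[[m]] <- rerun(m, "bins8")
      out[[m]] <- variant_combined(runs[[m]])
    }
  } else {
    message("AD/MD/FA variants require level = 'dwi'; skipped")
  }
  list(comparison = out, runs = runs)
}

# Collapse a bins8 table to a single-bin mode for table-level cohorts:
# single_bin_k keeps one bin, bin_10_90 averages the eight bins (the
# table-level generator defines values at bin granularity, so the wide
# bin is the mean of the bin values).
collapse_table <- function(table, mode, k = NULL) {
  stopifnot(inherits(table, "depthbin_table"), table$mode == "bins8")
  if (mode == "single_bin_k") {
    if (is.null(k) || !k %in% 1:8) stop("mode 'single_bin_k' requires k in 1..8")
    vals <- table$values[, , k, drop = FALSE]
    bins <- depth_bin_labels()[k]
  } else if (mode == "bin_10_90") {
    vals <- array(apply(table$values, c(1, 2), mean),
                  dim = c(dim(table$values)[1:2], 1L))
    bins <- "10-90%"
  } else {
    stop(sprintf("mode '%s' is not available for table-level cohorts", mode))
  }
  depthbin_table(vals, table$participants, metric = table$metric,
                 mode = mode, bins = bins, roi_names = table$roi_names,
                 lobe_map = table$lobe_map)
}

variant_combined <- function(run) {
  if (is.null(run$scores)) {
    return(rep(NA_real_, nrow(run$table$participants)))
  }
  run$scores$summary$combined
}
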