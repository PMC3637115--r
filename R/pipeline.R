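#' Run the full analysis pipeline
#'
#' End-to-end driver composing the stages of the analysis: for still
#' images, thresholding, size-gated object detection and morphometry; for
#' time-lapse sequences, frame sampling, nucleus detection, track linking
#' and motility summaries; and, when two or more groups are supplied,
#' per-parameter one-way ANOVA comparisons. All tables are written as CSV
#' into `config$output_dir` together with a JSON run manifest listing
#' every output file with a content hash. Identical config and inputs
#' produce byte-identical CSV output.
#'
#' @param config A [pipeline_config()].
#' @param stills Named list (one element per group, e.g. `CD`, `CTR`) of
#'   lists of [calibrated_image()] stills. Optional.
#' @param sequences Named list (one element per group) of lists of
#'   `timelapse` objects (or lists with `frames` and `times_h` as from
#'   [read_sequence()]). Optional.
#' @param reference_areas Pixel areas of representative cells used to
#'   calibrate the minimum object size; required with `stills` unless
#'   `min_size` is given.
#' @param min_size Explicit minimum object size in pixels (overrides the
#'   calibration).
#' @param nucleus_min_size Minimum nucleus blob size in pixels for
#'   sequence tracking (default 10).
#' @return A result bundle (list) with elements `records`, `summaries`,
#'   `comparisons`, `motility`, `manifest`, invisibly.
#' @export
run_pipeline <- function(config, stills = NULL, sequences = NULL,
                         reference_areas = NULL, min_size = NULL,
                         nucleus_min_size = 10L) {
  if (!inherits(config, "pipeline_config"))
    stop("`config` must be a pipeline_config")
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  out_files <- character(0)
  records <- NULL; comparisons <- list(); summaries <- list()
  motility <- NULL

  log_stage <- function(stage, input_id, msg) {
    message(sprintf("[%s] %s: %s", stage, input_id, msg))
  }

  if (!is.null(stills)) {
    if (is.null(min_size)) {
      if (is.null(reference_areas))
        stop("stage segment: `reference_areas` or `min_size` required for stills")
      min_size <- calibrate_min_size(reference_areas, config$min_size_factor)
    }
    rows <- list()
    for (grp in names(stills)) {
      for (i in seq_along(stills[[grp]])) {
        id <- sprintf("%s/%d", grp, i)
        img <- stills[[grp]][[i]]
        res <- tryCatch({
          th <- auto_threshold(img)
          rois <- detect_objects(th$mask, min_size = min_size)
          recs <- measure_objects(img, rois)
          log_stage("segment", id,
                    sprintf("threshold %d, %d object(s)", th$level,
                            nrow(recs)))
          if (nrow(recs))
            cbind(data.frame(group = grp, image = i), recs)
          else NULL
        }, error = function(e)
          stop(sprintf("stage segment failed on input %s: %s", id,
                       conditionMessage(e)), call. = FALSE))
        rows[[length(rows) + 1L]] <- res
      }
    }
    records <- do.call(rbind, rows)
    if (!is.null(records)) {
      f <- file.path(config$output_dir, "morphometry_records.csv")
      utils::write.csv(records, f, row.names = FALSE)
      out_files <- c(out_files, f)
      params <- c("feret_um", "orthogonal_um", "perimeter_um", "area_um2",
                  "circularity", "complexity")
      groups <- unique(records$group)
      for (p in params) {
        vals <- lapply(groups, function(g)
          records[records$group == g, p])
        names(vals) <- groups
        for (g in groups)
          summaries[[paste(p, g)]] <- summarize(vals[[g]], g, p)
        if (length(groups) >= 2L)
          comparisons[[p]] <- anova_oneway(vals, parameter = p)
      }
    }
  }

  if (!is.null(sequences)) {
    mot_rows <- list(); track_rows <- list()
    for (grp in names(sequences)) {
      for (i in seq_along(sequences[[grp]])) {
        id <- sprintf("%s/%d", grp, i)
        sq <- sequences[[grp]][[i]]
        res <- tryCatch({
          tracks <- if (inherits(sq, "timelapse")) {
            track_nuclei(sq, interval_h = config$interval_h,
                         gate = config$gate_um,
                         min_size = nucleus_min_size)
          } else {
            track_nuclei(sq$frames, times_h = sq$times_h,
                         interval_h = config$interval_h,
                         gate = config$gate_um,
                         min_size = nucleus_min_size)
          }
          log_stage("track", id,
                    sprintf("%d complete track(s)",
                            length(unique(tracks$cell_id))))
          tracks
        }, error = function(e)
          stop(sprintf("stage track failed on input %s: %s", id,
                       conditionMessage(e)), call. = FALSE))
        if (nrow(res)) {
          track_rows[[length(track_rows) + 1L]] <-
            cbind(data.frame(group = grp, sequence = i), res)
          mot_rows[[length(mot_rows) + 1L]] <-
            cbind(data.frame(group = grp, sequence = i),
                  summarize_tracks(res))
        }
      }
    }
    motility <- do.call(rbind, mot_rows)
    if (!is.null(motility)) {
      f1 <- file.path(config$output_dir, "tracks.csv")
      utils::write.csv(do.call(rbind, track_rows), f1, row.names = FALSE)
      f2 <- file.path(config$output_dir, "motility_summary.csv")
      utils::write.csv(motility, f2, row.names = FALSE)
      out_files <- c(out_files, f1, f2)
      groups <- unique(motility$group)
      for (p in c("total_displacement_um", "velocity_um_per_h")) {
        vals <- lapply(groups, function(g) motility[motility$group == g, p])
        names(vals) <- groups
        for (g in groups)
          summaries[[paste(p, g)]] <- summarize(vals[[g]], g, p)
        if (length(groups) >= 2L && all(lengths(vals) >= 2L))
          comparisons[[p]] <- anova_oneway(vals, parameter = p)
      }
    }
  }

  if (length(summaries)) {
    sum_df <- do.call(rbind, lapply(summaries, function(s)
      data.frame(parameter = s$parameter, group = s$label, n = s$n,
                 mean = s$mean, sd = s$sd, median = s$median,
                 min = s$min, max = s$max)))
    rownames(sum_df) <- NULL
    f <- file.path(config$output_dir, "group_summaries.csv")
    utils::write.csv(sum_df, f, row.names = FALSE)
    out_files <- c(out_files, f)
  } else sum_df <- NULL

  if (length(comparisons)) {
    cmp_df <- do.call(rbind, lapply(comparisons, function(x)
      data.frame(parameter = x$parameter, F = x$F, df1 = x$df1,
                 df2 = x$df2, p = x$p, significant = x$significant)))
    rownames(cmp_df) <- NULL
    f <- file.path(config$output_dir, "comparisons.csv")
    utils::write.csv(cmp_df, f, row.names = FALSE)
    out_files <- c(out_files, f)
  } else cmp_df <- NULL

  manifest <- list(
    config = unclass(config),
    seed = config$seed,
    package_version = as.character(utils::packageVersion("fibromorph")),
    timestamp = format(Sys.time(), tz = "UTC"),
    files = lapply(out_files, function(f)
      list(name = basename(f), md5 = unname(tools::md5sum(f)))))
  mf <- file.path(config$output_dir, "manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, digits = NA)

  invisible(list(records = records, summaries = sum_df,
                 comparisons = cmp_df, motility = motility,
                 manifest = manifest, output_dir = config$output_dir))
}
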