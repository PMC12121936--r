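#' Default pipeline configuration
#'
#' Returns the full nested configuration with every stage's defaults; any
#' value supplied in `overrides` (a nested list with the same shape)
#' replaces the default. Defaults follow the recommended operating point for
#' GCaMP6s axon imaging at 15.49 Hz: transient band 0.03-0.13 Hz with
#' selection threshold 0.3, four requested change points with a 2 s artifact
#' duration gate, ~20 s / 8th-percentile baseline with 0.12 dF/F / 0.5 s /
#' 0.1 dF/F peak gates, and a 0.8 maximum-correlation prefilter.
#'
#' @param overrides Nested list of overrides.
#' @return Nested configuration list.
#' @export
pipeline_config <- function(overrides = list()) {
  defaults <- list(
    smoothing = list(enabled = TRUE, window_frames = 15, polyorder = 3),
    selection = list(
      enabled = TRUE, band_low_hz = 0.03, band_high_hz = 0.13,
      power_threshold = 0.3, detrend = "linear"
    ),
    motion = list(
      enabled = TRUE, n_change_points = 4, min_artifact_duration_s = 2,
      deviation_k = 3, synchrony_check = TRUE, min_affected_fraction = 0.25,
      mode = "drop", verify_with_static = TRUE
    ),
    transients = list(
      enabled = TRUE, window_s = 20, percentile = 8, min_amplitude = 0.12,
      min_duration_s = 0.5, min_prominence = 0.1, subtract_only = FALSE
    ),
    cluster = list(
      enabled = TRUE, prefilter_r = 0.8, k_min = 2, k_max_fraction = 0.5,
      method = "both", linkage = "average", seed = 1
    )
  )
  modifyList(defaults, overrides)
}

#' Run the full preprocessing pipeline
#'
#' Orchestrates the whole flow on one session: Savitzky-Golay smoothing,
#' band-power ROI selection, z-shift artifact detection and removal (with
#' static-channel verification when a static channel is supplied), baseline
#' correction and transient extraction, and correlation clustering of the
#' surviving ROIs. Stages can be disabled individually via the config. The
#' returned manifest is deterministic for a given input and config (no
#' timestamps), so reruns are byte-comparable.
#'
#' @param traces Activity-channel [trace_matrix()].
#' @param static Optional static-channel [trace_matrix()] over the same ROIs.
#' @param config Nested configuration list; see [pipeline_config()]. Partial
#'   lists are merged over the defaults.
#' @param out_dir Optional output directory; when given, each stage writes
#'   its tabular artifacts (CSV) and the manifest (JSON) there.
#' @return A `subprep_run` object: list with `manifest` (counts and choices
#'   per stage), `selection`, `artifacts`, `transients`, `clusters` and the
#'   final `traces` used downstream. Stages that did not run are `NULL`.
#' @export
run_pipeline <- function(traces, static = NULL, config = list(),
                         out_dir = NULL) {
  stopifnot(inherits(traces, "trace_matrix"))
  cfg <- pipeline_config(config)
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  manifest <- list(
    package = "subprep",
    version = as.character(utils::packageVersion("subprep")),
    config = cfg, config_hash = rlang::hash(cfg),
    input = list(
      n_rois = n_rois(traces), n_frames = n_frames(traces),
      frame_rate_hz = frame_rate(traces), has_static = !is.null(static)
    ),
    stages = list(), status = "ok"
  )
  res <- list(selection = NULL, artifacts = NULL, transients = NULL,
              clusters = NULL)

  work <- traces
  if (isTRUE(cfg$smoothing$enabled)) {
    work <- smooth_traces(work, cfg$smoothing$window_frames,
                          cfg$smoothing$polyorder)
    manifest$stages$smoothing <- list(
      window_frames = cfg$smoothing$window_frames,
      polyorder = cfg$smoothing$polyorder
    )
  }

  if (isTRUE(cfg$selection$enabled)) {
    sel <- select_rois(
      band_power(work,
        band = c(cfg$selection$band_low_hz, cfg$selection$band_high_hz),
        detrend = cfg$selection$detrend
      ),
      threshold = cfg$selection$power_threshold
    )
    res$selection <- sel
    manifest$stages$selection <- list(
      n_in = nrow(sel), n_selected = sum(sel$selected),
      n_discarded = sum(!sel$selected),
      threshold = cfg$selection$power_threshold
    )
    if (!is.null(out_dir)) {
      readr::write_csv(tidy(sel), file.path(out_dir, "selection.csv"))
    }
    if (sum(sel$selected) == 0) {
      manifest$status <- "stopped_after_selection"
      warn("No ROI exceeded the band-power threshold; pipeline stopped.")
      out <- structure(list(manifest = manifest, traces = work), class = "subprep_run")
      out <- c(out, res)
      class(out) <- "subprep_run"
      if (!is.null(out_dir)) write_manifest(manifest, out_dir)
      return(out)
    }
    keep <- match(sel$roi_id[sel$selected], roi_ids(work))
    work <- tm_rows(work, keep)
  }

  if (isTRUE(cfg$motion$enabled)) {
    iv <- detect_artifacts(work,
      n_change_points = cfg$motion$n_change_points,
      min_artifact_duration_s = cfg$motion$min_artifact_duration_s,
      deviation_k = cfg$motion$deviation_k,
      synchrony_check = cfg$motion$synchrony_check,
      min_affected_fraction = cfg$motion$min_affected_fraction
    )
    if (!is.null(static) && isTRUE(cfg$motion$verify_with_static) &&
        nrow(iv) > 0) {
      sub <- match(roi_ids(work), roi_ids(static))
      iv <- verify_with_static_channel(
        tm_rows(static, sub), iv,
        n_change_points = cfg$motion$n_change_points,
        min_artifact_duration_s = cfg$motion$min_artifact_duration_s,
        deviation_k = cfg$motion$deviation_k
      )
    }
    res$artifacts <- iv
    # an unconfirmed interval on a verified session is population coactivity,
    # not motion: keep those frames
    iv_mask <- if ("confirmed" %in% names(iv)) {
      dplyr::filter(as_tibble(iv), .data$confirmed)
    } else {
      iv
    }
    manifest$stages$motion <- list(
      n_intervals = nrow(iv),
      n_confirmed = if ("confirmed" %in% names(iv)) sum(iv$confirmed) else NA,
      frames_dropped = if (nrow(iv_mask)) {
        sum(iv_mask$end_frame - iv_mask$start_frame)
      } else {
        0L
      },
      intervals = if (nrow(iv)) {
        lapply(seq_len(nrow(iv)), function(i) {
          list(start_frame = iv$start_frame[i], end_frame = iv$end_frame[i])
        })
      } else {
        list()
      },
      mode = cfg$motion$mode
    )
    if (!is.null(out_dir)) {
      readr::write_csv(as_tibble(iv), file.path(out_dir, "artifacts.csv"))
    }
    if (nrow(iv_mask) > 0) {
      masked <- apply_artifact_mask(work, iv_mask, mode = cfg$motion$mode)
      work <- if (cfg$motion$mode == "split") {
        # analyse the longest stable epoch; the rest are returned untouched
        lens <- vapply(masked, n_frames, integer(1))
        masked[[which.max(lens)]]
      } else {
        masked
      }
    }
  }

  tr <- NULL
  if (isTRUE(cfg$transients$enabled)) {
    tr <- extract_transients(work,
      window_s = cfg$transients$window_s,
      percentile = cfg$transients$percentile,
      min_amplitude = cfg$transients$min_amplitude,
      min_duration_s = cfg$transients$min_duration_s,
      min_prominence = cfg$transients$min_prominence,
      subtract_only = cfg$transients$subtract_only
    )
    res$transients <- tr
    manifest$stages$transients <- list(
      n_peaks = nrow(tr$peaks),
      n_rois_with_peaks = length(unique(tr$peaks$roi_id))
    )
    if (!is.null(out_dir)) {
      readr::write_csv(tr$peaks, file.path(out_dir, "peaks.csv"))
      write_trace_csv(tr$masked_dff, file.path(out_dir, "masked_dff.csv"))
    }
  }

  if (isTRUE(cfg$cluster$enabled)) {
    cl_input <- if (!is.null(tr)) tr$masked_dff else work
    cl <- withCallingHandlers(
      cluster_rois(cl_input,
        prefilter_r = cfg$cluster$prefilter_r, k_min = cfg$cluster$k_min,
        k_max_fraction = cfg$cluster$k_max_fraction,
        method = cfg$cluster$method, linkage = cfg$cluster$linkage,
        seed = cfg$cluster$seed
      ),
      warning = function(w) invokeRestart("muffleWarning")
    )
    res$clusters <- cl
    manifest$stages$cluster <- list(
      n_candidates = sum(!cl$groups$is_singleton),
      n_singletons = length(cl$singletons),
      k = cl$k, method = cl$method
    )
    if (!is.null(out_dir)) {
      readr::write_csv(cl$groups, file.path(out_dir, "groups.csv"))
      if (!is.null(cl$kscan)) {
        readr::write_csv(cl$kscan$scores, file.path(out_dir, "kscan.csv"))
      }
    }
  }

  out <- c(list(manifest = manifest, traces = work), res)
  class(out) <- "subprep_run"
  if (!is.null(out_dir)) write_manifest(manifest, out_dir)
  out
}

write_manifest <- function(manifest, out_dir) {
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA
  )
}

#' @export
print.subprep_run <- function(x, ...) {
  m <- x$manifest
  cat(sprintf(
    "<subprep_run> %d ROIs x %d frames, status: %s\n",
    m$input$n_rois, m$input$n_frames, m$status
  ))
  for (nm in names(m$stages)) {
    cat(sprintf("  %s: %s\n", nm, paste(
      names(m$stages[[nm]])[1:min(3, length(m$stages[[nm]]))],
      unlist(lapply(m$stages[[nm]][1:min(3, length(m$stages[[nm]]))],
                    function(v) paste(unlist(v), collapse = ",")))[
        1:min(3, length(m$stages[[nm]]))],
      sep = "=", collapse = ", "
    )))
  }
  invisible(x)
}
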