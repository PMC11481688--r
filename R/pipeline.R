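# End-to-end orchestration: simulate (or read) -> group -> cluster ->
# features -> phenotype -> correct -> report, plus the flow variant.

#' Pipeline configuration
#'
#' One configuration object holding every stage's parameters.  All
#' instrument-derived constants are named defaults here, never hard-coded
#' downstream: frame gap 2, max distance 30 nm, link radius 150 nm, more
#' than 15 molecules per cluster, more than 3 molecules per channel within
#' 150 nm, circularity window [0.43, 1] (skew window [1, 2.9] available
#' but opt-in; see the methods vignette), 50 nm size-histogram bins.
#'
#' @param imaging an [imaging_sim_config()] for the EV sample (or `NULL`
#'   when reading `input_locs`).
#' @param control an [imaging_sim_config()] for the antibody-only control
#'   used for the aggregate size reference and classifier training.
#' @param input_locs,input_control optional CSV paths read with
#'   [read_localizations()] instead of simulating.
#' @param frame_gap,max_distance_nm temporal grouping parameters.
#' @param link_radius_nm,min_molecules spatial clustering parameters.
#' @param phenotype_threshold,phenotype_radius_nm positivity rule.
#' @param skew_range optional inclusive skew window (`NULL` = no skew
#'   filtering, the default); `circ_range` inclusive circularity window.
#' @param pixel_nm feature discretisation pixel.
#' @param bin_width_nm size-histogram bin width.
#' @param correction `"size_fit"`, `"ml"`, or `"both"`.
#' @param ml_model classifier family for the ML route.
#' @param seed integer master seed (recorded in the manifest).
#' @return a list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(imaging = imaging_sim_config(),
                            control = imaging_sim_config(n_ev = 0L,
                                                         n_aggregate = 300L,
                                                         seed = 2L),
                            input_locs = NULL, input_control = NULL,
                            frame_gap = 2L, max_distance_nm = 30,
                            link_radius_nm = 150, min_molecules = 15L,
                            phenotype_threshold = 3L,
                            phenotype_radius_nm = 150,
                            skew_range = NULL, circ_range = c(0.43, 1),
                            pixel_nm = 10, bin_width_nm = 50,
                            correction = c("both", "size_fit", "ml"),
                            ml_model = "random_forest", seed = 1L) {
  correction <- match.arg(correction)
  structure(as.list(environment()), class = "pipeline_config")
}

# Run clustering + features + phenotyping on one localization table.
analyse_locs <- function(locs, cfg) {
  mols <- group_temporally(locs, frame_gap = cfg$frame_gap,
                           max_distance = cfg$max_distance_nm)
  cl <- detect_clusters(mols, link_radius = cfg$link_radius_nm,
                        min_molecules = cfg$min_molecules)
  feats <- compute_features(cl, locs,
                            loc_molecule = attr(mols, "loc_molecule"),
                            pixel_nm = cfg$pixel_nm)
  keep <- feats$circularity >= cfg$circ_range[1] &
    feats$circularity <= cfg$circ_range[2]
  if (!is.null(cfg$skew_range)) {
    keep <- keep & shape_filter(feats, skew_range = cfg$skew_range,
                                circ_range = cfg$circ_range)
  }
  calls <- call_phenotypes(cl, threshold = cfg$phenotype_threshold,
                           radius_nm = cfg$phenotype_radius_nm)
  calls <- calls[keep, , drop = FALSE]
  feats <- feats[keep, , drop = FALSE]
  feats$phenotype <- calls$phenotype[match(feats$cluster_id,
                                           calls$cluster_id)]
  list(molecules = mols, clusters = cl, features = feats, calls = calls,
       counts = c(localizations = nrow(locs), molecules = nrow(mols),
                  clusters = nrow(cl$clusters), shape_kept = sum(keep)))
}

#' Run the imaging pipeline end to end
#'
#' Simulates (or reads) the EV sample and the antibody-only control,
#' groups and clusters both, calls phenotypes, and applies the requested
#' false-positive corrections: the lognormal size decomposition (EV
#' reference from the sample's double positives, aggregate reference from
#' the control) and/or the feature classifier (trained double positives vs
#' control).
#'
#' @param cfg a [pipeline_config()].
#' @param output_dir optional directory for report artifacts (cluster and
#'   feature CSVs, summary CSV, decomposition JSON-like text, manifest).
#' @return list of class `"ev_pipeline_result"`: `summary` (raw
#'   `phenotype_summary`), `size_corrected`, `ml_corrected` (either may be
#'   `NULL` per `cfg$correction`), `decompositions`, `model`, `metrics`
#'   (held-out evaluation of the classifier), `sample`, `control` (stage
#'   objects), and `manifest` (seed + per-stage counts).
#' @export
run_imaging_pipeline <- function(cfg = pipeline_config(), output_dir = NULL) {
  stopifnot(inherits(cfg, "pipeline_config"))
  if (!is.null(cfg$input_locs)) {
    sample_locs <- read_localizations(cfg$input_locs)
    sample_truth <- NULL
  } else {
    sim <- simulate_imaging(cfg$imaging)
    sample_locs <- sim$locs
    sample_truth <- sim$truth
  }
  if (!is.null(cfg$input_control)) {
    control_locs <- read_localizations(cfg$input_control)
  } else {
    control_locs <- simulate_imaging(cfg$control)$locs
  }
  smp <- analyse_locs(sample_locs, cfg)
  ctl <- analyse_locs(control_locs, cfg)
  summary_raw <- if (nrow(smp$calls) > 0) {
    summarize_phenotypes(smp$calls)
  } else {
    warning("no clusters passed the filters: empty phenotype summary")
    structure(list(counts = c(CD81_only = 0, CD9_only = 0,
                              double_positive = 0, none = 0),
                   fractions = stats::setNames(rep(NA_real_, 3),
                                               phenotype_levels()[1:3]),
                   n_positive = 0, n_fov = NA_integer_,
                   fov_fractions = NULL, fov_mean = NULL, fov_sd = NULL),
              class = "phenotype_summary")
  }
  dp_feats <- smp$features[!is.na(smp$features$phenotype) &
                             smp$features$phenotype == "double_positive", ]
  sp_feats <- smp$features[!is.na(smp$features$phenotype) &
                             smp$features$phenotype %in%
                             c("CD81_only", "CD9_only"), ]
  ab_feats <- ctl$features
  size_corrected <- NULL; ml_corrected <- NULL
  decomps <- NULL; model <- NULL; metrics <- NULL
  can_correct <- nrow(dp_feats) > 0 && nrow(ab_feats) > 0 &&
    summary_raw$n_positive > 0
  if (cfg$correction %in% c("size_fit", "both") && can_correct) {
    ev_ref <- fit_lognormal(dp_feats$radius_of_gyration,
                            bin_width = cfg$bin_width_nm)
    ab_ref <- fit_lognormal(ab_feats$radius_of_gyration,
                            bin_width = cfg$bin_width_nm)
    decomp_of <- function(ph) {
      r <- sp_feats$radius_of_gyration[sp_feats$phenotype == ph]
      if (length(r) >= 2) {
        decompose_single_positive(r, ev_ref, ab_ref,
                                  bin_width = cfg$bin_width_nm)
      } else {
        NULL
      }
    }
    d81 <- decomp_of("CD81_only"); d9 <- decomp_of("CD9_only")
    decomps <- list(ev_ref = ev_ref, ab_ref = ab_ref,
                    CD81_only = d81, CD9_only = d9)
    size_corrected <- correct_summary(
      summary_raw,
      w_ev_cd9 = if (is.null(d9)) 1 else d9$w_ev,
      w_ev_cd81 = if (is.null(d81)) 1 else d81$w_ev)
  }
  if (cfg$correction %in% c("ml", "both") && can_correct) {
    ts <- build_training_set(dp_feats, ab_feats)
    split <- with_seed(cfg$seed + 1L, train_test_split(ts, 0.2))
    model <- train_model(split$train, model = cfg$ml_model, seed = cfg$seed)
    metrics <- tryCatch(evaluate_model(model, split$test),
                        error = function(e) NULL)
    ml_corrected <- if (nrow(sp_feats) > 0) {
      ml_correct(summary_raw, sp_feats, model)
    } else {
      NULL
    }
  }
  manifest <- list(seed = cfg$seed,
                   correction = cfg$correction,
                   counts = list(sample = smp$counts, control = ctl$counts),
                   positives = summary_raw$n_positive)
  res <- structure(list(summary = summary_raw,
                        size_corrected = size_corrected,
                        ml_corrected = ml_corrected,
                        decompositions = decomps, model = model,
                        metrics = metrics,
                        sample = smp, control = ctl,
                        sample_truth = sample_truth,
                        manifest = manifest),
                   class = "ev_pipeline_result")
  if (!is.null(output_dir)) write_pipeline_report(res, cfg, output_dir)
  res
}

#' Stratified train/test split of a training set
#'
#' @param ts an `"ev_training_set"`.
#' @param test_fraction held-out fraction per class (default 0.2).
#' @return list with `train` and `test` training sets.
#' @export
train_test_split <- function(ts, test_fraction = 0.2) {
  take <- function(rows) {
    n_test <- max(1L, round(length(rows) * test_fraction))
    sample(rows, n_test)
  }
  test_idx <- sort(c(take(which(ts$y == 0L)), take(which(ts$y == 1L))))
  subset_ts <- function(rows) {
    structure(list(x = ts$x[rows, , drop = FALSE], y = ts$y[rows],
                   provenance = ts$provenance[rows]),
              class = "ev_training_set")
  }
  list(train = subset_ts(setdiff(seq_along(ts$y), test_idx)),
       test = subset_ts(test_idx))
}

write_pipeline_report <- function(res, cfg, output_dir) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  write_clusters(res$sample$clusters,
                 file.path(output_dir, "clusters_sample.csv"))
  utils::write.csv(res$sample$features,
                   file.path(output_dir, "features_sample.csv"),
                   row.names = FALSE)
  summary_df <- data.frame(phenotype = names(res$summary$fractions),
                           count = as.numeric(
                             res$summary$counts[names(res$summary$fractions)]),
                           fraction = as.numeric(res$summary$fractions))
  utils::write.csv(summary_df, file.path(output_dir, "summary_raw.csv"),
                   row.names = FALSE)
  for (nm in c("size_corrected", "ml_corrected")) {
    obj <- res[[nm]]
    if (!is.null(obj)) {
      df <- data.frame(phenotype = names(obj$fractions),
                       count = as.numeric(obj$counts),
                       fraction = as.numeric(obj$fractions))
      utils::write.csv(df, file.path(output_dir, paste0(nm, ".csv")),
                       row.names = FALSE)
    }
  }
  manifest_lines <- c(
    sprintf("seed=%d", res$manifest$seed),
    sprintf("correction=%s", res$manifest$correction),
    sprintf("sample.%s=%d", names(res$manifest$counts$sample),
            res$manifest$counts$sample),
    sprintf("control.%s=%d", names(res$manifest$counts$control),
            res$manifest$counts$control),
    sprintf("positives=%d", res$manifest$positives))
  writeLines(manifest_lines, file.path(output_dir, "manifest.txt"))
  invisible(output_dir)
}

#' @export
print.ev_pipeline_result <- function(x, ...) {
  cat("<ev_pipeline_result>\n")
  print(x$summary)
  if (!is.null(x$size_corrected)) print(x$size_corrected)
  if (!is.null(x$ml_corrected)) print(x$ml_corrected)
  invisible(x)
}

#' Run the flow pipeline end to end
#'
#' Simulates (or reads) a flow trace, detects SSC events, calls phenotype
#' percentages, and recalculates them without double negatives.
#'
#' @param cfg a [flow_sim_config()] (simulation mode) or `NULL` with
#'   `input_trace` a CSV path (`time_ms, ssc, fl1, fl2`).
#' @param k_sigma detection-threshold multiplier (default 5).
#' @param fl1_threshold,fl2_threshold fluorescence positivity thresholds;
#'   default `5 * noise_sd` in simulation mode (generator-known truth
#'   scale), required when reading a trace.
#' @param min_events reliability floor (default 1000).
#' @param input_trace optional trace CSV path.
#' @return list of class `"flow_pipeline_result"`: `events`,
#'   `percentages` (quadruple), `recalculated` (triple, `NULL` when all
#'   events are double negative), `truth` (simulation only), `manifest`.
#' @export
run_flow_pipeline <- function(cfg = flow_sim_config(), k_sigma = 5,
                              fl1_threshold = NULL, fl2_threshold = NULL,
                              min_events = 1000L, input_trace = NULL) {
  truth <- NULL
  if (!is.null(input_trace)) {
    df <- utils::read.csv(input_trace)
    trace <- flow_trace(df$time_ms, df$ssc, df$fl1, df$fl2)
    if (is.null(fl1_threshold) || is.null(fl2_threshold)) {
      stop("fluorescence thresholds are required when reading a trace")
    }
  } else {
    stopifnot(inherits(cfg, "flow_sim_config"))
    sim <- simulate_flow(cfg)
    trace <- sim$trace
    truth <- sim$truth
    if (is.null(fl1_threshold)) fl1_threshold <- 5 * cfg$noise_sd
    if (is.null(fl2_threshold)) fl2_threshold <- 5 * cfg$noise_sd
  }
  events <- detect_events(trace, k_sigma = k_sigma)
  if (nrow(events) == 0L) {
    return(structure(list(events = events, percentages = NULL,
                          recalculated = NULL, truth = truth,
                          manifest = list(n_events = 0L, flagged = TRUE)),
                     class = "flow_pipeline_result"))
  }
  pct <- withCallingHandlers(
    call_flow_phenotypes(events, fl1_threshold, fl2_threshold,
                         min_events = min_events),
    warning = function(w) invokeRestart("muffleWarning"))
  recal <- if (pct[["double_negative"]] < 100) {
    recalc_without_double_negatives(pct)
  } else {
    NULL
  }
  structure(list(events = events, percentages = pct, recalculated = recal,
                 truth = truth,
                 manifest = list(n_events = nrow(events),
                                 flagged = isTRUE(attr(pct, "low_counts")),
                                 k_sigma = k_sigma,
                                 fl_thresholds = c(fl1_threshold,
                                                   fl2_threshold))),
            class = "flow_pipeline_result")
}

#' @export
print.flow_pipeline_result <- function(x, ...) {
  cat(sprintf("<flow_pipeline_result> %d event(s)%s\n",
              x$manifest$n_events,
              if (isTRUE(x$manifest$flagged)) " [low-count flag]" else ""))
  if (!is.null(x$percentages)) {
    cat("  percentages: ",
        paste(sprintf("%s=%.1f", names(x$percentages), x$percentages),
              collapse = "  "), "\n")
  }
  if (!is.null(x$recalculated)) {
    cat("  w/o DN:      ",
        paste(sprintf("%s=%.1f", names(x$recalculated), x$recalculated),
              collapse = "  "), "\n")
  }
  invisible(x)
}
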