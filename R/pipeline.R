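# End-to-end experiment orchestration: simulate/load -> preprocess ->
# features -> graphs -> leave-one-seizure-out training -> report.
#
# Records are processed one at a time (a 4020 s, 19-channel record is ~150 MB
# as doubles); only per-segment feature matrices and coherence matrices are
# retained. Per-record stage outputs are cached on disk keyed by a hash of
# everything upstream, so a rerun with an unchanged configuration reuses
# them.

obj_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, version = 2L)
  unname(tools::md5sum(f))
}

validate_section <- function(lst, fn, section) {
  if (is.null(lst)) return(list())
  allowed <- names(formals(fn))
  unknown <- setdiff(names(lst), allowed)
  if (length(unknown)) {
    stopf("unknown key(s) in config section '%s': %s", section,
          paste(unknown, collapse = ", "))
  }
  lst
}

#' Read and validate a run configuration
#'
#' JSON with optional sections \code{synthetic} (cohort_spec arguments),
#' \code{preprocess}, \code{features}, \code{edges} (\code{w_spatial},
#' \code{w_func}, \code{sigma}, \code{band}), \code{model}, \code{training},
#' \code{pipeline} (\code{interictal_stride}), plus top-level \code{seed},
#' \code{out_dir} and optional \code{data_dir} (plain-text cohort directory,
#' used when \code{synthetic} is absent). Unknown keys anywhere are rejected
#' before any computation.
#'
#' @param path path to the JSON config file, or an equivalent named list.
#' @return a validated list of class \code{run_config}.
#' @export
read_run_config <- function(path) {
  cfg <- if (is.character(path)) jsonlite::read_json(path, simplifyVector = TRUE) else path
  top_allowed <- c("seed", "out_dir", "data_dir", "synthetic", "preprocess",
                   "features", "edges", "model", "training", "pipeline")
  unknown <- setdiff(names(cfg), top_allowed)
  if (length(unknown)) stopf("unknown top-level config key(s): %s", paste(unknown, collapse = ", "))
  if (is.null(cfg$out_dir)) stopf("config needs an out_dir")
  if (is.null(cfg$synthetic) && is.null(cfg$data_dir)) {
    stopf("config needs either a synthetic section or a data_dir")
  }
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  cfg$synthetic <- validate_section(cfg$synthetic, cohort_spec, "synthetic")
  cfg$preprocess <- validate_section(cfg$preprocess, preprocess_config, "preprocess")
  cfg$features <- validate_section(cfg$features, feature_config, "features")
  edges_fn <- function(w_spatial = 0.5, w_func = 0.5, sigma = NULL, band = c(1, 40)) NULL
  cfg$edges <- validate_section(cfg$edges, edges_fn, "edges")
  cfg$model <- validate_section(cfg$model, model_config, "model")
  cfg$training <- validate_section(cfg$training, train_config, "training")
  pipeline_fn <- function(interictal_stride = 1L) NULL
  cfg$pipeline <- validate_section(cfg$pipeline, pipeline_fn, "pipeline")
  structure(cfg, class = "run_config")
}

# Per-segment feature extraction: node features + band-averaged coherence.
segment_features <- function(seg, fcfg, fs, band) {
  list(x = assemble_node_features(seg, fcfg, fs = fs),
       coh = coherence_matrix(seg$data, fs = fs, band = band),
       label = seg$label, seizure_group = seg$seizure_group,
       subject = seg$subject_id, t_start = seg$t_start)
}

# Fused montage + filter + normalize: one transpose in, per-derivation
# column work, one transpose out. Numerically identical to the exported
# stage-by-stage path (asserted in the tests) but with far less large-matrix
# traffic, which dominates on long recordings.
fast_preprocess <- function(rec, pp, spec = chb_bipolar_montage()) {
  labs <- canonical_label(rec$channel_labels)
  if (!all(is.finite(rec$data))) stopf("recording contains non-finite samples")
  already_bipolar <- any(grepl("-", labs, fixed = TRUE))
  hp <- butter_highpass(pp$hp_cutoff_hz, rec$fs)
  notches <- list()
  for (f0 in pp$notch_hz) {
    if (f0 >= rec$fs / 2) warnf("skipping infeasible notch at %g Hz (fs = %g Hz)", f0, rec$fs)
    else notches[[length(notches) + 1L]] <- iir_notch(f0, rec$fs)
  }
  rng <- pp$norm_range
  td <- t(rec$data)
  out <- matrix(0, nrow(td), nrow(spec))
  for (i in seq_len(nrow(spec))) {
    if (already_bipolar) {
      j <- match(spec$label[i], labs)
      if (is.na(j)) stopf("bipolar derivation %s missing from recording", spec$label[i])
      col <- td[, j]
    } else {
      ja <- match(spec$anode[i], labs)
      jc <- match(spec$cathode[i], labs)
      if (is.na(ja)) stopf("electrode %s missing from recording", spec$anode[i])
      if (is.na(jc)) stopf("electrode %s missing from recording", spec$cathode[i])
      col <- td[, ja] - td[, jc]
    }
    col <- filtfilt(hp$b, hp$a, col)
    for (nf in notches) col <- filtfilt(nf$b, nf$a, col)
    lo <- min(col); hi <- max(col)
    if (hi - lo < .Machine$double.eps) {
      warnf("constant channel(s) normalized to all zeros: %s", spec$label[i])
      col[] <- 0
    } else {
      col <- (col - lo) / (hi - lo) * (rng[2] - rng[1]) + rng[1]
    }
    out[, i] <- col
  }
  rec$data <- t(out)
  rec$channel_labels <- spec$label
  rec
}

process_record <- function(rec, subject_events, pp, fcfg, band, stride = 1L) {
  rec <- fast_preprocess(rec, pp)
  segs <- label_and_segment(rec, pp, subject_events = subject_events)
  if (stride > 1L && length(segs)) {
    lab <- vapply(segs, `[[`, integer(1), "label")
    keep0 <- which(lab == 0L)
    if (length(keep0)) keep0 <- keep0[seq(1L, length(keep0), by = stride)]
    segs <- segs[sort(c(which(lab == 1L), keep0))]
  }
  lapply(segs, segment_features, fcfg = fcfg, fs = rec$fs, band = band)
}

# Column-wise z-scoring: statistics from the training matrices only.
standardize_features <- function(train_x, test_x) {
  stacked <- do.call(rbind, train_x)
  mu <- colMeans(stacked)
  sdv <- apply(stacked, 2L, stats::sd)
  sdv[sdv == 0 | !is.finite(sdv)] <- 1
  z <- function(m) sweep(sweep(m, 2L, mu, "-"), 2L, sdv, "/")
  list(train = lapply(train_x, z), test = lapply(test_x, z))
}

#' Run a full experiment from a configuration
#'
#' Executes simulate/load, preprocessing, feature extraction, graph
#' construction, per-subject leave-one-seizure-out training and evaluation,
#' and writes the report directory: a per-subject summary CSV in the usual
#' sensitivity/AUC layout, per-fold metrics, ROC points, a train/test
#' feature-distribution overlap report, fold checkpoints and a manifest
#' (config, hash, seeds, package version). Deterministic for a fixed config.
#'
#' @param config a path to a JSON run configuration, or the equivalent list
#'   (see \code{\link{read_run_config}}).
#' @return (invisibly) a list with \code{summary}, \code{fold_results} and
#'   \code{out_dir}.
#' @export
run_experiment <- function(config) {
  cfg <- if (inherits(config, "run_config")) config else read_run_config(config)
  out_dir <- cfg$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cache_dir <- file.path(out_dir, "cache")
  dir.create(cache_dir, showWarnings = FALSE)

  pp <- do.call(preprocess_config, cfg$preprocess)
  fcfg <- do.call(feature_config, cfg$features)
  band <- cfg$edges$band %||% c(1, 40)
  stride <- as.integer(cfg$pipeline$interictal_stride %||% 1L)
  synthetic <- length(cfg$synthetic) > 0 || is.null(cfg$data_dir)

  # ---- stage 1+2: data, preprocessing, features (record by record) ----
  if (synthetic) {
    spec <- do.call(cohort_spec, c(cfg$synthetic, list(seed = cfg$seed)))
    plan <- cohort_plan(spec)
    subjects <- unique(plan$subject)
    subject_events <- lapply(subjects, function(s) plan_subject_events(plan, s, spec))
    names(subject_events) <- subjects
    get_record <- function(i) generate_planned_recording(spec, plan[i, ])
    upstream <- list(spec = unclass(spec), pp = unclass(pp), fcfg = unclass(fcfg),
                     band = band, stride = stride)
  } else {
    paths <- sort(list.files(cfg$data_dir, pattern = "\\.csv$", full.names = TRUE))
    paths <- paths[file.exists(paste0(paths, ".json"))]
    if (!length(paths)) stopf("no recordings found in %s", cfg$data_dir)
    headers <- lapply(paths, function(p) jsonlite::read_json(paste0(p, ".json"), simplifyVector = TRUE))
    plan <- data.frame(subject = vapply(headers, `[[`, character(1), "subject_id"),
                       record = basename(paths), path = paths)
    subjects <- unique(plan$subject)
    subject_events <- lapply(subjects, function(s) {
      hs <- headers[plan$subject == s]
      ev <- do.call(rbind, lapply(hs, function(h) {
        if (!length(h$events$onset_s)) return(NULL)
        data.frame(onset_s = as.numeric(h$events$onset_s) + h$start_s,
                   offset_s = as.numeric(h$events$offset_s) + h$start_s)
      }))
      if (is.null(ev)) ev <- data.frame(onset_s = numeric(), offset_s = numeric())
      ev <- ev[order(ev$onset_s), , drop = FALSE]
      ev$group <- seq_len(nrow(ev))
      ev
    })
    names(subject_events) <- subjects
    get_record <- function(i) read_text_recording(plan$path[i])
    upstream <- list(paths = paths, mtime = file.mtime(paths), pp = unclass(pp),
                     fcfg = unclass(fcfg), band = band, stride = stride)
  }

  feats <- vector("list", nrow(plan))
  for (i in seq_len(nrow(plan))) {
    key <- obj_hash(list(upstream = upstream, record = plan$record[i]))
    cache_file <- file.path(cache_dir, paste0(key, ".rds"))
    if (file.exists(cache_file)) {
      feats[[i]] <- readRDS(cache_file)
    } else {
      rec <- get_record(i)
      feats[[i]] <- process_record(rec, subject_events[[plan$subject[i]]],
                                   pp, fcfg, band, stride)
      saveRDS(feats[[i]], cache_file, version = 2L)
      rm(rec)
    }
  }
  segs <- unlist(feats, recursive = FALSE)
  if (!length(segs)) stopf("stage features: no labeled segments produced")

  # ---- stage 3: graphs + LOOCV training per subject ----
  dist_mat <- geodesic_matrix(montage_positions())
  w_spatial <- cfg$edges$w_spatial %||% 0.5
  w_func <- cfg$edges$w_func %||% 0.5
  sigma <- cfg$edges$sigma
  model_cfg <- do.call(model_config, cfg$model)
  fold_rows <- list()
  roc_rows <- list()
  drift_rows <- list()
  models_dir <- file.path(out_dir, "models")
  dir.create(models_dir, showWarnings = FALSE)

  seg_subject <- vapply(segs, `[[`, character(1), "subject")
  for (si in seq_along(subjects)) {
    s <- subjects[si]
    ss <- segs[seg_subject == s]
    meta <- data.frame(label = vapply(ss, `[[`, integer(1), "label"),
                       seizure_group = vapply(ss, `[[`, numeric(1), "seizure_group"))
    folds <- make_loocv_folds(meta)
    for (fi in seq_along(folds)) {
      fold <- folds[[fi]]
      zs <- standardize_features(lapply(ss[fold$train], `[[`, "x"),
                                 lapply(ss[fold$test], `[[`, "x"))
      mk_graph <- function(feat_x, seg) {
        as_graph_sample(feat_x, build_adjacency(dist_mat, seg$coh, w_spatial,
                                                w_func, sigma), seg$label)
      }
      g_train <- Map(mk_graph, zs$train, ss[fold$train])
      g_test <- Map(mk_graph, zs$test, ss[fold$test])
      tcfg <- do.call(train_config,
                      c(cfg$training, list(seed = child_seed(cfg$seed, 100L * si + fi))))
      fit <- train_fold(g_train, tcfg, model_cfg)
      save_gcn(fit$params, fit$cfg,
               file.path(models_dir, sprintf("%s_fold%02d.json", s, fi)))
      p <- predict_gcn(fit, g_test)
      y <- meta$label[fold$test]
      cc <- confusion_counts(p, y)
      auc <- if (length(unique(y)) == 2L) {
        ra <- roc_auc(p, y)
        roc_rows[[length(roc_rows) + 1L]] <-
          cbind(subject = s, fold = fi, ra$roc)
        ra$auc
      } else NA_real_
      fold_rows[[length(fold_rows) + 1L]] <- data.frame(
        subject = s, fold = fi, group = fold$group, n_test = length(y),
        sensitivity = sensitivity(cc[["tp"]], cc[["fn"]]), auc = auc)
      dr <- feature_distribution_report(do.call(rbind, zs$train),
                                        do.call(rbind, zs$test))
      drift_rows[[length(drift_rows) + 1L]] <- cbind(subject = s, fold = fi, dr)
    }
  }

  fold_results <- do.call(rbind, fold_rows)
  summary_tab <- aggregate_results(fold_results)
  utils::write.csv(fold_results, file.path(out_dir, "fold_results.csv"), row.names = FALSE)
  utils::write.csv(summary_tab, file.path(out_dir, "summary.csv"), row.names = FALSE)
  utils::write.csv(do.call(rbind, roc_rows), file.path(out_dir, "roc_points.csv"),
                   row.names = FALSE)
  utils::write.csv(do.call(rbind, drift_rows), file.path(out_dir, "feature_drift.csv"),
                   row.names = FALSE)
  manifest <- list(config = unclass(cfg), config_hash = obj_hash(unclass(cfg)),
                   seed = cfg$seed,
                   package_version = as.character(utils::packageVersion("seizegraph")),
                   r_version = R.version.string)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(summary = summary_tab, fold_results = fold_results, out_dir = out_dir))
}
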