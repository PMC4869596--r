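# Pipeline configuration and end-to-end orchestration: preprocessing ->
# band power -> PSI matrices -> density sweep -> group statistics.

#' Pipeline configuration
#'
#' All analysis constants live here as defaults rather than being
#' hard-coded in the stages: broadband filter edges, artifact criteria,
#' analysis and baseline windows, bands, the edge-count sweep, the null
#' count, and the density level used for node-degree statistics.
#'
#' @param filter_low,filter_high broadband Butterworth passband, Hz
#' @param filter_order Butterworth prototype order per pass
#' @param notch notch center Hz or NULL
#' @param criteria an [artifact_criteria()]
#' @param analysis_window ms window for power/PSI (default 200..700)
#' @param baseline_window ms window labelling the pre-cue reference segment
#' @param bands named band list
#' @param K_sweep edge-count sweep (default 60..180 step 20)
#' @param n_random rewired nulls per level (default 20)
#' @param degree_K edge count for node-degree statistics (default 120)
#' @param alpha significance level
#' @param min_levels multi-density rule minimum
#' @param relative_change_method see [relative_change()]
#' @param clustering_mode,path_mode see [clustering_coefficient()],
#'   [char_path_length()]
#' @param broadband_filter apply the broadband filter stage (disable for
#'   already band-limited synthetic data)
#' @param seed master seed for all stochastic stages
#' @return object of class `pipeline_config`
#' @export
pipeline_config <- function(filter_low = 0.1, filter_high = 40,
                            filter_order = 2, notch = NULL,
                            criteria = artifact_criteria(),
                            analysis_window = c(200, 700),
                            baseline_window = c(-500, 0),
                            bands = default_bands(),
                            K_sweep = seq(60, 180, by = 20),
                            n_random = 20,
                            degree_K = 120,
                            alpha = 0.05,
                            min_levels = 3,
                            relative_change_method = "symmetric",
                            clustering_mode = "onnela",
                            path_mode = "harmonic",
                            broadband_filter = TRUE,
                            seed = 1) {
  stopifnot(all(K_sweep > 0), n_random >= 1, degree_K > 0)
  structure(as.list(environment()), class = "pipeline_config")
}

#' Write / read a pipeline configuration as JSON
#' @param config a [pipeline_config()]
#' @param path file path
#' @return `path` / a [pipeline_config()]
#' @export
write_config <- function(config, path) {
  x <- unclass(config)
  x$criteria <- unclass(x$criteria)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$criteria <- do.call(artifact_criteria, as.list(x$criteria))
  if (is.list(x$bands)) x$bands <- lapply(x$bands, as.numeric)
  do.call(pipeline_config, x)
}

log_stage <- function(verbose, ...) {
  if (verbose) message(sprintf(...))
  invisible(NULL)
}

#' Preprocess one subject's epochs
#'
#' Broadband zero-phase filtering (optional), re-referencing when the
#' montage reference channels are present, artifact rejection, and
#' per-condition ERP subtraction. EOG channels are used for rejection and
#' then dropped.
#'
#' @param epochs an [epochset()]
#' @param config a [pipeline_config()]
#' @param montage a [montage()]
#' @param verbose log one line per stage with input/output counts
#' @return list: `epochs` (induced activity, analysis channels only),
#'   `rejection` (report table), `erps`
#' @export
preprocess_subject <- function(epochs, config = pipeline_config(),
                               montage = default_montage(),
                               verbose = FALSE) {
  ne0 <- n_epochs(epochs)
  if (config$broadband_filter) {
    epochs <- bandpass_filter(epochs, config$filter_low, config$filter_high,
                              config$filter_order, notch = config$notch)
    log_stage(verbose, "filter: %g-%g Hz on %d epochs",
              config$filter_low, config$filter_high, ne0)
  }
  if (length(montage$reference) && all(montage$reference %in% epochs$channels)) {
    epochs <- rereference(epochs, montage$reference,
                          keep = intersect(montage$eog, epochs$channels))
    log_stage(verbose, "rereference: mean of %s; %d channels retained",
              paste(montage$reference, collapse = "+"), length(epochs$channels))
  }
  rej <- reject_artifacts(epochs, config$criteria, eog = montage$eog)
  epochs <- rej$epochs
  log_stage(verbose, "artifact rejection: %d of %d epochs kept",
            n_epochs(epochs), ne0)
  for (cond in unique(epochs$condition)) {
    if (!sum(epochs$condition == cond)) stop("empty condition: ", cond)
  }
  if (!n_epochs(epochs)) stop("all epochs rejected")
  eog_present <- intersect(montage$eog, epochs$channels)
  if (length(eog_present)) {
    epochs <- select_channels(epochs, setdiff(epochs$channels, eog_present))
  }
  ind <- remove_evoked(epochs)
  log_stage(verbose, "ERP subtraction: %d condition(s)", length(ind$erps))
  list(epochs = ind$epochs, rejection = rej$report, erps = ind$erps)
}

#' Run the full analysis pipeline on a multi-subject dataset
#'
#' For each subject: preprocessing, Hamming-FFT band power with percent
#' change versus Baseline, per-band/per-condition PSI matrices (analytic
#' signal over the full epoch, phases cropped to the analysis window), and
#' a small-world density sweep per condition. Then group statistics:
#' mixed-design ANOVA (Task within, Age between) on gamma/lambda/sigma at
#' every density level with the multi-density significance rule, and ROI
#' node-degree contrasts at `degree_K`.
#'
#' The result is a pure function of (inputs, config): all stochastic
#' stages (rewired nulls) derive their seeds from `config$seed`.
#'
#' @param subjects list of [epochset()] objects (one per subject, with
#'   `group` set) or of `generate_epochs()` results
#' @param config a [pipeline_config()]
#' @param montage a [montage()]
#' @param verbose log stage lines
#' @return a result bundle (list): `power`, `pct_change`, `psi`,
#'   `metrics` (sweep table), `anova` (per band/metric/K), `rule`
#'   (multi-density flags), `roi_degree`, `roi_tests`, `tmaps`,
#'   `rejection`, `config`
#' @export
run_pipeline <- function(subjects, config = pipeline_config(),
                         montage = default_montage(), verbose = FALSE) {
  subjects <- lapply(subjects, function(s) if (inherits(s, "epochset")) s else s$epochs)
  power_tabs <- list(); pct_tabs <- list(); psi_all <- list()
  metric_tabs <- list(); degree_tabs <- list(); rej_tabs <- list()
  si <- 0L
  for (es in subjects) {
    si <- si + 1L
    pp <- preprocess_subject(es, config, montage, verbose)
    ep <- pp$epochs
    rej_tabs[[si]] <- pp$rejection
    pw <- band_power(ep, config$bands, window = config$analysis_window)
    power_tabs[[si]] <- pw
    if ("Baseline" %in% ep$condition) {
      for (cond in setdiff(unique(ep$condition), "Baseline")) {
        pct_tabs[[length(pct_tabs) + 1L]] <- percent_change(pw, cond, "Baseline")
      }
    }
    psi_all[[ep$subject]] <- list()
    for (b in names(config$bands)) {
      ph <- instantaneous_phase(ep, config$bands[[b]],
                                window = config$analysis_window)
      for (cond in unique(ep$condition)) {
        m <- psi_matrix(ph, cond)
        psi_all[[ep$subject]][[b]][[cond]] <- m
        sweep <- density_sweep(m, config$K_sweep, config$n_random,
                               seed = (config$seed + si * 7919L) %% .Machine$integer.max)
        metric_tabs[[length(metric_tabs) + 1L]] <-
          sweep_table(sweep, subject = ep$subject, group = ep$group,
                      band = b, condition = cond)
        gK <- threshold_graph(m, config$degree_K)
        deg <- node_degree(gK)
        degree_tabs[[length(degree_tabs) + 1L]] <- data.table::data.table(
          subject = ep$subject, group = ep$group, band = b,
          condition = cond, channel = names(deg), degree = as.numeric(deg))
      }
    }
    log_stage(verbose, "subject %s: PSI + sweep done", ep$subject)
  }
  metrics <- data.table::rbindlist(metric_tabs)
  degrees <- data.table::rbindlist(degree_tabs)
  # group statistics on normalized metrics at every density level
  anova_rows <- list(); rule_rows <- list()
  two_groups <- length(unique(stats::na.omit(degrees$group))) >= 2
  if (two_groups) {
    for (b in names(config$bands)) {
      for (metric in c("gamma", "lambda", "sigma")) {
        pvals <- numeric(0)
        for (K in config$K_sweep) {
          sel <- which(metrics[["band"]] == b & metrics[["K"]] == K)
          d <- metrics[sel, ]
          an <- mixed_anova(data.table::data.table(
            subject = d$subject, group = d$group, task = d$condition,
            value = d[[metric]]))
          an$band <- b; an$metric <- metric; an$K <- K
          anova_rows[[length(anova_rows) + 1L]] <- an
          pvals <- c(pvals, an$p[an$effect == "task"])
        }
        rule_rows[[length(rule_rows) + 1L]] <- data.table::data.table(
          band = b, metric = metric, effect = "task",
          n_significant = sum(pvals < config$alpha),
          significant = multi_density_rule(pvals, config$alpha,
                                           config$min_levels))
      }
    }
  }
  # ROI node-degree contrasts at degree_K
  roi_rows <- list(); roi_test_rows <- list(); tmaps <- list()
  for (b in names(config$bands)) {
    for (roi_name in names(montage$rois)) {
      roi <- montage$rois[[roi_name]]
      d <- degrees[degrees$band == b, ]
      agg <- d[, list(mean_degree = mean(degree[channel %in% roi])),
               by = c("subject", "group", "condition")]
      agg$band <- b; agg$roi <- roi_name; agg$K <- config$degree_K
      roi_rows[[length(roi_rows) + 1L]] <- agg
      if (all(c("Go", "NoGo") %in% agg$condition)) {
        for (g in unique(stats::na.omit(agg$group))) {
          ag <- agg[agg$group == g, ]
          go <- ag$mean_degree[ag$condition == "Go"][order(ag$subject[ag$condition == "Go"])]
          ng <- ag$mean_degree[ag$condition == "NoGo"][order(ag$subject[ag$condition == "NoGo"])]
          if (length(go) >= 2 && stats::var(go - ng) > 0) {
            tt <- paired_t(go, ng)
            tt$band <- b; tt$roi <- roi_name; tt$group <- g
            tt$effect <- "Go - NoGo"
            roi_test_rows[[length(roi_test_rows) + 1L]] <- tt
          }
        }
      }
    }
    d <- degrees[degrees$band == b, ]
    if (all(c("Go", "NoGo") %in% d$condition)) {
      tm <- degree_tmap(d, c("NoGo", "Go"))
      tm$band <- b
      tmaps[[length(tmaps) + 1L]] <- tm
    }
  }
  list(
    power = data.table::rbindlist(power_tabs),
    pct_change = if (length(pct_tabs)) data.table::rbindlist(pct_tabs) else NULL,
    psi = psi_all,
    metrics = metrics,
    anova = if (length(anova_rows)) data.table::rbindlist(anova_rows) else NULL,
    rule = if (length(rule_rows)) data.table::rbindlist(rule_rows) else NULL,
    roi_degree = data.table::rbindlist(roi_rows),
    roi_tests = if (length(roi_test_rows)) data.table::rbindlist(roi_test_rows) else NULL,
    tmaps = if (length(tmaps)) data.table::rbindlist(tmaps) else NULL,
    rejection = data.table::rbindlist(rej_tabs),
    config = config
  )
}
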