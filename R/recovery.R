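#' Plant amplicons at known topological-zone positions
#'
#' Places amplicons on distinct loops at arc positions chosen from the
#' analytic zone-band arithmetic: an amplicon with effective first-cut
#' rate `A = k0 * L * Hm(e)` (cuts/min between the left anchor and the
#' amplicon end) stays PCR-positive at time `t` while roughly
#' `A <= log(1/threshold) / t`, so consecutive timepoints delimit bands of
#' `A` corresponding to the zones D, P, VC, E. Two amplicons are placed
#' per zone band (at fixed geometric positions 0.45 and 0.7 within each
#' band, the D band capped below the loop-apex maximum, the E band
#' spanning a 4-fold range under its edge) and, optionally, one amplicon
#' embedded inside a MAR footprint (hazard 0, positive at every time).
#'
#' @param model a `nucleoid_model` with at least 9 loops.
#' @param config a [simulation_config()] (supplies the timepoints and
#'   detection threshold).
#' @param length_bp amplicon length (default 254 bp).
#' @param include_embedded also plant one amplicon inside a MAR footprint.
#' @return an [amplicon_table()]; names encode the intended band
#'   (`amp_D1`, ..., `amp_E3`).
#' @export
plant_amplicons_by_zone <- function(model, config, length_bp = 254L,
                                    include_embedded = TRUE) {
  stopifnot(inherits(model, "nucleoid_model"), inherits(config, "simulation_config"))
  times <- config$timepoints_min[config$timepoints_min > 0]
  if (length(times) < 2L) stopf("need at least two non-zero timepoints")
  cc <- log(1 / config$detection_threshold)
  edges <- cc / times                      # admissible upper A per zone
  zones <- c("D", "P", "VC", "E")[seq_along(times)]
  n_needed <- 2L * length(times) + as.integer(include_embedded)
  if (nrow(model$loops) < n_needed)
    stopf("model has %d loops but %d amplicons are planted", nrow(model$loops), n_needed)

  alpha <- model$profile$alpha
  k0 <- model$profile$k0
  qs <- c(0.45, 0.7)
  rows <- list()
  li <- 0L
  for (z in seq_along(times)) {
    hi <- edges[z]
    lo <- if (z < length(times)) edges[z + 1L] else edges[z] / 4
    for (q in qs) {
      li <- li + 1L
      lp <- model$loops[li, ]
      fl <- lp$mar_left_bp / lp$total_bp
      fr <- lp$mar_right_bp / lp$total_bp
      a_max <- k0 * lp$total_bp * .free_measure(0.5, fl, fr, alpha)
      hi_eff <- min(hi, 0.9 * a_max)
      if (hi_eff <= lo) stopf("zone band %s empty for loop %s", zones[z], lp$loop_id)
      A <- lo * (hi_eff / lo)^q
      e <- .free_measure_inv(A / (k0 * lp$total_bp), fl, fr, alpha)
      start <- max(round(e * lp$total_bp) - length_bp, round(fl * lp$total_bp))
      rows[[length(rows) + 1L]] <- data.frame(
        name = sprintf("amp_%s%d", zones[z], which(qs == q)),
        loop_id = lp$loop_id, start_bp = start, stringsAsFactors = FALSE)
    }
  }
  if (include_embedded) {
    li <- li + 1L
    lp <- model$loops[li, ]
    if (lp$mar_left_bp < length_bp + 2)
      stopf("MAR footprint of %s too short to embed a %d bp amplicon",
            lp$loop_id, length_bp)
    rows[[length(rows) + 1L]] <- data.frame(
      name = sprintf("amp_E%d", 3L), loop_id = lp$loop_id, start_bp = 1,
      stringsAsFactors = FALSE)
  }
  rows <- do.call(rbind, rows)
  amplicon_table(rows$name, rows$loop_id, rows$start_bp, length_bp, model = model)
}

#' Ground-truth zone calls from the analytic survival model
#'
#' The expected PCR pattern of each amplicon is its analytic survival
#' probability ([analytic_amplicon_survival()]) thresholded at the
#' detection threshold; the truth zone is the innermost positive zone of
#' that pattern. Also reports each amplicon's arc distance from the
#' nearer anchor.
#'
#' @param model a `nucleoid_model`.
#' @param amplicons an [amplicon_table()].
#' @param config a [simulation_config()].
#' @return data.frame: `amplicon`, `zone`, `rank`, `arc_distance`,
#'   `survival` columns per timepoint.
#' @export
true_zones <- function(model, amplicons, config) {
  times <- config$timepoints_min[config$timepoints_min > 0]
  scheme <- zone_scheme(times, c("D", "P", "VC", "E")[seq_along(times)])
  p <- analytic_amplicon_survival(model, amplicons, times)
  idx <- match(amplicons$loop_id, model$loops$loop_id)
  u_mid <- (amplicons$start_bp + amplicons$length_bp / 2) / model$loops$total_bp[idx]
  calls <- lapply(seq_len(nrow(amplicons)), function(i) {
    pattern <- ifelse(p[i, ] >= config$detection_threshold, "+", "-")
    cl <- call_position(pattern, scheme)
    data.frame(amplicon = amplicons$name[i], zone = cl$zone, rank = cl$rank,
               arc_distance = pmin(u_mid[i], 1 - u_mid[i]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, calls)
  cbind(out, as.data.frame(p))
}

#' End-to-end simulation-recovery experiment
#'
#' The full pipeline on synthetic ground truth: build a loop ensemble,
#' plant amplicons at known zone positions, simulate replicate PCR
#' detection under limited digestion, call positions from the simulated
#' score matrix, and compare with the analytic truth. The ensemble is
#' then aged with [evolve_nhos()] (mode and parameters from the config),
#' detection and mapping repeated, and the positional shift, loop-size
#' drift and embedded-fraction change reported.
#'
#' @param config a `run_config` list ([default_run_config()]).
#' @return list of class `recovery_report`: `accuracy` (fraction of
#'   amplicons whose called zone equals the truth zone), `n_amplicons`,
#'   `confusion` (truth x called table), `calls`, `truth`, `qc_failed`
#'   (TRUE when every call carries a QC violation), `evolved`
#'   (`median_rank_shift`, `shift_summary`, `mean_size_drift`,
#'   `embedded_before/after`, `loop_count_before/after`), `seed`,
#'   `runtime_sec`.
#' @export
run_recovery_experiment <- function(config = default_run_config()) {
  t0 <- proc.time()[["elapsed"]]
  profile <- accessibility_profile(config$k0, config$alpha)
  sim_cfg <- simulation_config(config$timepoints_min, config$n_nucleoids,
                               config$n_replicates, config$detection_threshold,
                               config$dnase_u_per_ml, config$seed)
  model <- build_nucleoid_ensemble(config$n_loops, config$mean_kbp, config$cv,
                                   config$embedded_target, profile,
                                   seed = config$seed)
  amplicons <- plant_amplicons_by_zone(model, sim_cfg,
                                       length_bp = config$amplicon_length_bp)
  truth <- true_zones(model, amplicons, sim_cfg)
  times <- sim_cfg$timepoints_min[sim_cfg$timepoints_min > 0]
  scheme <- zone_scheme(times, c("D", "P", "VC", "E")[seq_along(times)])
  scores <- simulate_amplicon_detection(model, amplicons, sim_cfg, age_label = "young")
  calls <- mapping_table(scores, scheme)
  qc_failed <- all(!is.na(calls$violation))
  ok <- !is.na(calls$zone)
  acc <- if (any(ok))
    mean(calls$zone[ok] == truth$zone[match(calls$amplicon[ok], truth$amplicon)])
  else 0
  confusion <- table(truth = truth$zone[match(calls$amplicon, truth$amplicon)],
                     called = factor(ifelse(is.na(calls$zone), "QC-fail", calls$zone)))

  # age the ensemble and repeat the mapping
  ev_params <- if (config$evolve_mode == "B_extension")
    list(extension = list(kind = "fraction", frac = config$extension_fraction))
  else list(p_sub = config$p_sub)
  aged <- evolve_nhos(model, config$evolve_mode, ev_params,
                      seed = substream_seed(config$seed, 17L))
  amp_aged <- remap_amplicons(amplicons, model, aged)
  sim_cfg_aged <- sim_cfg
  sim_cfg_aged$seed <- substream_seed(config$seed, 23L)
  scores_aged <- simulate_amplicon_detection(aged, amp_aged, sim_cfg_aged,
                                             age_label = "aged")
  calls_aged <- mapping_table(scores_aged, scheme)
  shift <- positional_shift(calls, calls_aged)
  surv_before <- model$loops$total_bp[model$loops$free_bp > 0]
  surv_after <- aged$loops$total_bp[aged$loops$free_bp > 0]
  evolved <- list(
    mode = config$evolve_mode,
    median_rank_shift = stats::median(shift$per_amplicon$delta_rank, na.rm = TRUE),
    shift_summary = shift$summary,
    mean_size_drift = mean(surv_after) / mean(surv_before) - 1,
    embedded_before = embedded_fraction(model),
    embedded_after = embedded_fraction(aged),
    loop_count_before = length(surv_before),
    loop_count_after = length(surv_after))

  structure(list(accuracy = acc, n_amplicons = nrow(amplicons),
                 confusion = confusion, calls = calls, truth = truth,
                 scores = scores, qc_failed = qc_failed, evolved = evolved,
                 seed = config$seed,
                 runtime_sec = proc.time()[["elapsed"]] - t0),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("Zone recovery: %d/%d amplicons correct (accuracy %.2f)%s\n",
              round(x$accuracy * x$n_amplicons), x$n_amplicons, x$accuracy,
              if (x$qc_failed) " [ALL CALLS FAILED QC]" else ""))
  print(x$confusion)
  ev <- x$evolved
  cat(sprintf(paste0("After %s: median rank shift %+g (away %d / toward %d / ",
                     "unchanged %d), mean loop-size drift %+.2f%%,\n",
                     "embedded fraction %.4f -> %.4f, loops %d -> %d\n"),
              ev$mode, ev$median_rank_shift, ev$shift_summary[["away"]],
              ev$shift_summary[["toward"]], ev$shift_summary[["unchanged"]],
              100 * ev$mean_size_drift, ev$embedded_before, ev$embedded_after,
              ev$loop_count_before, ev$loop_count_after))
  cat(sprintf("Seed %d, runtime %.1f s\n", x$seed, x$runtime_sec))
  invisible(x)
}

#' Write a recovery report's tables to a directory
#'
#' @param report a `recovery_report`.
#' @param out_dir destination directory (created if missing).
#' @return named character vector of files written, invisibly.
#' @export
write_recovery_report <- function(report, out_dir) {
  stopifnot(inherits(report, "recovery_report"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  files <- c(calls = file.path(out_dir, "position_calls.tsv"),
             truth = file.path(out_dir, "truth_zones.tsv"),
             scores = file.path(out_dir, "score_matrix.tsv"),
             summary = file.path(out_dir, "recovery_summary.yaml"))
  utils::write.table(report$calls, files[["calls"]], sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  utils::write.table(report$truth, files[["truth"]], sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  write_score_matrix(report$scores, files[["scores"]])
  ev <- report$evolved
  yaml::write_yaml(list(accuracy = report$accuracy,
                        n_amplicons = report$n_amplicons,
                        qc_failed = report$qc_failed, seed = report$seed,
                        evolve = list(mode = ev$mode,
                                      median_rank_shift = ev$median_rank_shift,
                                      mean_size_drift = ev$mean_size_drift,
                                      embedded_before = ev$embedded_before,
                                      embedded_after = ev$embedded_after)),
                   files[["summary"]])
  invisible(files)
}
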