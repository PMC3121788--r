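#' Expected NM-attached DNA fraction for one loop (analytic)
#'
#' Closed-form/quadrature oracle for the Monte-Carlo digestion simulator.
#' Cuts fall on a loop as a non-homogeneous Poisson process with per-bp
#' hazard `k0 * a(d(u))` (see [accessibility_profile()]); a position at arc
#' coordinate `u` remains on an NM-attached fragment iff no cut separates
#' it from either anchor, which has probability
#' \deqn{e^{-H(0,u)} + e^{-H(u,1)} - e^{-H(0,1)},}
#' with \eqn{H(x,y)} the cumulative cut hazard (in cuts) over the arc
#' interval. The attached mass fraction integrates this over the free loop;
#' MAR footprint mass is always attached. The cumulative hazard is exact
#' (closed form); the outer integral is numerical to relative tolerance
#' 1e-6.
#'
#' In the uniform-hazard limit (`alpha = 0`, no footprints) this reduces to
#' `(2/(kL t))(1 - exp(-kL t)) - exp(-kL t)`.
#'
#' @param loop a single loop: list or one-row data.frame with `total_bp`,
#'   `mar_left_bp`, `mar_right_bp`.
#' @param profile an [accessibility_profile()].
#' @param t digestion time(s) in minutes (>= 0); vectorized.
#' @return expected attached mass fraction(s) in \[0, 1\].
#' @examples
#' lp <- list(total_bp = 42000, mar_left_bp = 420, mar_right_bp = 420)
#' analytic_attached_fraction(lp, accessibility_profile(), t = c(0, 5, 60))
#' @export
analytic_attached_fraction <- function(loop, profile, t) {
  stopifnot(inherits(profile, "accessibility_profile"))
  if (any(t < 0)) stopf("digestion time must be >= 0")
  L <- as.numeric(loop$total_bp)
  fl <- as.numeric(loop$mar_left_bp) / L
  fr <- as.numeric(loop$mar_right_bp) / L
  alpha <- profile$alpha
  rate <- profile$k0 * L
  Tm <- .free_measure(1, fl, fr, alpha)

  vapply(t, function(tt) {
    if (tt == 0 || rate == 0 || Tm == 0) return(1)
    Htot <- rate * tt * Tm
    f <- function(u) {
      H0u <- rate * tt * .free_measure(u, fl, fr, alpha)
      exp(-H0u) + exp(-(Htot - H0u)) - exp(-Htot)
    }
    # split at the apex where the integrand has a kink
    int <- stats::integrate(f, fl, 0.5, rel.tol = 1e-8, subdivisions = 500L)$value +
      stats::integrate(f, 0.5, 1 - fr, rel.tol = 1e-8, subdivisions = 500L)$value
    fl + fr + int
  }, numeric(1))
}

#' Analytic amplicon survival probability
#'
#' Probability that an amplicon interval is both uncut and on an
#' NM-attached fragment at digestion time `t`: with `s`,`e` the interval
#' bounds in arc fraction, the amplicon survives attached iff there is no
#' cut in (0, e) (left-anchored) or none in (s, 1) (right-anchored).
#'
#' @param model a `nucleoid_model`.
#' @param amplicons an [amplicon_table()].
#' @param t digestion time(s) in minutes.
#' @return matrix of survival probabilities, amplicons x timepoints.
#' @export
analytic_amplicon_survival <- function(model, amplicons, t) {
  validate_amplicons(amplicons, model)
  idx <- match(amplicons$loop_id, model$loops$loop_id)
  arcs <- .loop_arcs(model$loops[idx, , drop = FALSE])
  alpha <- model$profile$alpha
  s <- amplicons$start_bp / arcs$L
  e <- (amplicons$start_bp + amplicons$length_bp) / arcs$L
  rate <- model$profile$k0 * arcs$L
  Tm <- .free_measure(1, arcs$fl, arcs$fr, alpha)
  Hs <- .free_measure(s, arcs$fl, arcs$fr, alpha)
  He <- .free_measure(e, arcs$fl, arcs$fr, alpha)
  out <- sapply(t, function(tt) {
    exp(-rate * tt * He) + exp(-rate * tt * (Tm - Hs)) - exp(-rate * tt * Tm)
  })
  out <- matrix(out, nrow = nrow(amplicons),
                dimnames = list(amplicons$name, paste0("t", t)))
  out
}

#' Simulate limited DNase I digestion of a nucleoid ensemble
#'
#' Monte-Carlo realization of the outside-in digestion rule: distal loop
#' regions are cut first, NM-proximal regions later, MAR footprints never.
#' For every loop x nucleoid realization and every inter-timepoint window,
#' the number of new cuts is Poisson with mean equal to the accessibility-
#' weighted hazard mass of the window, and the joint (min, max) cut
#' positions are drawn by exact order-statistic inversion of the
#' accessibility measure. A fragment is NM-attached iff it contains an
#' anchor, so the attached mass of a realization is
#' `u_min + (1 - u_max)` of the loop (1 if uncut); cut sets are coupled
#' across timepoints through their arrival windows, so every realized time
#' course is non-increasing.
#'
#' Percent attached at each timepoint is the DNA mass on anchor-containing
#' fragments averaged over nucleoids, as a percentage of total mass;
#' the reported `sd` is across replicates.
#'
#' @param model a `nucleoid_model`.
#' @param config a [simulation_config()].
#' @param label label for the output time course.
#' @param keep_cut_records if `TRUE`, return per-realization, per-window
#'   cut summaries (`n_cuts`, `min_pos`, `max_pos`).
#' @return a list of class `digestion_simulation`: `timecourse` (a
#'   [digestion_timecourse()]), `replicate_pct` (timepoints x replicates
#'   matrix), and `cut_records` (data.frame or `NULL`).
#' @export
simulate_digestion <- function(model, config, label = "sim",
                               keep_cut_records = FALSE) {
  stopifnot(inherits(model, "nucleoid_model"), inherits(config, "simulation_config"))
  if (nrow(model$loops) == 0L) stopf("model has no loops")
  tp <- config$timepoints_min
  times <- tp[tp > 0]
  deltas <- diff(c(0, times))
  arcs <- .loop_arcs(model$loops)
  alpha <- model$profile$alpha
  k0 <- model$profile$k0
  nn <- config$n_nucleoids
  nre <- nrow(model$loops) * nn
  L <- rep(arcs$L, each = nn)
  fl <- rep(arcs$fl, each = nn)
  fr <- rep(arcs$fr, each = nn)
  Tm <- .free_measure(1, fl, fr, alpha)
  total_mass <- sum(L)

  rep_pct <- matrix(NA_real_, nrow = length(tp), ncol = config$n_replicates,
                    dimnames = list(paste0("t", tp), paste0("rep", seq_len(config$n_replicates))))
  rep_pct[1, ] <- 100
  records <- if (keep_cut_records) vector("list", config$n_replicates) else NULL

  for (r in seq_len(config$n_replicates)) {
    set.seed(substream_seed(config$seed, r))
    runmin <- rep(Inf, nre)
    runmax <- rep(-Inf, nre)
    anycut <- logical(nre)
    rec_r <- if (keep_cut_records) vector("list", length(times)) else NULL
    for (j in seq_along(times)) {
      lam <- k0 * L * Tm * deltas[j]
      N <- stats::rpois(nre, lam)
      idx <- which(N > 0)
      umin <- umax <- rep(NA_real_, nre)
      if (length(idx)) {
        n_i <- N[idx]
        Fmax <- stats::runif(length(idx))^(1 / n_i)
        umax[idx] <- .free_measure_inv(Fmax * Tm[idx], fl[idx], fr[idx], alpha)
        Fmin <- Fmax
        multi <- n_i > 1L
        if (any(multi)) {
          w2 <- stats::runif(sum(multi))
          Fmin[multi] <- Fmax[multi] * (1 - (1 - w2)^(1 / (n_i[multi] - 1L)))
        }
        umin[idx] <- ifelse(multi, .free_measure_inv(Fmin * Tm[idx], fl[idx], fr[idx], alpha),
                            umax[idx])
        runmin[idx] <- pmin(runmin[idx], umin[idx])
        runmax[idx] <- pmax(runmax[idx], umax[idx])
        anycut[idx] <- TRUE
      }
      att <- ifelse(anycut, runmin + 1 - runmax, 1)
      rep_pct[j + 1L, r] <- 100 * sum(att * L) / total_mass
      if (keep_cut_records) {
        rec_r[[j]] <- data.frame(
          replicate = r,
          loop_id = rep(model$loops$loop_id, each = nn),
          nucleoid = rep(seq_len(nn), times = nrow(model$loops)),
          t_start = c(0, times)[j], t_end = times[j],
          n_cuts = N, min_pos = umin, max_pos = umax,
          stringsAsFactors = FALSE
        )
      }
    }
    if (keep_cut_records) records[[r]] <- do.call(rbind, rec_r)
  }

  tc <- digestion_timecourse(
    label = label,
    time_min = tp,
    pct_attached = rowMeans(rep_pct),
    sd = if (config$n_replicates > 1L) apply(rep_pct, 1, stats::sd) else NA_real_,
    n = config$n_replicates
  )
  structure(list(timecourse = tc, replicate_pct = rep_pct,
                 cut_records = if (keep_cut_records) do.call(rbind, records) else NULL),
            class = "digestion_simulation")
}

#' Simulate PCR amplicon detection across digestion timepoints
#'
#' For each replicate and timepoint, an amplicon is scored PCR-positive iff
#' the fraction of that replicate's nucleoids in which the amplicon
#' interval is uncut *and* lies on an anchor-containing fragment reaches
#' `config$detection_threshold`. Sampling is exact: the first-cut times of
#' the three disjoint arc regions left of, within, and right of the
#' amplicon are exponential with the corresponding hazard-mass rates, and
#' the amplicon survives attached at time `t` iff the amplicon region is
#' uncut and at least one flanking region is uncut. Replicates use
#' independent substreams of the master seed.
#'
#' @param model a `nucleoid_model`.
#' @param amplicons an [amplicon_table()]; every `loop_id` must exist.
#' @param config a [simulation_config()].
#' @param age_label age-group label stamped on the output rows.
#' @return an `amplicon_scores` data.frame (`amplicon`, `age`,
#'   `timepoint_min`, `replicate`, `detected`), with the underlying
#'   surviving-fraction estimates in `attr(, "fractions")`.
#' @export
simulate_amplicon_detection <- function(model, amplicons, config,
                                        age_label = "sim") {
  stopifnot(inherits(model, "nucleoid_model"), inherits(config, "simulation_config"))
  validate_amplicons(amplicons, model)
  idx <- match(amplicons$loop_id, model$loops$loop_id)
  arcs <- .loop_arcs(model$loops[idx, , drop = FALSE])
  alpha <- model$profile$alpha
  s <- amplicons$start_bp / arcs$L
  e <- (amplicons$start_bp + amplicons$length_bp) / arcs$L
  rate <- model$profile$k0 * arcs$L
  Tm <- .free_measure(1, arcs$fl, arcs$fr, alpha)
  Hs <- .free_measure(s, arcs$fl, arcs$fr, alpha)
  He <- .free_measure(e, arcs$fl, arcs$fr, alpha)
  r_left <- rate * Hs
  r_amp <- rate * (He - Hs)
  r_right <- rate * (Tm - He)

  tp <- config$timepoints_min
  nn <- config$n_nucleoids
  out <- vector("list", config$n_replicates)
  frac <- array(NA_real_, dim = c(nrow(amplicons), length(tp), config$n_replicates),
                dimnames = list(amplicons$name, paste0("t", tp), NULL))
  rexp0 <- function(n, rate) if (rate <= 0) rep(Inf, n) else stats::rexp(n, rate)
  for (r in seq_len(config$n_replicates)) {
    set.seed(substream_seed(config$seed, 1000L + r))
    det <- matrix(NA, nrow = nrow(amplicons), ncol = length(tp))
    for (a in seq_len(nrow(amplicons))) {
      e1 <- rexp0(nn, r_left[a]); e2 <- rexp0(nn, r_amp[a]); e3 <- rexp0(nn, r_right[a])
      for (j in seq_along(tp)) {
        tt <- tp[j]
        surv <- (e2 > tt) & ((e1 > tt) | (e3 > tt))
        frac[a, j, r] <- mean(surv)
        det[a, j] <- frac[a, j, r] >= config$detection_threshold
      }
    }
    out[[r]] <- data.frame(
      amplicon = rep(amplicons$name, times = length(tp)),
      age = age_label,
      timepoint_min = rep(tp, each = nrow(amplicons)),
      replicate = r,
      detected = as.vector(det),
      stringsAsFactors = FALSE
    )
  }
  scores <- do.call(rbind, out)
  class(scores) <- c("amplicon_scores", "data.frame")
  attr(scores, "fractions") <- frac
  scores
}
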