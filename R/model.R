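#' Accessibility profile of loop DNA to DNase I
#'
#' Collapses the two protection factors acting on NM-anchored loop DNA --
#' steric hindrance by the proteinaceous NM and the gradient of negative
#' supercoiling that increases from loop tip to base -- into a single
#' monotone accessibility function
#' \deqn{a(d) = (d / 0.5)^{\alpha},}
#' where \eqn{d = \min(u, 1 - u)} is the arc distance (fraction of total
#' loop length) from the nearer anchor, so \eqn{a} is 0 at the anchors and
#' 1 at the loop apex. The per-bp cleavage hazard at arc position `u` is
#' `k0 * a(d(u))` cuts per bp per minute; DNA inside a MAR footprint
#' (embedded within the NM) has hazard exactly 0.
#'
#' @param k0 base cleavage hazard at the loop apex, cuts / bp / min.
#' @param alpha gradient exponent (>= 0); `alpha = 0` gives a uniform
#'   hazard over the free loop, larger values protect NM-proximal DNA
#'   more strongly.
#' @return an object of class `accessibility_profile`.
#' @examples
#' accessibility_profile(k0 = 1e-4, alpha = 2)
#' @export
accessibility_profile <- function(k0 = 1e-4, alpha = 2) {
  stopifnot(is.numeric(k0), length(k0) == 1L, is.numeric(alpha), length(alpha) == 1L)
  if (k0 < 0) stopf("k0 must be >= 0, got %g", k0)
  if (alpha < 0) stopf("alpha must be >= 0, got %g", alpha)
  structure(list(k0 = k0, alpha = alpha, embedded_hazard = 0),
            class = "accessibility_profile")
}

#' @export
print.accessibility_profile <- function(x, ...) {
  cat(sprintf("Accessibility profile: a(d) = (2d)^%g, k0 = %g cuts/bp/min, embedded hazard 0\n",
              x$alpha, x$k0))
  invisible(x)
}

# ---- accessibility measure -------------------------------------------------
#
# G(u) = int_0^u (2 min(s, 1-s))^alpha ds, the accessibility-weighted arc
# measure on [0, 1]; closed form on each half, symmetric about 0.5.

.G_left <- function(x, alpha) 2^alpha * x^(alpha + 1) / (alpha + 1)

.G <- function(u, alpha) {
  half <- .G_left(0.5, alpha)          # = 0.5 / (alpha + 1)
  ifelse(u <= 0.5, .G_left(u, alpha), 2 * half - .G_left(1 - u, alpha))
}

.G_left_inv <- function(m, alpha) ((alpha + 1) * m / 2^alpha)^(1 / (alpha + 1))

.G_inv <- function(m, alpha) {
  half <- .G_left(0.5, alpha)
  ifelse(m <= half, .G_left_inv(pmax(m, 0), alpha),
         1 - .G_left_inv(pmax(2 * half - m, 0), alpha))
}

# accessibility measure of [0, u] restricted to the free (non-footprint)
# region, for footprints [0, fl] and [1 - fr, 1]
.free_measure <- function(u, fl, fr, alpha) {
  u <- pmin(pmax(u, fl), 1 - fr)
  .G(u, alpha) - .G(fl, alpha)
}

# inverse of .free_measure in u, for m in [0, .free_measure(1, ...)]
.free_measure_inv <- function(m, fl, fr, alpha) {
  .G_inv(.G(fl, alpha) + m, alpha)
}

# ---- loop ensemble ---------------------------------------------------------

#' Build a synthetic ensemble of NM-anchored DNA loops
#'
#' Generates a `nucleoid_model`: a collection of DNA loops, each anchored to
#' the nuclear matrix at both ends through a matrix attachment region (MAR)
#' footprint, plus an accessibility profile. Loop total sizes are drawn from
#' a normal distribution (truncated at a small positive floor) and rounded
#' to whole bp; the MAR footprint of each loop is the `embedded_target`
#' fraction of its length, split equally between the two anchors. Loops are
#' laid head-to-tail along a synthetic genome coordinate (`genome_start`)
#' so that amplicon positions have fixed genomic offsets across
#' rearrangements of the loop pattern.
#'
#' @param n_loops number of loops.
#' @param mean_kbp mean loop size in kbp (default 42, the newborn-neuron
#'   average estimated from the DNA-halo assay).
#' @param cv coefficient of variation of loop size.
#' @param embedded_target target fraction of total DNA embedded within the
#'   NM (default 0.02, the classic ~2 % DNase-resistant fraction).
#' @param profile an [accessibility_profile()].
#' @param seed integer seed; the ensemble is reproducible bit-for-bit.
#' @return an object of class `nucleoid_model` with elements `loops`
#'   (data.frame: `loop_id`, `total_bp`, `mar_left_bp`, `mar_right_bp`,
#'   `free_bp`, `genome_start`), `profile` and `seed`.
#' @examples
#' m <- build_nucleoid_ensemble(100, seed = 1)
#' embedded_fraction(m)
#' @export
build_nucleoid_ensemble <- function(n_loops, mean_kbp = 42, cv = 0.1,
                                    embedded_target = 0.02,
                                    profile = accessibility_profile(),
                                    seed = 1L) {
  stopifnot(is.numeric(n_loops), n_loops >= 1)
  if (mean_kbp <= 0) stopf("mean_kbp must be > 0, got %g", mean_kbp)
  if (embedded_target < 0 || embedded_target >= 1)
    stopf("embedded_target must be in [0, 1), got %g", embedded_target)
  if (embedded_target >= 0.5)
    stopf("embedded_target %g leaves no room for free loop DNA", embedded_target)
  stopifnot(inherits(profile, "accessibility_profile"))

  set.seed(substream_seed(seed, 0L))
  mean_bp <- mean_kbp * 1000
  sizes <- round(stats::rnorm(n_loops, mean_bp, cv * mean_bp))
  sizes <- pmax(sizes, ceiling(mean_bp * 0.05))  # truncate pathological tails
  mar_side <- round(sizes * embedded_target / 2)
  loops <- data.frame(
    loop_id = sprintf("loop_%04d", seq_len(n_loops)),
    total_bp = as.numeric(sizes),
    mar_left_bp = as.numeric(mar_side),
    mar_right_bp = as.numeric(mar_side),
    stringsAsFactors = FALSE
  )
  loops$free_bp <- loops$total_bp - loops$mar_left_bp - loops$mar_right_bp
  loops$genome_start <- cumsum(c(0, loops$total_bp[-n_loops]))

  model <- structure(list(loops = loops, profile = profile, seed = seed),
                     class = "nucleoid_model")
  realized <- embedded_fraction(model)
  if (embedded_target > 0 &&
      abs(realized - embedded_target) > 0.1 * embedded_target)
    stopf("realized embedded fraction %.4g misses target %.4g by more than 10%%",
          realized, embedded_target)
  model
}

#' Fraction of total DNA embedded within the NM
#'
#' @param model a `nucleoid_model`.
#' @return the summed MAR footprint mass over total DNA mass.
#' @export
embedded_fraction <- function(model) {
  stopifnot(inherits(model, "nucleoid_model"))
  with(model$loops, sum(mar_left_bp + mar_right_bp) / sum(total_bp))
}

#' @export
print.nucleoid_model <- function(x, ...) {
  cat(sprintf("Nucleoid model: %d loops, mean size %.1f kbp, embedded fraction %.4f\n",
              nrow(x$loops), mean(x$loops$total_bp) / 1000, embedded_fraction(x)))
  print(x$profile)
  invisible(x)
}

# per-loop anchor footprints as arc fractions
.loop_arcs <- function(loops) {
  list(L = loops$total_bp,
       fl = loops$mar_left_bp / loops$total_bp,
       fr = loops$mar_right_bp / loops$total_bp)
}

#' Define amplicons within model loops
#'
#' @param name unique amplicon names.
#' @param loop_id id of the carrying loop.
#' @param start_bp 0-based start within the loop coordinate.
#' @param length_bp amplicon length in bp (> 0).
#' @param chromosome_label chromosome annotation carried as metadata.
#' @param expressed logical annotation (expression is never modelled,
#'   only carried).
#' @param model optional `nucleoid_model`; when given, intervals are
#'   validated against the loop table.
#' @return a data.frame of class `amplicon_table`.
#' @export
amplicon_table <- function(name, loop_id, start_bp, length_bp,
                           chromosome_label = NA_character_,
                           expressed = NA, model = NULL) {
  if (anyDuplicated(name)) stopf("amplicon names must be unique")
  if (any(length_bp <= 0)) stopf("amplicon length_bp must be > 0")
  if (any(start_bp < 0)) stopf("amplicon start_bp must be >= 0")
  amps <- data.frame(name = as.character(name), loop_id = as.character(loop_id),
                     start_bp = as.numeric(start_bp),
                     length_bp = as.numeric(length_bp),
                     chromosome_label = chromosome_label,
                     expressed = expressed, stringsAsFactors = FALSE)
  if (!is.null(model)) validate_amplicons(amps, model)
  class(amps) <- c("amplicon_table", "data.frame")
  amps
}

validate_amplicons <- function(amplicons, model) {
  idx <- match(amplicons$loop_id, model$loops$loop_id)
  if (anyNA(idx)) {
    bad <- amplicons$loop_id[is.na(idx)]
    stopf("amplicon loop_id not in model: %s", paste(unique(bad), collapse = ", "))
  }
  tot <- model$loops$total_bp[idx]
  if (any(amplicons$start_bp + amplicons$length_bp > tot))
    stopf("amplicon interval exceeds its loop length")
  invisible(TRUE)
}

#' Simulation configuration for digestion and detection
#'
#' @param timepoints_min sampled digestion times in minutes, starting at 0
#'   (default `c(0, 5, 15, 30, 60)`).
#' @param n_nucleoids nucleoids drawn per replicate.
#' @param n_replicates independent experimental replicates (default 4).
#' @param detection_threshold minimum fraction of nucleoids retaining an
#'   intact, NM-attached amplicon copy for a PCR-positive call.
#' @param dnase_u_per_ml bench DNase I concentration, carried as metadata
#'   only (default 0.92 U/ml).
#' @param seed master seed for the simulation streams.
#' @return an object of class `simulation_config`.
#' @export
simulation_config <- function(timepoints_min = c(0, 5, 15, 30, 60),
                              n_nucleoids = 1000L, n_replicates = 4L,
                              detection_threshold = 1e-3,
                              dnase_u_per_ml = 0.92, seed = 1L) {
  if (length(timepoints_min) < 1L || timepoints_min[1] != 0)
    stopf("timepoints_min must start at 0")
  if (any(diff(timepoints_min) <= 0))
    stopf("timepoints_min must be strictly increasing")
  if (any(timepoints_min < 0)) stopf("negative digestion time")
  if (detection_threshold <= 0 || detection_threshold > 1)
    stopf("detection_threshold must be in (0, 1], got %g", detection_threshold)
  if (n_nucleoids < 1) stopf("n_nucleoids must be >= 1")
  if (n_replicates < 1) stopf("n_replicates must be >= 1")
  structure(list(timepoints_min = as.numeric(timepoints_min),
                 n_nucleoids = as.integer(n_nucleoids),
                 n_replicates = as.integer(n_replicates),
                 detection_threshold = detection_threshold,
                 dnase_u_per_ml = dnase_u_per_ml,
                 seed = as.integer(seed)),
            class = "simulation_config")
}
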