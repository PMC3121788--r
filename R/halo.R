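#' DNA loop size from DNA-halo radius
#'
#' After maximum ethidium-bromide-driven halo expansion the halo radius
#' tracks the average loop size: a loop is an out-and-back path of B-DNA
#' from the NM, so
#' \deqn{\mathrm{kbp} = 2 R \,/\, \mathrm{rise},}
#' with `R` in µm and the helical rise in nm/bp (canonical B-DNA
#' 0.34 nm/bp by default; the constant is exposed so alternative
#' calibrations can be swapped in).
#'
#' @param radius_um halo radius (radii) in µm, >= 0.
#' @param rise_nm_per_bp helical rise, nm per bp.
#' @return loop size(s) in kbp; linear and strictly monotone in the radius.
#' @examples
#' loop_size_from_halo(7.141)  # ~42 kbp
#' @export
loop_size_from_halo <- function(radius_um, rise_nm_per_bp = 0.34) {
  if (any(radius_um < 0)) stopf("halo radius must be >= 0")
  stopifnot(rise_nm_per_bp > 0)
  2 * radius_um / rise_nm_per_bp
}

#' Halo / nucleus / NM measurement set
#'
#' @param label age-group label.
#' @param nucleus_diameter_um,nm_diameter_um,halo_radius_um per-nucleoid
#'   measurements in µm (halo radius: from the core nucleoid contour to
#'   the outer halo limit). All present values must be > 0.
#' @return data.frame of class `halo_measurements` with attribute `label`.
#' @export
halo_measurements <- function(label, nucleus_diameter_um, nm_diameter_um,
                              halo_radius_um) {
  d <- data.frame(nucleus_diameter_um = as.numeric(nucleus_diameter_um),
                  nm_diameter_um = as.numeric(nm_diameter_um),
                  halo_radius_um = as.numeric(halo_radius_um))
  for (col in names(d))
    if (any(d[[col]] <= 0, na.rm = TRUE)) stopf("%s must be > 0", col)
  attr(d, "label") <- as.character(label)
  class(d) <- c("halo_measurements", "data.frame")
  d
}

#' Per-field mean and sample SD of a measurement set
#'
#' @param set a [halo_measurements()] data.frame (n >= 2).
#' @return data.frame `field`, `mean`, `sd`, `n` (sample SD, n-1
#'   denominator).
#' @export
summarize_measurements <- function(set) {
  stopifnot(inherits(set, "halo_measurements"))
  if (nrow(set) < 2L) stopf("need n >= 2 for a sample SD, got n = %d", nrow(set))
  data.frame(field = names(set),
             mean = vapply(set, mean, numeric(1), na.rm = TRUE),
             sd = vapply(set, stats::sd, numeric(1), na.rm = TRUE),
             n = vapply(set, function(x) sum(!is.na(x)), numeric(1)),
             row.names = NULL)
}

#' Average loop-size estimate from a halo measurement set
#'
#' @param set a [halo_measurements()] data.frame.
#' @param rise_nm_per_bp helical rise used for the conversion.
#' @return list of class `loop_size_estimate`: `mean_kbp`, `sd_kbp`,
#'   `rise_nm_per_bp`, `n`.
#' @export
loop_size_estimate <- function(set, rise_nm_per_bp = 0.34) {
  stopifnot(inherits(set, "halo_measurements"))
  kbp <- loop_size_from_halo(set$halo_radius_um, rise_nm_per_bp)
  structure(list(mean_kbp = mean(kbp),
                 sd_kbp = if (length(kbp) > 1L) stats::sd(kbp) else NA_real_,
                 rise_nm_per_bp = rise_nm_per_bp, n = length(kbp)),
            class = "loop_size_estimate")
}

#' @export
print.loop_size_estimate <- function(x, ...) {
  cat(sprintf("Average DNA loop size: %.1f kbp ± %.2f (n = %d, rise %.2f nm/bp)\n",
              x$mean_kbp, x$sd_kbp, x$n, x$rise_nm_per_bp))
  invisible(x)
}

#' Two-sample Student's t-test between measurement groups
#'
#' Pooled-variance two-sample t by default (the convention for equal-n
#' group comparisons), two-tailed, significant at `p < alpha`
#' (default alpha 0.01, a 99 % significance level); Welch's unequal-
#' variance variant is available by flag. Two degenerate zero-variance
#' samples with equal means give t = 0, p = 1 rather than an error.
#'
#' @param sample_a,sample_b numeric vectors, each n >= 2.
#' @param alpha significance level.
#' @param variant "pooled" (Student) or "welch".
#' @return list of class `t_test_result`: `t_statistic`,
#'   `degrees_of_freedom`, `p_value`, `significant`, `alpha`, `variant`.
#' @export
students_t_test <- function(sample_a, sample_b, alpha = 0.01,
                            variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  if (length(sample_a) < 2L || length(sample_b) < 2L)
    stopf("each sample needs n >= 2")
  va <- stats::var(sample_a); vb <- stats::var(sample_b)
  if (va == 0 && vb == 0) {
    equal <- isTRUE(all.equal(mean(sample_a), mean(sample_b)))
    tt <- if (equal) 0 else sign(mean(sample_a) - mean(sample_b)) * Inf
    pv <- if (equal) 1 else 0
    df <- length(sample_a) + length(sample_b) - 2L
  } else {
    ht <- stats::t.test(sample_a, sample_b, var.equal = variant == "pooled")
    tt <- unname(ht$statistic); df <- unname(ht$parameter); pv <- ht$p.value
  }
  structure(list(t_statistic = tt, degrees_of_freedom = df, p_value = pv,
                 significant = pv < alpha, alpha = alpha, variant = variant),
            class = "t_test_result")
}

#' @export
print.t_test_result <- function(x, ...) {
  cat(sprintf("%s two-sample t: t = %.4f, df = %.2f, p = %.4g (%ssignificant at %.2g)\n",
              if (x$variant == "pooled") "Student's" else "Welch's",
              x$t_statistic, x$degrees_of_freedom, x$p_value,
              if (x$significant) "" else "not ", x$alpha))
  invisible(x)
}

#' NM resilience check
#'
#' A resilient nuclear matrix withstands the tearing forces of EB-driven
#' halo expansion; operationally the mean NM diameter exceeding the mean
#' nuclear diameter is taken as the resilience signature.
#'
#' @param set a [halo_measurements()] data.frame with both diameter fields.
#' @return list: `ratio` (mean NM diameter / mean nucleus diameter),
#'   `resilient` (`ratio > 1`).
#' @export
nm_resilience <- function(set) {
  stopifnot(inherits(set, "halo_measurements"))
  if (all(is.na(set$nm_diameter_um)) || all(is.na(set$nucleus_diameter_um)))
    stopf("both nucleus and NM diameters are required")
  ratio <- mean(set$nm_diameter_um, na.rm = TRUE) /
    mean(set$nucleus_diameter_um, na.rm = TRUE)
  list(ratio = ratio, resilient = ratio > 1)
}

#' Simulate halo-radius measurements from a loop ensemble
#'
#' Emits a synthetic [halo_measurements()] set: each nucleoid's halo
#' radius is the ensemble mean free loop length converted to µm
#' (`free_bp * rise / 1000 / 2`, the one-way extension of an out-and-back
#' loop) perturbed by multiplicative Gaussian noise of coefficient of
#' variation `noise_cv`; nucleus and NM diameters are drawn around their
#' configured means with the same noise model. Composing with
#' [loop_size_from_halo()] at zero noise is an exact inverse of the
#' conversion.
#'
#' @param model a `nucleoid_model`.
#' @param n number of nucleoids to measure (>= 1).
#' @param noise_cv measurement coefficient of variation (>= 0).
#' @param rise_nm_per_bp helical rise, nm per bp.
#' @param seed integer seed.
#' @param nucleus_mean_um,nm_mean_um configured mean diameters (µm).
#' @param label label for the output set.
#' @return a [halo_measurements()] data.frame.
#' @export
simulate_halo_radii <- function(model, n, noise_cv = 0.05,
                                rise_nm_per_bp = 0.34, seed = 1L,
                                nucleus_mean_um = 10, nm_mean_um = 11,
                                label = "sim") {
  stopifnot(inherits(model, "nucleoid_model"))
  if (n < 1) stopf("n must be >= 1, got %g", n)
  if (noise_cv < 0) stopf("noise_cv must be >= 0, got %g", noise_cv)
  set.seed(substream_seed(seed, 0L))
  r0 <- mean(model$loops$free_bp) * rise_nm_per_bp / 1000 / 2
  noise <- function(mu) mu * (1 + stats::rnorm(n, 0, noise_cv))
  halo_measurements(label,
                    nucleus_diameter_um = noise(nucleus_mean_um),
                    nm_diameter_um = noise(nm_mean_um),
                    halo_radius_um = noise(r0))
}
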