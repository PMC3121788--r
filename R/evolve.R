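#' Evolve the nuclear higher-order structure under an aging model
#'
#' Two competing mechanisms for the age-dependent displacement of genes
#' away from the NM:
#'
#' * **Mode A (MAR substitution)**: each loop independently re-anchors with
#'   probability `p_sub` -- new potential MARs become actualized and
#'   substitute previous ones. Contiguous runs of re-anchoring loops are
#'   re-partitioned into new loops whose sizes are redrawn from the
#'   configured distribution; the run's total DNA mass is conserved
#'   exactly (the last redrawn loop is clipped to the run boundary).
#'   Amplicons keep their fixed genomic offsets and can be re-localized
#'   with [remap_amplicons()].
#' * **Mode B (MAR extension)**: each MAR footprint grows by absorbing
#'   adjacent free loop DNA, reducing the free loop without changing any
#'   loop's total size, so total DNA mass is conserved exactly and the
#'   embedded fraction rises. A loop whose free DNA reaches zero is fully
#'   embedded (merged into the NM); extensions never drive `free_bp`
#'   negative -- draws beyond the available free DNA are clipped.
#'
#' @param model a `nucleoid_model`.
#' @param mode `"A_substitution"` or `"B_extension"`.
#' @param params mode A: `list(p_sub =, size_mean_bp =, size_cv =)`
#'   (size defaults: current mean, cv 0.1). Mode B: `list(extension =)`
#'   where `extension` is either `list(kind = "fraction", frac =)` -- each
#'   loop's two footprints deterministically absorb `frac/2` of its free
#'   DNA apiece (default `frac = 0.2`) -- or
#'   `list(kind = "gamma", mean_bp =, cv =)` for stochastic per-footprint
#'   draws.
#' @param seed integer seed for the stochastic draws.
#' @return a new `nucleoid_model`; for mode A the ids of substituted loops
#'   are in `attr(, "substituted")`.
#' @examples
#' m <- build_nucleoid_ensemble(50, seed = 1)
#' mB <- evolve_nhos(m, "B_extension", list(extension = list(kind = "fraction", frac = 0.2)))
#' embedded_fraction(mB) - embedded_fraction(m)  # = 0.2 * (1 - ef0)
#' @export
evolve_nhos <- function(model, mode = c("A_substitution", "B_extension"),
                        params = list(), seed = 1L) {
  stopifnot(inherits(model, "nucleoid_model"))
  mode <- match.arg(mode)
  if (mode == "B_extension") .evolve_extension(model, params, seed)
  else .evolve_substitution(model, params, seed)
}

.evolve_extension <- function(model, params, seed) {
  ext <- params$extension %||% list(kind = "fraction", frac = 0.2)
  loops <- model$loops
  free <- loops$free_bp
  if (identical(ext$kind, "fraction")) {
    frac <- ext$frac %||% 0.2
    if (frac < 0 || frac > 1) stopf("extension fraction must be in [0, 1]")
    ext_l <- frac * free / 2
    ext_r <- frac * free / 2
  } else if (identical(ext$kind, "gamma")) {
    if (is.null(ext$mean_bp)) stopf("gamma extension needs mean_bp")
    cv <- ext$cv %||% 0.5
    set.seed(substream_seed(seed, 2L))
    shape <- 1 / cv^2
    ext_l <- stats::rgamma(nrow(loops), shape = shape, scale = ext$mean_bp / shape)
    ext_r <- stats::rgamma(nrow(loops), shape = shape, scale = ext$mean_bp / shape)
    over <- ext_l + ext_r > free   # clip, never negative free DNA
    scl <- free[over] / (ext_l[over] + ext_r[over])
    ext_l[over] <- ext_l[over] * scl
    ext_r[over] <- ext_r[over] * scl
  } else stopf("unknown extension kind '%s'", ext$kind %||% "<missing>")
  loops$mar_left_bp <- loops$mar_left_bp + ext_l
  loops$mar_right_bp <- loops$mar_right_bp + ext_r
  loops$free_bp <- loops$total_bp - loops$mar_left_bp - loops$mar_right_bp
  loops$free_bp[abs(loops$free_bp) < 1e-9] <- 0
  out <- model
  out$loops <- loops
  out
}

.evolve_substitution <- function(model, params, seed) {
  p_sub <- params$p_sub %||% 0.5
  if (p_sub < 0 || p_sub > 1) stopf("p_sub must be in [0, 1]")
  loops <- model$loops
  mean_bp <- params$size_mean_bp %||% mean(loops$total_bp)
  cv <- params$size_cv %||% 0.1
  emb <- embedded_fraction(model)
  set.seed(substream_seed(seed, 3L))
  sub <- stats::runif(nrow(loops)) < p_sub

  draw_sizes <- function(mass) {
    # iid draws until the run mass is covered; last loop clipped to the
    # boundary so the run's DNA mass is conserved exactly
    sizes <- numeric(0)
    while (sum(sizes) < mass) {
      blk <- round(stats::rnorm(max(8L, ceiling(mass / mean_bp)), mean_bp, cv * mean_bp))
      blk <- pmax(blk, ceiling(mean_bp * 0.05))
      sizes <- c(sizes, blk)
    }
    k <- which(cumsum(sizes) >= mass)[1]
    sizes <- sizes[seq_len(k)]
    sizes[k] <- mass - sum(sizes[-k])
    if (k > 1L && sizes[k] < mean_bp * 0.05) {
      sizes[k - 1L] <- sizes[k - 1L] + sizes[k]
      sizes <- sizes[-k]
    }
    sizes
  }

  runs <- rle(sub)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  pieces <- vector("list", length(runs$values))
  counter <- 0L
  for (i in seq_along(runs$values)) {
    block <- loops[starts[i]:ends[i], , drop = FALSE]
    if (!runs$values[i]) { pieces[[i]] <- block; next }
    mass <- sum(block$total_bp)
    sizes <- draw_sizes(mass)
    counter <- counter + length(sizes)
    mar <- round(sizes * emb / 2)
    pieces[[i]] <- data.frame(
      loop_id = sprintf("subst_%05d", (counter - length(sizes) + 1L):counter),
      total_bp = as.numeric(sizes),
      mar_left_bp = as.numeric(mar), mar_right_bp = as.numeric(mar),
      free_bp = as.numeric(sizes - 2 * mar),
      genome_start = NA_real_, stringsAsFactors = FALSE)
  }
  new_loops <- do.call(rbind, pieces)
  new_loops$genome_start <- cumsum(c(0, new_loops$total_bp[-nrow(new_loops)]))
  rownames(new_loops) <- NULL
  out <- model
  out$loops <- new_loops
  attr(out, "substituted") <- new_loops$loop_id[startsWith(new_loops$loop_id, "subst_")]
  out
}

#' Re-localize amplicons after a loop-pattern rearrangement
#'
#' Amplicons sit at fixed genomic offsets; after [evolve_nhos()] mode A
#' redraws the loop boundaries, each amplicon's loop assignment and
#' within-loop coordinate are re-derived from its genomic offset (an
#' amplicon that would straddle a new loop boundary is shifted back to fit
#' inside the loop containing its start). After mode B, coordinates are
#' unchanged and the input is returned as-is.
#'
#' @param amplicons an [amplicon_table()] defined on `old_model`.
#' @param old_model,new_model `nucleoid_model`s before and after evolution.
#' @return an [amplicon_table()] defined on `new_model`.
#' @export
remap_amplicons <- function(amplicons, old_model, new_model) {
  validate_amplicons(amplicons, old_model)
  if (identical(old_model$loops$loop_id, new_model$loops$loop_id))
    return(amplicons)
  old_idx <- match(amplicons$loop_id, old_model$loops$loop_id)
  offset <- old_model$loops$genome_start[old_idx] + amplicons$start_bp
  nl <- new_model$loops
  new_idx <- findInterval(offset, nl$genome_start)
  start <- offset - nl$genome_start[new_idx]
  over <- start + amplicons$length_bp > nl$total_bp[new_idx]
  start[over] <- nl$total_bp[new_idx][over] - amplicons$length_bp[over]
  amplicon_table(amplicons$name, nl$loop_id[new_idx], start,
                 amplicons$length_bp, amplicons$chromosome_label,
                 amplicons$expressed, model = new_model)
}
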