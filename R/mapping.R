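#' Summarize replicate PCR detections into a +/- symbol
#'
#' "+" iff every replicate amplified, "-" iff none did, "±" otherwise
#' (the published convention: ± marks a target negative in one experiment).
#'
#' @param detected logical vector of per-replicate detection calls.
#' @return one of "+", "±", "-".
#' @examples
#' score_replicates(c(TRUE, TRUE, TRUE, FALSE))  # "±"
#' @export
score_replicates <- function(detected) {
  if (length(detected) == 0L) stopf("no replicates to score")
  detected <- as.logical(detected)
  if (anyNA(detected)) stopf("NA detection call")
  if (all(detected)) "+" else if (!any(detected)) "-" else "±"
}

.is_positive_symbol <- function(sym, ambiguous_counts_positive = TRUE) {
  sym == "+" | (ambiguous_counts_positive & sym == "±")
}

#' Check outside-in admissibility of a zone positivity pattern
#'
#' Under the outside-in digestion model the amplifiable zones of a target
#' form a prefix of the zone order D, P, VC, E: a negative at an early
#' (outer) timepoint followed by a positive at a later (inner) one is
#' physically impossible and marks a QC failure.
#'
#' @param pattern character vector of symbols "+", "±", "-" ordered
#'   outermost (D) to innermost (E).
#' @param ambiguous_counts_positive treat "±" as positive.
#' @return `TRUE` if admissible, `FALSE` otherwise.
#' @export
monotonicity_check <- function(pattern, ambiguous_counts_positive = TRUE) {
  pos <- .is_positive_symbol(pattern, ambiguous_counts_positive)
  !any(diff(as.integer(pos)) > 0L)
}

#' Call the topological zone of a target sequence
#'
#' The zone of a target is the innermost (longest-digestion) zone whose
#' summary symbol is positive; with `ambiguous_counts_positive` (the
#' default, matching how published tables place ±-bearing patterns) a "±"
#' also counts as positive, and the call is flagged ambiguous when the
#' call-determining symbol is "±". Non-monotone patterns and all-negative
#' patterns are unscorable.
#'
#' @param pattern symbols ordered as `scheme$zone` (outermost first).
#' @param scheme a [zone_scheme_from_timepoints()] result.
#' @param ambiguous_counts_positive treat "±" as positive (strict mode:
#'   `FALSE`).
#' @return list of class `position_call`: `zone`, `rank` (innermost = 1),
#'   `ambiguous`, `violations` (character vector, empty when scorable).
#' @examples
#' tc <- digestion_timecourse("P0", c(0, 5, 15, 30, 60),
#'                            c(100, 55.9, 24.5, 17.6, 8.8))
#' sch <- zone_scheme_from_timepoints(tc)
#' call_position(c("+", "+", "+", "-"), sch)$zone  # "VC"
#' @export
call_position <- function(pattern, scheme, ambiguous_counts_positive = TRUE) {
  stopifnot(inherits(scheme, "zone_scheme"))
  if (length(pattern) != nrow(scheme))
    stopf("pattern length %d but scheme has %d zones", length(pattern), nrow(scheme))
  bad <- setdiff(pattern, c("+", "-", "±"))
  if (length(bad)) stopf("unknown symbol(s): %s", paste(bad, collapse = ", "))
  violations <- character(0)
  if (!monotonicity_check(pattern, ambiguous_counts_positive))
    violations <- c(violations,
                    "non-monotone pattern: negative zone followed inward by a positive")
  pos <- .is_positive_symbol(pattern, ambiguous_counts_positive)
  if (!any(pos)) violations <- c(violations, "no positive zone")
  if (length(violations))
    return(structure(list(zone = NA_character_, rank = NA_integer_,
                          ambiguous = NA, violations = violations),
                     class = "position_call"))
  i <- max(which(pos))
  ranks <- zone_ranks(scheme)
  structure(list(zone = scheme$zone[i],
                 rank = unname(ranks[scheme$zone[i]]),
                 ambiguous = pattern[i] == "±",
                 violations = character(0)),
            class = "position_call")
}

#' Summarize an amplicon score matrix into per-zone symbols
#'
#' @param scores an `amplicon_scores` data.frame (`amplicon`, `age`,
#'   `timepoint_min`, `replicate`, `detected`).
#' @param scheme a [zone_scheme_from_timepoints()] result; score rows are
#'   matched to zones by timepoint (timepoint 0, the undigested control,
#'   is ignored).
#' @return data.frame `amplicon`, `age`, `zone`, `symbol`.
#' @export
summarize_scores <- function(scores, scheme) {
  stopifnot(inherits(scheme, "zone_scheme"))
  need <- c("amplicon", "age", "timepoint_min", "replicate", "detected")
  miss <- setdiff(need, names(scores))
  if (length(miss)) stopf("score matrix lacks column(s): %s", paste(miss, collapse = ", "))
  sc <- scores[scores$timepoint_min %in% scheme$timepoint_min, , drop = FALSE]
  missing_tp <- setdiff(scheme$timepoint_min, sc$timepoint_min)
  if (length(missing_tp))
    stopf("score matrix lacks zone timepoint(s): %s", paste(missing_tp, collapse = ", "))
  key <- paste(sc$amplicon, sc$age, sc$timepoint_min, sep = "\r")
  sym <- tapply(sc$detected, key, score_replicates)
  parts <- do.call(rbind, strsplit(names(sym), "\r", fixed = TRUE))
  out <- data.frame(amplicon = parts[, 1], age = parts[, 2],
                    timepoint_min = as.numeric(parts[, 3]),
                    symbol = as.character(sym), stringsAsFactors = FALSE)
  out$zone <- scheme$zone[match(out$timepoint_min, scheme$timepoint_min)]
  out[order(out$amplicon, out$age, out$timepoint_min),
      c("amplicon", "age", "zone", "symbol")]
}

#' Positional mapping table of amplicons relative to the NM
#'
#' One position call per (amplicon, age) pair from a replicate-level score
#' matrix or from a pre-summarized symbol table; rows with QC violations
#' (non-monotone or all-negative patterns) are retained with `NA` zone and
#' the violation recorded, without aborting the remaining calls. A
#' `rank` column (innermost = 1, outermost = number of zones) supports
#' trend statistics.
#'
#' @param scores an `amplicon_scores` data.frame, or a summary data.frame
#'   with columns `amplicon`, `age`, `zone`, `symbol`.
#' @param scheme a [zone_scheme_from_timepoints()] result.
#' @param ambiguous_counts_positive treat "±" as positive when calling.
#' @return data.frame of class `position_calls`: `amplicon`, `age`,
#'   `zone`, `rank`, `ambiguous`, `violation`.
#' @export
mapping_table <- function(scores, scheme, ambiguous_counts_positive = TRUE) {
  smry <- if (all(c("zone", "symbol") %in% names(scores))) scores
  else summarize_scores(scores, scheme)
  pairs <- unique(smry[, c("amplicon", "age")])
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    sub <- smry[smry$amplicon == pairs$amplicon[i] & smry$age == pairs$age[i], ]
    pattern <- sub$symbol[match(scheme$zone, sub$zone)]
    if (anyNA(pattern))
      return(data.frame(amplicon = pairs$amplicon[i], age = pairs$age[i],
                        zone = NA_character_, rank = NA_integer_, ambiguous = NA,
                        violation = "incomplete zone coverage",
                        stringsAsFactors = FALSE))
    cl <- call_position(pattern, scheme, ambiguous_counts_positive)
    data.frame(amplicon = pairs$amplicon[i], age = pairs$age[i],
               zone = cl$zone, rank = cl$rank, ambiguous = cl$ambiguous,
               violation = if (length(cl$violations))
                 paste(cl$violations, collapse = "; ") else NA_character_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("position_calls", "data.frame")
  out
}

#' Per-amplicon positional movement between two ages
#'
#' For each amplicon, the change in zone distance rank between a younger
#' and an older mapping table: `delta_rank = rank_old - rank_young`, so
#' positive values mean the target moved away from the NM.
#'
#' @param table_young,table_old [mapping_table()] results over the same
#'   amplicon set.
#' @return list with `per_amplicon` (data.frame `amplicon`, `rank_young`,
#'   `rank_old`, `delta_rank`, `movement`) and `summary` (counts of
#'   `away`, `toward`, `unchanged`).
#' @export
positional_shift <- function(table_young, table_old) {
  if (!setequal(table_young$amplicon, table_old$amplicon))
    stopf("amplicon sets differ between tables")
  m <- merge(table_young[, c("amplicon", "rank")],
             table_old[, c("amplicon", "rank")],
             by = "amplicon", suffixes = c("_young", "_old"))
  m$delta_rank <- m$rank_old - m$rank_young
  m$movement <- ifelse(is.na(m$delta_rank), NA_character_,
                       ifelse(m$delta_rank > 0, "away",
                              ifelse(m$delta_rank < 0, "toward", "unchanged")))
  list(per_amplicon = m,
       summary = c(away = sum(m$movement == "away", na.rm = TRUE),
                   toward = sum(m$movement == "toward", na.rm = TRUE),
                   unchanged = sum(m$movement == "unchanged", na.rm = TRUE)))
}

#' Expand a symbol pattern table into replicate-level detection calls
#'
#' Inverse of [summarize_scores()] for building fixtures and round-trip
#' checks: "+" expands to all replicates positive, "-" to all negative,
#' "±" to a single negative replicate (the last), matching the published
#' footnote semantics. An undigested control row (timepoint 0, all
#' positive) is added for each (amplicon, age).
#'
#' @param patterns data.frame with columns `amplicon`, `age`, and one
#'   symbol column per zone label in `scheme$zone`.
#' @param scheme a [zone_scheme_from_timepoints()] result.
#' @param n_replicates replicates per call (default 4).
#' @return an `amplicon_scores` data.frame.
#' @export
expand_patterns <- function(patterns, scheme, n_replicates = 4L) {
  stopifnot(inherits(scheme, "zone_scheme"), n_replicates >= 2L)
  miss <- setdiff(c("amplicon", "age", scheme$zone), names(patterns))
  if (length(miss)) stopf("pattern table lacks column(s): %s", paste(miss, collapse = ", "))
  rows <- lapply(seq_len(nrow(patterns)), function(i) {
    tps <- c(0, scheme$timepoint_min)
    syms <- c("+", unlist(patterns[i, scheme$zone], use.names = FALSE))
    do.call(rbind, lapply(seq_along(tps), function(j) {
      det <- switch(syms[j],
                    "+" = rep(TRUE, n_replicates),
                    "-" = rep(FALSE, n_replicates),
                    "±" = c(rep(TRUE, n_replicates - 1L), FALSE),
                    stopf("unknown symbol '%s'", syms[j]))
      data.frame(amplicon = patterns$amplicon[i], age = patterns$age[i],
                 timepoint_min = tps[j], replicate = seq_len(n_replicates),
                 detected = det, stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("amplicon_scores", "data.frame")
  out
}
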