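#' Read a digestion time course from TSV
#'
#' Expects a UTF-8 TSV with header `label time_min pct_attached sd n`
#' (decimal point, percentages as numbers 0-100, `NA` allowed for `sd`).
#' Validation failures report the offending file line.
#'
#' @param path TSV path.
#' @param label which course to load when the file holds several; may be
#'   omitted for a single-course file.
#' @return a [digestion_timecourse()].
#' @seealso [read_timecourses()] to load every course in a file.
#' @export
read_timecourse <- function(path, label = NULL) {
  tcs <- read_timecourses(path)
  if (is.null(label)) {
    if (length(tcs) != 1L)
      stopf("'%s' holds %d courses (%s); pick one with label=",
            path, length(tcs), paste(names(tcs), collapse = ", "))
    return(tcs[[1]])
  }
  if (!label %in% names(tcs))
    stopf("no course labelled '%s' in '%s' (have: %s)", label, path,
          paste(names(tcs), collapse = ", "))
  tcs[[label]]
}

#' Read all digestion time courses in a TSV file
#'
#' @param path TSV path (header `label time_min pct_attached sd n`).
#' @return named list of [digestion_timecourse()] objects.
#' @export
read_timecourses <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  d <- utils::read.delim(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  need <- c("label", "time_min", "pct_attached", "sd", "n")
  miss <- setdiff(need, names(d))
  if (length(miss)) stopf("%s: missing column(s) %s", path, paste(miss, collapse = ", "))
  if (nrow(d) == 0L) stopf("%s: empty time-course file", path)
  d$.line <- seq_len(nrow(d)) + 1L  # header is line 1
  out <- list()
  for (lab in unique(d$label)) {
    sub <- d[d$label == lab, ]
    bad_order <- which(diff(sub$time_min) <= 0)
    if (length(bad_order))
      stopf("%s line %d: times not strictly increasing for '%s'",
            path, sub$.line[bad_order[1] + 1L], lab)
    if (sub$time_min[1] != 0)
      stopf("%s line %d: course '%s' must start at time 0", path, sub$.line[1], lab)
    if (abs(sub$pct_attached[1] - 100) > 1e-9)
      stopf("%s line %d: pct_attached at time 0 must be 100 for '%s'",
            path, sub$.line[1], lab)
    bad_pct <- which(sub$pct_attached < 0 | sub$pct_attached > 100)
    if (length(bad_pct))
      stopf("%s line %d: pct_attached outside [0, 100]", path, sub$.line[bad_pct[1]])
    out[[lab]] <- digestion_timecourse(lab, sub$time_min, sub$pct_attached,
                                       sub$sd, sub$n)
  }
  out
}

#' Write digestion time course(s) to TSV
#'
#' @param tc a [digestion_timecourse()] or a list of them.
#' @param path destination TSV.
#' @return `path`, invisibly.
#' @export
write_timecourse <- function(tc, path) {
  if (inherits(tc, "digestion_timecourse")) tc <- list(tc)
  rows <- do.call(rbind, lapply(tc, function(x)
    cbind(label = attr(x, "label"), as.data.frame(x))))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a replicate-level amplicon score matrix from TSV
#'
#' Header `amplicon age timepoint_min replicate detected`; `detected` is
#' 0/1 or TRUE/FALSE. Duplicate (amplicon, age, timepoint, replicate)
#' rows are an error.
#'
#' @param path TSV path.
#' @return an `amplicon_scores` data.frame with replicate counts per
#'   (amplicon, age) in `attr(, "replicate_counts")`.
#' @export
read_score_matrix <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  d <- utils::read.delim(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  need <- c("amplicon", "age", "timepoint_min", "replicate", "detected")
  miss <- setdiff(need, names(d))
  if (length(miss)) stopf("%s: missing column(s) %s", path, paste(miss, collapse = ", "))
  if (nrow(d) == 0L) stopf("%s: empty score matrix", path)
  key <- paste(d$amplicon, d$age, d$timepoint_min, d$replicate, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- which(duplicated(key))[1]
    stopf("%s line %d: duplicate (amplicon, age, timepoint, replicate) row",
          path, dup + 1L)
  }
  d$detected <- as.logical(d$detected)
  if (anyNA(d$detected)) stopf("%s: unparseable 'detected' values", path)
  class(d) <- c("amplicon_scores", "data.frame")
  counts <- tapply(d$replicate, paste(d$amplicon, d$age, sep = "\r"),
                   function(x) length(unique(x)))
  attr(d, "replicate_counts") <- counts
  d
}

#' Write an amplicon score matrix to TSV
#'
#' @param scores an `amplicon_scores` data.frame.
#' @param path destination TSV.
#' @return `path`, invisibly.
#' @export
write_score_matrix <- function(scores, path) {
  out <- as.data.frame(scores)[, c("amplicon", "age", "timepoint_min",
                                   "replicate", "detected")]
  out$detected <- as.integer(out$detected)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a zone symbol pattern table from TSV
#'
#' Header `amplicon age` plus one column per zone (e.g. `D P VC E`) with
#' symbols `+`, `-`, `±`.
#'
#' @param path TSV path.
#' @return data.frame of patterns.
#' @export
read_patterns <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  d <- utils::read.delim(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8",
                         check.names = FALSE)
  if (!all(c("amplicon", "age") %in% names(d)))
    stopf("%s: pattern table needs 'amplicon' and 'age' columns", path)
  d
}

#' Path to a packaged example data file
#'
#' @param file file name under the package's `extdata/`; with no argument,
#'   lists the available files.
#' @return a file path, or a character vector of file names.
#' @export
nhos_example <- function(file = NULL) {
  if (is.null(file))
    return(list.files(system.file("extdata", package = "nhoskit")))
  path <- system.file("extdata", file, package = "nhoskit")
  if (path == "") stopf("no packaged file '%s'", file)
  path
}

# ---- run configuration -----------------------------------------------------

.run_config_keys <- c("n_loops", "mean_kbp", "cv", "embedded_target", "k0",
                      "alpha", "timepoints_min", "n_nucleoids", "n_replicates",
                      "detection_threshold", "dnase_u_per_ml", "amplicon_length_bp",
                      "evolve_mode", "extension_fraction", "p_sub", "noise_cv",
                      "rise_nm_per_bp", "seed", "out_dir", "log_level")

#' Default pipeline run configuration
#'
#' Study conditions for the simulation-recovery pipeline: a 1,000-loop
#' ensemble of mean size 42 kbp (CV 0.1) with 2 % of total DNA embedded in
#' the NM, digestion sampled at 0/5/15/30/60 min with DNase I at
#' 0.92 U/ml (metadata), 4 replicates of 10,000 nucleoids, PCR positivity
#' threshold 1e-3, and a mode-B evolution step absorbing 20 % of free DNA.
#'
#' @param seed master seed.
#' @return named list of class `run_config`.
#' @export
default_run_config <- function(seed = 1L) {
  structure(list(
    n_loops = 1000L, mean_kbp = 42, cv = 0.1, embedded_target = 0.02,
    k0 = 1e-4, alpha = 2, timepoints_min = c(0, 5, 15, 30, 60),
    n_nucleoids = 10000L, n_replicates = 4L, detection_threshold = 1e-3,
    dnase_u_per_ml = 0.92, amplicon_length_bp = 254L,
    evolve_mode = "B_extension", extension_fraction = 0.2, p_sub = 1,
    noise_cv = 0.05, rise_nm_per_bp = 0.34,
    seed = as.integer(seed), out_dir = NULL, log_level = "info"
  ), class = "run_config")
}

#' Read a pipeline run configuration from YAML
#'
#' Unknown keys are rejected by name; omitted keys take the defaults of
#' [default_run_config()]. The serialization round-trips losslessly with
#' [write_run_config()].
#'
#' @param path YAML file.
#' @return a `run_config` list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  vals <- yaml::read_yaml(path)
  unknown <- setdiff(names(vals), .run_config_keys)
  if (length(unknown))
    stopf("unknown config key(s): %s", paste(unknown, collapse = ", "))
  cfg <- default_run_config()
  for (k in names(vals)) cfg[[k]] <- vals[[k]]
  cfg$timepoints_min <- as.numeric(cfg$timepoints_min)
  cfg
}

#' Write a pipeline run configuration to YAML
#'
#' @param config a `run_config` list.
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config[!vapply(config, is.null, logical(1))], path)
  invisible(path)
}

# ---- model fixtures (FASTA / BED / TSV / YAML) -----------------------------

#' Export a nucleoid model and its amplicons as analysis fixtures
#'
#' Writes, under `prefix`: a synthetic genome as FASTA (one record per
#' loop, random sequence drawn from the model seed), MAR footprints and
#' amplicon intervals as BED6 (0-based half-open, loop id as the chrom
#' field), the loop table as full-precision TSV, and the model parameters
#' as YAML. [import_fixture()] reproduces the model exactly from these
#' files.
#'
#' @param model a `nucleoid_model`.
#' @param amplicons an [amplicon_table()] (may be `NULL`).
#' @param prefix path prefix for the output files.
#' @return named character vector of the files written.
#' @export
export_fixture <- function(model, amplicons = NULL, prefix) {
  stopifnot(inherits(model, "nucleoid_model"))
  if (!is.null(amplicons)) validate_amplicons(amplicons, model)
  dir <- dirname(prefix)
  if (!dir.exists(dir)) stopf("destination directory does not exist: %s", dir)
  files <- c(genome = paste0(prefix, "_genome.fasta"),
             mars = paste0(prefix, "_mars.bed"),
             amplicons = paste0(prefix, "_amplicons.bed"),
             loops = paste0(prefix, "_loops.tsv"),
             config = paste0(prefix, "_config.yaml"))

  set.seed(substream_seed(model$seed, 9L))
  seqs <- Biostrings::DNAStringSet(vapply(model$loops$total_bp, function(L)
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""),
    character(1)))
  names(seqs) <- model$loops$loop_id
  Biostrings::writeXStringSet(seqs, files[["genome"]])

  lp <- model$loops
  has_l <- lp$mar_left_bp > 0
  has_r <- lp$mar_right_bp > 0
  mars <- GenomicRanges::GRanges(
    seqnames = c(lp$loop_id[has_l], lp$loop_id[has_r]),
    ranges = IRanges::IRanges(
      start = c(rep(1L, sum(has_l)), round(lp$total_bp[has_r] - lp$mar_right_bp[has_r]) + 1L),
      end = c(round(lp$mar_left_bp[has_l]), round(lp$total_bp[has_r]))),
    name = c(paste0(lp$loop_id[has_l], "_MAR_L"), paste0(lp$loop_id[has_r], "_MAR_R")),
    score = 0L)
  rtracklayer::export(mars, files[["mars"]], format = "bed")

  if (!is.null(amplicons) && nrow(amplicons)) {
    amps <- GenomicRanges::GRanges(
      seqnames = amplicons$loop_id,
      ranges = IRanges::IRanges(start = round(amplicons$start_bp) + 1L,
                                width = round(amplicons$length_bp)),
      name = amplicons$name, score = 0L)
    rtracklayer::export(amps, files[["amplicons"]], format = "bed")
  } else files <- files[names(files) != "amplicons"]

  fmt <- lp
  for (col in c("total_bp", "mar_left_bp", "mar_right_bp", "free_bp", "genome_start"))
    fmt[[col]] <- sprintf("%.17g", lp[[col]])
  utils::write.table(fmt, files[["loops"]], sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")

  yaml::write_yaml(list(k0 = model$profile$k0, alpha = model$profile$alpha,
                        seed = model$seed, n_loops = nrow(lp)),
                   files[["config"]])
  files
}

#' Re-import a nucleoid model exported with [export_fixture()]
#'
#' @param prefix the prefix passed to [export_fixture()].
#' @return list with `model` (a `nucleoid_model`, equal to the exported
#'   one) and `amplicons` (an [amplicon_table()] or `NULL`).
#' @export
import_fixture <- function(prefix) {
  loops_path <- paste0(prefix, "_loops.tsv")
  cfg_path <- paste0(prefix, "_config.yaml")
  for (p in c(loops_path, cfg_path))
    if (!file.exists(p)) stopf("fixture file not found: %s", p)
  lp <- utils::read.delim(loops_path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  for (col in c("total_bp", "mar_left_bp", "mar_right_bp", "free_bp", "genome_start"))
    lp[[col]] <- as.numeric(lp[[col]])
  cfg <- yaml::read_yaml(cfg_path)
  model <- structure(list(loops = lp,
                          profile = accessibility_profile(cfg$k0, cfg$alpha),
                          seed = cfg$seed),
                     class = "nucleoid_model")
  amp_path <- paste0(prefix, "_amplicons.bed")
  amplicons <- NULL
  if (file.exists(amp_path)) {
    gr <- rtracklayer::import(amp_path, format = "bed")
    amplicons <- amplicon_table(
      name = gr$name,
      loop_id = as.character(GenomicRanges::seqnames(gr)),
      start_bp = GenomicRanges::start(gr) - 1L,
      length_bp = GenomicRanges::width(gr),
      model = model)
  }
  list(model = model, amplicons = amplicons)
}
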