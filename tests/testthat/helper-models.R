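# tiny builders shared across the suite

single_loop_model <- function(total_bp = 42000, mar_bp = 420,
                              k0 = 1e-4, alpha = 2, seed = 1L) {
  structure(list(
    loops = data.frame(loop_id = "L1", total_bp = total_bp,
                       mar_left_bp = mar_bp, mar_right_bp = mar_bp,
                       free_bp = total_bp - 2 * mar_bp, genome_start = 0,
                       stringsAsFactors = FALSE),
    profile = accessibility_profile(k0, alpha), seed = seed),
    class = "nucleoid_model")
}

table3_courses <- function() {
  read_timecourses(nhos_example("table3_timecourses.tsv"))
}

table5_calls <- function() {
  sch <- zone_scheme(c(5, 15, 30, 60))
  mapping_table(read_score_matrix(nhos_example("table5_scores.tsv")), sch)
}

# run the default recovery experiment once per session
default_recovery <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- run_recovery_experiment(default_run_config(seed = 1))
    cache
  }
})
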