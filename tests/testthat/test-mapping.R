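test_that("replicate scoring follows the +/±/- footnote semantics", {
  expect_equal(score_replicates(c(TRUE, TRUE, TRUE, FALSE)), "±")
  expect_equal(score_replicates(rep(TRUE, 4)), "+")
  expect_equal(score_replicates(rep(FALSE, 4)), "-")
  expect_equal(score_replicates(TRUE), "+")
  expect_error(score_replicates(logical(0)), "no replicates")
})

test_that("position calls pick the innermost positive zone", {
  sch <- zone_scheme(c(5, 15, 30, 60))
  expect_equal(call_position(c("+", "+", "+", "-"), sch)$zone, "VC")   # NFM at P0
  expect_equal(call_position(c("+", "-", "-", "-"), sch)$zone, "D")    # GFAP at P7
  expect_equal(call_position(c("+", "+", "+", "+"), sch)$zone, "E")    # MPZ 5' at P80
  cl <- call_position(c("+", "+", "+", "±"), sch)
  expect_equal(cl$zone, "E")
  expect_true(cl$ambiguous)
  # inward - followed by + is impossible under outside-in digestion
  bad <- call_position(c("-", "+", "+", "+"), sch)
  expect_true(is.na(bad$zone))
  expect_match(bad$violations, "non-monotone")
  none <- call_position(rep("-", 4), sch)
  expect_match(none$violations, "no positive zone")
})

test_that("strict mode treats ± as negative", {
  sch <- zone_scheme(c(5, 15, 30, 60))
  cl <- call_position(c("+", "+", "±", "-"), sch, ambiguous_counts_positive = FALSE)
  expect_equal(cl$zone, "P")
  expect_false(cl$ambiguous)
})

test_that("random admissible patterns have a unique innermost-positive call", {
  sch <- zone_scheme(c(5, 15, 30, 60))
  set.seed(7)
  for (i in 1:200) {
    k <- sample(1:4, 1)  # positive prefix length
    pattern <- c(sample(c("+", "±"), k, replace = TRUE), rep("-", 4 - k))
    expect_true(monotonicity_check(pattern))
    cl <- call_position(pattern, sch)
    expect_equal(cl$zone, sch$zone[k])
    expect_equal(cl$ambiguous, pattern[k] == "±")
  }
})

test_that("the transcribed score fixture reproduces every published call", {
  calls <- table5_calls()
  expect_equal(nrow(calls), 36L)
  expect_true(all(is.na(calls$violation)))
  expected <- rbind(
    data.frame(age = "P0",
               amplicon = c("NFM", "NFL", "MBP", "GFAP", "MPZ5p", "MPZ3p", "ACT", "ALB", "AFP"),
               zone = c("VC", "E", "E", "P", "E", "P", "E", "E", "E"),
               ambiguous = c(FALSE, TRUE, FALSE, TRUE, FALSE, TRUE, TRUE, TRUE, TRUE)),
    data.frame(age = "P7",
               amplicon = c("NFM", "NFL", "MBP", "GFAP", "MPZ5p", "MPZ3p", "ACT", "ALB", "AFP"),
               zone = c("VC", "VC", "E", "D", "E", "D", "VC", "VC", "VC"),
               ambiguous = c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE)),
    data.frame(age = "P80",
               amplicon = c("NFM", "NFL", "MBP", "GFAP", "MPZ5p", "MPZ3p", "ACT", "ALB", "AFP"),
               zone = c("VC", "E", "E", "VC", "E", "VC", "VC", "VC", "VC"),
               ambiguous = c(TRUE, TRUE, TRUE, TRUE, FALSE, TRUE, FALSE, FALSE, FALSE)),
    data.frame(age = "P540",
               amplicon = c("NFM", "NFL", "MBP", "GFAP", "MPZ5p", "MPZ3p", "ACT", "ALB", "AFP"),
               zone = c("P", "P", "VC", "D", "P", "D", "P", "P", "P"),
               ambiguous = c(TRUE, TRUE, TRUE, FALSE, TRUE, FALSE, TRUE, TRUE, TRUE)))
  m <- merge(as.data.frame(calls), expected, by = c("amplicon", "age"),
             suffixes = c("", "_exp"))
  expect_equal(nrow(m), 36L)
  expect_equal(m$zone, m$zone_exp)
  expect_equal(m$ambiguous, m$ambiguous_exp)
})

test_that("violating rows are retained without aborting the other calls", {
  sch <- zone_scheme(c(5, 15, 30, 60))
  smry <- data.frame(
    amplicon = rep(c("ok", "bad"), each = 4), age = "P0",
    zone = rep(c("D", "P", "VC", "E"), 2),
    symbol = c("+", "+", "-", "-", "-", "+", "+", "+"))
  mt <- mapping_table(smry, sch)
  expect_equal(mt$zone[mt$amplicon == "ok"], "P")
  expect_true(is.na(mt$zone[mt$amplicon == "bad"]))
  expect_match(mt$violation[mt$amplicon == "bad"], "non-monotone")
})

test_that("positional shift counts movements away from the NM", {
  calls <- table5_calls()
  shift <- positional_shift(calls[calls$age == "P0", ], calls[calls$age == "P540", ])
  expect_gt(shift$summary[["away"]], shift$summary[["toward"]])
  expect_equal(sum(shift$summary), 9)
  # identity
  same <- positional_shift(calls[calls$age == "P7", ], calls[calls$age == "P7", ])
  expect_equal(unname(same$summary[["unchanged"]]), 9)
  expect_true(all(same$per_amplicon$delta_rank == 0))
  # mismatched amplicon sets
  expect_error(positional_shift(calls[calls$age == "P0", ][1:3, ],
                                calls[calls$age == "P540", ]),
               "amplicon sets differ")
})

test_that("pattern expansion round-trips through replicate scoring", {
  sch <- zone_scheme(c(5, 15, 30, 60))
  pat <- read_patterns(nhos_example("table5_patterns.tsv"))
  sc <- expand_patterns(pat, sch, n_replicates = 4L)
  smry <- summarize_scores(sc, sch)
  for (i in seq_len(nrow(pat))) {
    sub <- smry[smry$amplicon == pat$amplicon[i] & smry$age == pat$age[i], ]
    expect_equal(sub$symbol[match(sch$zone, sub$zone)],
                 unname(unlist(pat[i, sch$zone])))
  }
})
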