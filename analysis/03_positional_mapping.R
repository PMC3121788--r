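#!/usr/bin/env Rscript
# Positional mapping of the nine gene targets relative to the NM from the
# transcribed replicate-level PCR score matrix, and the positional shift
# between newborn (P0) and aged (P540) neurons.

library(nhoskit)

dir.create("results", showWarnings = FALSE)
scheme <- zone_scheme(c(5, 15, 30, 60))
scores <- read_score_matrix(nhos_example("table5_scores.tsv"))
calls <- mapping_table(scores, scheme)
write.table(calls, "results/mapping_table.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE, fileEncoding = "UTF-8")
cat(sprintf("Called %d (amplicon, age) pairs; %d scorable.\n",
            nrow(calls), sum(is.na(calls$violation))))

cat("\nZone placements by age (E = embedded ... D = distal):\n")
tab <- with(calls, table(age, factor(zone, levels = c("E", "VC", "P", "D"))))
print(tab[c("P0", "P7", "P80", "P540"), ])

shift <- positional_shift(calls[calls$age == "P0", ], calls[calls$age == "P540", ])
write.table(shift$per_amplicon, "results/positional_shifts_p0_p540.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("\nP0 -> P540: %d targets moved away from the NM, %d toward, %d unchanged.\n",
            shift$summary[["away"]], shift$summary[["toward"]],
            shift$summary[["unchanged"]]))

# the MPZ gene's intrinsic topology: its 5' end stays closer to the NM than
# its 3' end at every age
mpz <- merge(calls[calls$amplicon == "MPZ5p", c("age", "rank")],
             calls[calls$amplicon == "MPZ3p", c("age", "rank")],
             by = "age", suffixes = c("_5p", "_3p"))
stopifnot(all(mpz$rank_5p <= mpz$rank_3p))
cat("MPZ 5' region is at least as close to the NM as the 3' region at all ages.\n")
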