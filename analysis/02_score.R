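#!/usr/bin/env Rscript
# Validate and score the cohort written by 01_simulate.R: apply the
# inclusion rules, compute ISS/NISS/RTS and both TRISS survival
# probabilities per patient, and write the scored registry.

library(traumascore)

cohort <- read_registry("results/cohort.csv")
split <- apply_exclusions(cohort)
cat(sprintf("read %d records; excluded %d (fatal validation issues)\n",
            nrow(cohort), nrow(split$excluded)))
if (nrow(split$issues)) {
  print(table(split$issues$rule))
}

scored <- score_cohort(split$cohort)
write.csv(scored, "results/scored.csv", row.names = FALSE)

cat(sprintf("score ranges: ISS %d-%d, NISS %d-%d, RTS %.3f-%.4f\n",
            min(scored$iss), max(scored$iss), min(scored$niss),
            max(scored$niss), min(scored$rts), max(scored$rts)))
cat(sprintf("coefficient sets: %d blunt, %d penetrating\n",
            sum(scored$coefficient_set == "blunt"),
            sum(scored$coefficient_set == "penetrating")))
cat("written: results/scored.csv\n")
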