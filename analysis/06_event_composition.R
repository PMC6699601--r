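#!/usr/bin/env Rscript
# Raw-level composition of the task events: does elevated NI come from
# persistently high or persistently low power? Distribution of {-1, 1, 3}
# per event in the high beta/gamma range plus a Kruskal-Wallis contrast.

suppressPackageStartupMessages(library(teamneuro))

levels <- utils::read.csv("results/levels.csv", stringsAsFactors = FALSE)
events <- utils::read.csv("results/events.csv", stringsAsFactors = FALSE)

gamma_bins <- band_scheme("B")$gamma
res <- level_composition(levels, events, bins = gamma_bins)
utils::write.csv(res$composition, "results/event_level_composition.csv",
                 row.names = FALSE, quote = FALSE)
jsonlite::write_json(res$test, "results/event_level_test.json",
                     auto_unbox = TRUE)

cat("Gamma-band (33-40 Hz) level composition per event:\n")
print(res$composition, row.names = FALSE)
cat(sprintf("Kruskal-Wallis across events: H = %.1f, df = %d, p = %.3g\n",
            res$test$H, res$test$df, res$test$p))
cat("The seizure epoch was injected at level -1: its p_low should dominate,\n")
cat("showing organization driven by suppressed, not elevated, power.\n")
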