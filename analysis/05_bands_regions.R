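#!/usr/bin/env Rscript
# Frequency-band and scalp-region structure of the team NI: per-band NI
# traces, an anterior-vs-posterior rank-sum contrast inside an event
# window, and a time x frequency map for one sensor.

suppressPackageStartupMessages(library(teamneuro))

levels <- utils::read.csv("results/levels.csv", stringsAsFactors = FALSE)
events <- utils::read.csv("results/events.csv", stringsAsFactors = FALSE)
nds <- build_team_nds(levels)
tni <- team_ni(nds)

# per-band NI (pooled over sensors)
bands <- band_aggregate(tni, band_scheme("A"))
utils::write.csv(bands, "results/band_ni.csv", row.names = FALSE,
                 quote = FALSE)

# anterior vs posterior during the second intubation, 18-40 Hz
ev <- events[events$label == "INTB-2", ]
hi <- tni[tni$freq_hz >= 18, ]
per_sensor <- do.call(rbind, lapply(split(hi, hi$sensor), function(x) {
  avg <- average_ni(x)
  data.frame(sensor = x$sensor[1], second = avg$second, ni = avg$ni)
}))
win <- bracket_event(per_sensor, event_segment(ev$label, ev$start_s, ev$end_s))
contrast <- region_contrast(win[win$core, ], region_map("simulation"))
jsonlite::write_json(contrast, "results/region_contrast.json",
                     auto_unbox = TRUE)

# time x frequency map at F3
tf <- time_frequency_map(tni, "F3")
utils::write.csv(tf, "results/tf_map_F3.csv", quote = FALSE)

band_means <- tapply(bands$ni, bands$band, mean, na.rm = TRUE)
cat("Mean NI by band (bits):\n")
print(round(band_means, 3))
cat(sprintf("Anterior vs posterior during %s (18-40 Hz): Z = %.2f, p = %.3g, fold = %.2f\n",
            ev$label, contrast$Z, contrast$p, contrast$fold_ratio))
cat("Time x frequency map for F3:", nrow(tf), "s x", ncol(tf), "bins ->",
    "results/tf_map_F3.csv\n")
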