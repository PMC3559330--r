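#!/usr/bin/env Rscript
# Stage 2: classify the tidal regime of every day of the season.
#
# High tides are local maxima of the gauge record (>= 0.1 m prominence,
# >= 8 h apart); a day with exactly one high tide is diurnal, two or more
# semidiurnal. Daily amplitude is half the daily range. Writes
# results/regime_calendar.csv.

library(tideforage)

tide <- read_tide_csv("results/raw/tide.csv")
cal <- build_regime_calendar(tide)
write.csv(cal, "results/regime_calendar.csv", row.names = FALSE)

runs <- rle(cal$regime)
cat("Season of", nrow(cal), "days:",
    sum(cal$regime == "diurnal"), "diurnal,",
    sum(cal$regime == "semidiurnal"), "semidiurnal,",
    sum(cal$regime == "unclassified"), "unclassified\n")
cat("Regime runs:",
    paste(runs$lengths, substr(runs$values, 1, 1), collapse = ", "), "\n")
cat(sprintf("Mean daily amplitude: %.2f m (diurnal) vs %.2f m (semidiurnal)\n",
            mean(cal$amplitude_m[cal$regime == "diurnal"]),
            mean(cal$amplitude_m[cal$regime == "semidiurnal"])))
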