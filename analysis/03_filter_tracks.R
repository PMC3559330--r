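#!/usr/bin/env Rscript
# Stage 3: clean the ARGOS tracks.
#
# Fixes strictly inside the land mask are rejected, then the sequential
# maximum-speed filter removes fixes implying travel above 8 km/h
# (class 3 fixes and track endpoints are immune). Writes
# results/filtered_fixes.csv with a retained flag and rejection reason.

library(tideforage)

fixes <- read_argos_csv("results/raw/argos.csv")
mask <- read_landmask("results/raw/landmask.geojson")

n0 <- nrow(fixes)
fixes <- apply_landmask(fixes, mask)
n_land <- sum(!fixes$retained)
fixes <- speed_filter(fixes, vmax = 8)
n_speed <- sum(fixes$reason == "speed", na.rm = TRUE)

write.csv(fixes, "results/filtered_fixes.csv", row.names = FALSE)

cat(sprintf("%d fixes from %d birds\n", n0, length(unique(fixes$animal_id))))
cat(sprintf("  rejected on land:      %4d\n", n_land))
cat(sprintf("  rejected by speed:     %4d\n", n_speed))
cat(sprintf("  retained:              %4d (%.1f%% removed)\n",
            sum(fixes$retained), 100 * (n0 - sum(fixes$retained)) / n0))
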