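#!/usr/bin/env Rscript
# Step 5 — histogram figures from the analysed dataset.
#
# Hourly and seasonal in-buffer activity histograms and the phase
# occupancy contrast, drawn from the tables step 2 wrote. Requires
# steps 1-2 to have run; figures land in results/figures/.

library(fishwolf)
library(ggplot2)

ana_dir <- "results/dataset/analysis"
stopifnot(dir.exists(ana_dir))
dir.create("results/figures", showWarnings = FALSE, recursive = TRUE)

hours <- readr::read_csv(file.path(ana_dir, "hour_histogram.csv"),
                         show_col_types = FALSE)
p1 <- ggplot(hours, aes(hour, n)) +
  geom_col(fill = "steelblue4") +
  labs(x = "hour of day (local)", y = "in-buffer fixes",
       title = "Hourly activity within 20 m of the fishing water source") +
  theme_minimal()
ggsave("results/figures/hourly_activity.pdf", p1, width = 6, height = 4)

dates <- readr::read_csv(file.path(ana_dir, "date_histogram.csv"),
                         show_col_types = FALSE)
p2 <- ggplot(dates, aes(date, n)) +
  geom_col(fill = "darkolivegreen") +
  labs(x = NULL, y = "in-buffer fixes",
       title = "Seasonal activity within 20 m of the fishing water source") +
  theme_minimal()
ggsave("results/figures/seasonal_activity.pdf", p2, width = 6, height = 4)

occ <- readr::read_csv(file.path(ana_dir, "occupancy.csv"), show_col_types = FALSE)
occ$phase <- factor(occ$phase, levels = c("before", "during", "after"))
p3 <- ggplot(occ, aes(phase, hours_per_day)) +
  geom_col(fill = "sienna") +
  facet_wrap(~radius, scales = "free_y",
             labeller = labeller(radius = function(r) paste0(r, " m buffer"))) +
  labs(x = NULL, y = "hours per day",
       title = "Buffer occupancy before, during and after the fishing period") +
  theme_minimal()
ggsave("results/figures/phase_occupancy.pdf", p3, width = 7, height = 4)

cat("figures written to results/figures/\n")
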