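#!/usr/bin/env Rscript
# Estimate WBGT hour by hour over the simulated weather, aggregate to daily
# summaries, and detect heat-wave episodes and tropical nights.
# Reads results/synthetic/weather.csv (run 01_simulate.R first).

suppressPackageStartupMessages(library(heatstrain))

out_dir <- "results/events"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

weather <- read_weather("results/synthetic/weather.csv")
est <- series_wbgt(weather)
write_weather(est, file.path(out_dir, "weather_wbgt.csv"))
cat(sprintf("estimated WBGT for %d hours; %d outside the formula envelope\n",
            nrow(est), sum(!est$valid)))

daily <- daily_summaries(weather)
daily$tropical_night <- is_tropical_night(daily$night_tmin)
episodes <- detect_heat_waves(daily)
daily$heat_wave_day <- in_heat_wave(daily$date, episodes)
readr::write_csv(daily, file.path(out_dir, "daily_summaries.csv"))
readr::write_csv(episodes, file.path(out_dir, "heat_wave_episodes.csv"))

cat(sprintf("%d heat-wave episodes covering %d days; %d tropical nights (%d indeterminate)\n",
            nrow(episodes), sum(daily$heat_wave_day),
            sum(daily$tropical_night, na.rm = TRUE),
            sum(is.na(daily$tropical_night))))
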