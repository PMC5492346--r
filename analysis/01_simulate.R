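#!/usr/bin/env Rscript
# Simulate the study's two kinds of input: an hourly summer weather series
# with declared heat-wave episodes and tropical nights, and a worker cohort
# drawn at the published prevalences. Outputs land in results/synthetic/.

suppressPackageStartupMessages(library(heatstrain))

out_dir <- "results/synthetic"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

weather_cfg <- weather_gen_config(
  n_days = 30,
  base_tmean = 26, diurnal_amplitude = 6, # ordinary days peak at 32, below the advisory threshold
  heatwave_episodes = list(
    list(start_day = 8, length = 3, peak_tmax = 35.5),
    list(start_day = 20, length = 2, peak_tmax = 34.0)
  ),
  tropical_nights = c(9, 10, 21),
  noise_sd = 0.4,
  seed = 20130801
)
weather <- generate_weather(weather_cfg)
write_weather(weather, file.path(out_dir, "weather.csv"))
cat(sprintf("simulated %d hourly observations over %d days (seed %d)\n",
            nrow(weather), weather_cfg$n_days, weather_cfg$seed))

cohort_cfg <- cohort_gen_config(n_cases = 1000, seed = 20130802)
cohort <- generate_cohort(cohort_cfg)
write_cases(cohort, file.path(out_dir, "cohort.csv"))
cat(sprintf("simulated a %d-worker cohort at the published prevalences\n",
            nrow(cohort)))
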