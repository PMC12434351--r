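#!/usr/bin/env Rscript
# Stage 6: duty-cycle and storage arithmetic for deployment planning.
#
# The high-frequency setting (an image every 30 s, 0700-0830) produces 180
# images/day and fills a 6480-image card in 36 days; the low-frequency
# setting (every 30 min, 0700-0800, both endpoints captured) runs for a
# year. A 2-h interval around the clock also lasts a year on one card.

library(beachtrack)
dir.create("results", showWarnings = FALSE)

settings <- list(
  high_frequency = duty_cycle("0700", "0830", 30),
  low_frequency  = duty_cycle("0700", "0800", 1800, "include_both"),
  two_hourly     = duty_cycle("0000", "2400", 7200)
)
capacity <- 6480

tbl <- do.call(rbind, lapply(names(settings), function(nm) {
  d <- settings[[nm]]
  rate <- images_per_day(d)
  data.frame(
    setting = nm,
    window = paste0(d$window_start, "-", d$window_end),
    interval_s = d$interval_seconds,
    images_per_day = rate,
    days_to_capacity = days_to_capacity(capacity, rate),
    year_feasible = feasible_duration(capacity, d, 365)$feasible
  )
}))
print(tbl)
utils::write.csv(tbl, "results/camera_logistics.csv", row.names = FALSE)

cat(sprintf("high-frequency: %d images/day, card full after %d days (%d images)\n",
            tbl$images_per_day[1], tbl$days_to_capacity[1],
            tbl$images_per_day[1] * tbl$days_to_capacity[1]))
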