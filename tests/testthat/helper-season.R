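# hand-built true_season objects for deterministic observation-model tests

manual_season <- function(tracks, n_days, beach_length_m = 200L,
                          spring_tide_day0 = 1L) {
  tidal_day <- (seq_len(n_days) - spring_tide_day0) %% 15L
  phase <- beachtrack::classify_phase(tidal_day)
  if (nrow(tracks) > 0) {
    tracks$tidal_day <- tidal_day[tracks$day]
    tracks$phase <- phase[tracks$day]
    tracks <- cbind(track_id = seq_len(nrow(tracks)), tracks)
  }
  structure(
    list(
      config = beachtrack::season_config(
        beach_length_m = beach_length_m, n_days = n_days,
        spring_tide_day0 = spring_tide_day0
      ),
      days = data.frame(
        day = seq_len(n_days), tidal_day = tidal_day, phase = phase,
        n_tracks = tabulate(tracks$day, nbins = n_days)
      ),
      tracks = tracks
    ),
    class = "true_season"
  )
}

full_beach_station <- function(beach_length_m) {
  beachtrack::camera_station("cam_full", 0, beach_length_m)
}
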