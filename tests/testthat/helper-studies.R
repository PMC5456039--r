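# Shared experiment: simulate a study, process tracks to interpolated
# bird-days, attach ground-truth ARS labels and environmental covariates,
# and return the per-day design list. Used by the habitat-model recovery
# tests.
truth_labelled_designs <- function(cfg) {
  st <- trackars::simulate_study(cfg)
  locs <- list()
  for (b in unique(st$tracks$bird_id)) {
    tr <- trackars::project_fixes(st$tracks[st$tracks$bird_id == b, ],
                                  cfg$colony_lonlat)
    trips <- trackars::split_trips(tr, cfg$colony_lonlat)
    for (tt in trips) {
      bds <- suppressMessages(
        trackars::split_bird_days(tt, cfg$colony_lonlat))
      for (bd in bds) {
        bd$bird_id <- b
        bd$trip_id <- tt$trip_id[2]
        locs[[length(locs) + 1]] <- bd
      }
    }
  }
  locs <- do.call(rbind, locs)
  locs$label <- trackars::truth_ars_labels(locs, st$truth$bouts)
  # multi-day wanderers can drift past the raster domain edge; those
  # locations annotate to NA and are dropped from the designs
  ann <- suppressWarnings(trackars::annotate_locations(locs, st$rasters))
  list(designs = suppressMessages(trackars::day_designs(ann)), study = st)
}
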