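# shared fixtures: presets are cached once per test run

medicyc_cfg <- local({
  cfg <- NULL
  function() {
    if (is.null(cfg)) cfg <<- pgti_preset("medicyc_63MeV")
    cfg
  }
})

s2c2_cfg <- local({
  cfg <- NULL
  function() {
    if (is.null(cfg)) cfg <<- pgti_preset("s2c2_148MeV")
    cfg
  }
})

# distal half-maximum crossing of a (spatial) profile: the fall-off position
falloff_position <- function(h) {
  ctr <- bin_centers(h)
  cts <- h$counts
  pop <- which(cts > 0)
  distal <- ctr >= ctr[pop[1]] + 0.5 * (ctr[pop[length(pop)]] - ctr[pop[1]])
  pk <- which(distal & cts == max(cts[distal]))[1]
  half <- cts[pk] / 2
  j <- pk
  while (j < length(cts) && cts[j + 1] >= half) j <- j + 1
  below <- which(cts[(j + 1):length(cts)] < half)
  j <- j + below[1]
  stats::approx(c(cts[j - 1], cts[j]), c(ctr[j - 1], ctr[j]), xout = half)$y
}

# reference map + resolved detector for the 63 MeV reference geometry
medicyc_reco <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- medicyc_cfg()
      model <- build_range_model(cfg)
      map <- proton_time_map(build_geometry(cfg), cfg$beam$energy_MeV,
                             model = model)
      det <- resolve_detector(build_detectors(cfg)[[1]], map)
      cache <<- list(cfg = cfg, model = model, map = map, det = det,
                     ref_map = build_reference_map(map, det))
    }
    cache
  }
})
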