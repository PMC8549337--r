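# Independent oracles and small fixtures used across the suite.

# Brute-force connected component by scalar depth-first search: an
# implementation deliberately separate from the package's vectorised
# frontier BFS. Returns sorted 1-based linear indices of the component of
# `fg` containing seed_ijk.
oracle_component <- function(fg, seed_ijk, connectivity) {
  d <- dim(fg)
  nb <- list()
  for (di in -1:1) for (dj in -1:1) for (dk in -1:1) {
    o <- sum(abs(c(di, dj, dk)))
    if (o == 0) next
    keep <- switch(as.character(connectivity),
                   "6" = o == 1, "18" = o <= 2, "26" = TRUE)
    if (keep) nb[[length(nb) + 1]] <- c(di, dj, dk)
  }
  visited <- array(FALSE, d)
  lin <- function(v) (v[3] - 1) * d[1] * d[2] + (v[2] - 1) * d[1] + v[1]
  stack <- list(as.integer(seed_ijk))
  visited[lin(seed_ijk)] <- TRUE
  found <- lin(seed_ijk)
  while (length(stack) > 0) {
    v <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    for (o in nb) {
      w <- v + o
      if (any(w < 1) || any(w > d)) next
      lw <- lin(w)
      if (fg[lw] && !visited[lw]) {
        visited[lw] <- TRUE
        found <- c(found, lw)
        stack[[length(stack) + 1]] <- w
      }
    }
  }
  sort(found)
}

# A small all-soft-tissue scene (no air gap, no flap, no bone) with the
# given markers; handy for closed-form forward-model checks.
flat_scene <- function(markers, seed = 1, ...) {
  build_scene(scene_config(markers, seed = seed, air_thickness = 0,
                           flap_thickness = 0, include_bone = FALSE,
                           depth_range = c(6, 7), ...))
}

# Noise-free, blur-free protocol at a given energy.
ideal_protocol <- function(kv, tin_filter = FALSE) {
  acquisition_protocol(kv, psf_fwhm = 0, noise_sd = 0,
                       tin_filter = tin_filter)
}

# material codes as the package stores them
mat_code <- function(name) {
  codes <- stats::setNames(1:7, c("air", "soft_tissue", "muscle_flap",
                                  "bone", "tooth", "titanium_clip",
                                  "calcification"))
  codes[[name]]
}
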