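# compact phantoms used throughout the suite: same anatomy model as the
# study grid, on a desk-size grid
small_geom <- function(diameter = 20, amplitude = 10,
                       dim = c(70L, 70L, 90L)) {
  phantom_geometry(diameter, amplitude, dim = dim)
}

small_case <- local({
  cache <- new.env(parent = emptyenv())
  function(diameter = 20, amplitude = 10) {
    key <- sprintf("d%g_a%g", diameter, amplitude)
    if (is.null(cache[[key]])) {
      ph <- build_phantom(small_geom(diameter, amplitude))
      itv <- union_itv(ph$gtvs)
      ptv <- expand_margin(itv, 5)
      cache[[key]] <- list(phantom = ph, itv = itv, ptv = ptv,
                           gtv_ref = ph$gtvs[[ph$reference_phase]])
    }
    cache[[key]]
  }
})

# uniform-value volume helper
uniform_volume <- function(value, dim = c(8L, 8L, 8L), spacing = 1)
  new_volume(array(value, dim), spacing)

# linear SI ramp dose: D = g * z_mm
ramp_volume <- function(g, dim = c(20L, 20L, 40L), spacing = 1) {
  z <- (seq_len(dim[3]) - 1) * spacing
  new_volume(aperm(array(rep(g * z, each = dim[1] * dim[2]), dim), c(1, 2, 3)),
             spacing)
}

# brute-force D_x oracle: largest dose level d in the multiset with
# (fraction of voxels >= d) >= x/100, by exhaustive scan of levels
oracle_dx <- function(doses, x) {
  lev <- sort(unique(doses), decreasing = TRUE)
  keep <- vapply(lev, function(d) mean(doses >= d) >= x / 100, logical(1))
  max(lev[keep])
}
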