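# Shared fixtures, all generated in code.

# small fast grid for unit tests (half the default field of view)
small_grid <- function() grid_geometry(c(32, 32, 16), c(3, 3, 3))

small_spec <- function(seed = 1, ...) {
  phantom_spec(grid = small_grid(), brain_semiaxes_mm = c(40, 40, 21),
               tumor_radius_mm = 9, seed = seed, ...)
}

small_case <- function(seed = 1, archetype = "compact", group = "WHO_I", ...) {
  generate_phantom(small_spec(seed), archetype_params(archetype, ...),
                   case_id = sprintf("t%03d", seed), group = group)
}

# brute-force EDT oracle: minimum over all foreground voxel centers
brute_edt <- function(mask, spacing) {
  idx <- which(mask, arr.ind = TRUE)
  d <- dim(mask)
  pts <- as.matrix(expand.grid(seq_len(d[1]), seq_len(d[2]), seq_len(d[3])))
  out <- apply(pts, 1, function(p) {
    sqrt(min(colSums(((t(idx) - p) * spacing)^2)))
  })
  array(out, dim = d)
}

# brute-force Dice coefficient of two binary volumes
dice <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

# U statistic of the first sample by explicit pair counting
brute_U <- function(x, y) {
  sum(outer(x, y, `>`)) + 0.5 * sum(outer(x, y, `==`))
}
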