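# Programmatic fixtures: all test volumes are generated in code.

# logical ball of radius R_um centred in its grid
ball_array <- function(R_um, spacing = 1, margin_vox = 5) {
  n <- 2 * ceiling(R_um / spacing) + 2 * margin_vox + 1
  g <- ((0:(n - 1)) - (n - 1) / 2) * spacing
  r2 <- outer(outer(g^2, g^2, "+"), g^2, "+")
  array(r2 <= R_um^2, c(n, n, n))
}

ball_mask <- function(R_um, spacing = 1, margin_vox = 5) {
  binary_mask(ball_array(R_um, spacing, margin_vox), spacing)
}

# two overlapping balls of radius R with centres 2*offset apart along x:
# a dumbbell with a neck at the midplane when offset < R
dumbbell_array <- function(R = 6, offset = 4.5, spacing = 1) {
  n <- 2 * ceiling(R + offset) + 11
  g <- ((0:(n - 1)) - (n - 1) / 2) * spacing
  gx1 <- (g - offset)^2
  gx2 <- (g + offset)^2
  b1 <- outer(outer(gx1, g^2, "+"), g^2, "+") <= R^2
  b2 <- outer(outer(gx2, g^2, "+"), g^2, "+") <= R^2
  list(mask = array(b1 | b2, c(n, n, n)), n = n,
       center_plane = (n - 1) / 2 + 1)
}

# radial distance array for a grid (um)
radial_field <- function(dim, spacing, center) {
  gx <- ((0:(dim[1] - 1)) * spacing[1] - center[1])^2
  gy <- ((0:(dim[2] - 1)) * spacing[2] - center[2])^2
  gz <- ((0:(dim[3] - 1)) * spacing[3] - center[3])^2
  sqrt(outer(outer(gx, gy, "+"), gz, "+"))
}
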