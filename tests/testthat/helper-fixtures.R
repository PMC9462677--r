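# shared fixtures, built once per test run

.fixtures <- new.env(parent = emptyenv())

# the workhorse phantom: full geometry at a 5 mm tet10 mesh, solved
phantom_fix <- function() {
  if (is.null(.fixtures$ph5))
    .fixtures$ph5 <- make_phantom(phantom_spec(edge = 5))
  .fixtures$ph5
}

# coarse phantom for cheap repeated solves
coarse_phantom_fix <- function() {
  if (is.null(.fixtures$ph7))
    .fixtures$ph7 <- make_phantom(phantom_spec(edge = 7))
  .fixtures$ph7
}

rotation_axis_angle <- function(axis, angle) {
  a <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -a[3], a[2], a[3], 0, -a[1], -a[2], a[1], 0),
              3, 3, byrow = TRUE)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

random_rigid <- function(max_angle_deg = 10, max_t = 2) {
  ax <- stats::rnorm(3)
  ang <- stats::runif(1, 0, max_angle_deg * pi / 180)
  rigid_transform(rotation_axis_angle(ax, ang),
                  stats::runif(3, -max_t, max_t))
}

# a uniform-density grid covering a box mesh with margin
uniform_grid <- function(hu, lo = c(-5, -5, -5), hi = c(15, 15, 15),
                         spacing = c(1, 1, 1)) {
  dims <- ceiling((hi - lo) / spacing) + 1L
  density_grid(array(hu, dims), origin = lo, spacing = spacing,
               dims = dims, value_kind = "HU")
}
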