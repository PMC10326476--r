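# Small in-code fixtures shared across test files.

# tiny centered grid: odd x-shape so a voxel column sits on x = 0
tiny_grid <- function(shape = c(9L, 9L, 9L), voxel = 2) {
  template_grid(shape, voxel)
}

# constant volume on a grid
const_volume <- function(value, grid = tiny_grid()) {
  volume_image(array(value, dim = grid$shape), grid)
}

# mask from a logical predicate over world coordinates
coord_mask <- function(grid, pred) {
  X <- world_coordinates(grid, 1L)
  Y <- world_coordinates(grid, 2L)
  Z <- world_coordinates(grid, 3L)
  binary_mask(pred(X, Y, Z), grid)
}

# random mask with given inclusion probability
random_mask <- function(grid, p = 0.3) {
  binary_mask(array(stats::runif(prod(grid$shape)) < p, dim = grid$shape),
              grid)
}
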