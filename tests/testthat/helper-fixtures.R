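# shared fixture builders; all fixtures are generated in code

const_grid <- function(value, nr = 8, nc = 8, ps = 1, origin = c(0, nr * ps),
                       date = NA_real_) {
  ndvi_grid(matrix(value, nr, nc), pixel_size = ps, origin = origin,
            date = date, range = if (value <= 1) c(0, 1) else NULL)
}

iid_beta_grid <- function(nr, nc, alpha, beta, ps = 1, seed = 1,
                          date = NA_real_) {
  set.seed(seed)
  ndvi_grid(matrix(stats::rbeta(nr * nc, alpha, beta), nr, nc),
            pixel_size = ps, date = date)
}

# two-date stack of constant grids, for plumbing tests
const_stack <- function(values, dates, nr = 8, nc = 8, ps = 1) {
  grid_stack(Map(function(v, d) const_grid(v, nr, nc, ps, date = d),
                 values, dates))
}

beta_skewness <- function(a, b) {
  2 * (b - a) * sqrt(a + b + 1) / ((a + b + 2) * sqrt(a * b))
}
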