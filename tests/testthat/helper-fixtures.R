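# Shared fixtures: all synthetic, generated in code.

default_eos <- surface_eos()
default_const <- physical_constants()

# coarse but physically resolved solver settings for tests that only need
# qualitative/percent-level agreement
quick_config <- function(c_uM, t_end_s = 3000, dt_out_s = 10, ...) {
  simulation_config(c_uM, t_end_s = t_end_s, dt_out_s = dt_out_s,
                    n_cells = 70, h_surface_um = 2, ...)
}

# independent bisection solver for the isodesmic mass balance
# K*c_tot = x/(1-x)^2, used as an oracle for the closed form
bisect_isodesmic_x <- function(y, tol = 1e-13) {
  if (y == 0) return(0)
  f <- function(x) x / (1 - x)^2 - y
  lo <- 0; hi <- 1 - 1e-15
  while (hi - lo > tol * hi) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}
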