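#' Isodesmic association parameters
#'
#' In the isodesmic model a single equilibrium constant K governs the
#' addition of a monomer to a cluster of any size, producing a geometric
#' cluster size distribution.
#'
#' @param K_um3 Equilibrium constant in um^3 (number-density standard
#'   state); `K_um3 = 0` means no association. A clustering propensity of
#'   3 per uM corresponds to about 5e-3 um^3.
#' @param n_max Hard cap on the cluster size considered when truncating the
#'   distribution. Default 1e4.
#' @return An object of class `isodesmic_params`.
#' @export
isodesmic_params <- function(K_um3 = 5e-3, n_max = 1e4) {
  stopifnot(K_um3 >= 0, n_max >= 1)
  structure(list(K_um3 = K_um3, n_max = as.integer(n_max)),
            class = "isodesmic_params")
}

#' Free monomer concentration of the isodesmic equilibrium
#'
#' Mass balance of the geometric distribution c_n = c1 (K c1)^(n-1) gives
#' K c_tot = x / (1 - x)^2 with x = K c1. The closed-form root
#' x = ((2y + 1) - sqrt(4y + 1)) / (2y), y = K c_tot, is evaluated in its
#' conjugate form x = 2y / ((2y + 1) + sqrt(4y + 1)), which is free of
#' cancellation at small y.
#'
#' @param c_total_um3 Total monomer number density, molecules/um^3.
#' @param params An [isodesmic_params()].
#' @return The free monomer number density c1 in molecules/um^3.
#' @export
solve_monomer_density <- function(c_total_um3, params = isodesmic_params()) {
  if (any(c_total_um3 < 0)) stop("total concentration must be non-negative")
  K <- params$K_um3
  if (K == 0) return(c_total_um3)
  y <- K * c_total_um3
  x <- 2 * y / ((2 * y + 1) + sqrt(4 * y + 1))
  x / K
}

#' Isodesmic cluster size distribution
#'
#' Truncated geometric distribution c_n = c1 x^(n-1), x = K c1, with the
#' truncation n_max chosen so that at least 99.9% of the monomer mass is
#' retained. The distribution is an equilibrium snapshot; cluster
#' interconversion is assumed frozen on the experimental timescale.
#'
#' @inheritParams solve_monomer_density
#' @return An object of class `isodesmic_distribution`: a list with `n`
#'   (sizes 1..n_max), `c_n` (number densities, um^-3), `c1`,
#'   `c_total_um3`, `x` and `mass_fraction_retained`.
#' @export
isodesmic_distribution <- function(c_total_um3, params = isodesmic_params()) {
  stopifnot(length(c_total_um3) == 1L)
  if (c_total_um3 < 0) stop("total concentration must be non-negative")
  c1 <- solve_monomer_density(c_total_um3, params)
  x <- params$K_um3 * c1
  if (c_total_um3 == 0 || x == 0) {
    n_max <- 1L
  } else {
    # retained mass fraction of sizes 1..N is 1 - x^N (N(1-x) + 1)
    tail_frac <- function(N) x^N * (N * (1 - x) + 1)
    n_max <- 1L
    while (tail_frac(n_max) > 1e-3 && n_max < params$n_max) {
      n_max <- min(2L * n_max, params$n_max)
    }
    if (tail_frac(n_max) > 1e-3) {
      stop(sprintf(
        "cannot retain 99.9%% of mass within n_max = %d (x = %.6f, tail = %.3g)",
        params$n_max, x, tail_frac(n_max)))
    }
    # shrink back to the smallest adequate truncation
    while (n_max > 1L && tail_frac(n_max - 1L) <= 1e-3) n_max <- n_max - 1L
  }
  n <- seq_len(n_max)
  c_n <- c1 * x^(n - 1)
  structure(
    list(n = n, c_n = c_n, c1 = c1, x = x, c_total_um3 = c_total_um3,
         mass_fraction_retained = if (c_total_um3 > 0)
           sum(n * c_n) / c_total_um3 else 1),
    class = "isodesmic_distribution"
  )
}

#' @export
print.isodesmic_distribution <- function(x, ...) {
  cat(sprintf(
    "Isodesmic cluster distribution: c_tot = %.4g/um^3, c1 = %.4g/um^3, x = %.4f, n_max = %d\n",
    x$c_total_um3, x$c1, x$x, max(x$n)))
  invisible(x)
}

#' Weight-average aggregation number
#'
#' For the untruncated isodesmic distribution the number-average
#' aggregation number is 1/(1 - x); this computes it from a truncated
#' distribution.
#'
#' @param dist An [isodesmic_distribution()].
#' @return The number-average cluster size (monomers per cluster).
#' @export
mean_aggregation_number <- function(dist) {
  stopifnot(inherits(dist, "isodesmic_distribution"))
  sum(dist$n * dist$c_n) / sum(dist$c_n)
}
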