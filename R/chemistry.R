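# Near-road NO-NO2-O3 chemistry: two reactions,
#   NO + O3 -> NO2        (rate k1, ppb-1 s-1)
#   NO2 + hv -> NO + O3   (photolysis rate j, s-1)
# relaxed toward photostationary state over the time of flight from road
# sources. Both reactions conserve NOx = NO + NO2 and Ox = O3 + NO2, so
# the system reduces to a single ODE in O3 and conservation holds by
# construction.

BOLTZMANN <- 1.380649e-23  # J K-1

#' Chemical state of one air parcel
#'
#' @param no,no2,o3 mixing ratios, ppb (vectorised; recycled to a common
#'   length)
#' @return object of class `chem_state` with derived `nox` and `ox`
#' @export
chem_state <- function(no, no2, o3) {
  n <- max(length(no), length(no2), length(o3))
  no <- rep_len(no, n); no2 <- rep_len(no2, n); o3 <- rep_len(o3, n)
  if (any(no < -1e-12 | no2 < -1e-12 | o3 < -1e-12)) {
    stop("mixing ratios must be non-negative")
  }
  structure(list(no = pmax(no, 0), no2 = pmax(no2, 0), o3 = pmax(o3, 0),
                 nox = pmax(no, 0) + pmax(no2, 0),
                 ox = pmax(o3, 0) + pmax(no2, 0)),
            class = "chem_state")
}

#' Rate coefficient for NO + O3 -> NO2
#'
#' Arrhenius expression `3.0e-12 * exp(-1500 / T)` cm3 molec-1 s-1,
#' converted to mixing-ratio units (ppb-1 s-1) at the given temperature
#' and pressure via the ideal-gas number density.
#'
#' @param temp temperature, K
#' @param pressure pressure, Pa
#' @return k1 in ppb-1 s-1
#' @export
rate_k1 <- function(temp, pressure = 101325) {
  stopifnot(all(temp > 0), all(pressure > 0))
  k_cm3 <- 3.0e-12 * exp(-1500 / temp)            # cm3 molec-1 s-1
  n_air <- pressure / (BOLTZMANN * temp) * 1e-6    # molec cm-3
  k_cm3 * n_air * 1e-9                             # ppb-1 s-1
}

#' NO2 photolysis rate from solar zenith angle
#'
#' Clear-sky power-of-cosine parameterisation
#' `j = j_max * cos(zenith)^e * cloud_factor` for zenith below 90 degrees,
#' zero otherwise. An hourly j series may be supplied directly to the
#' pipeline instead of this parameterisation.
#'
#' @param solar_zenith solar zenith angle, degrees (0 = overhead)
#' @param cloud_factor transmission factor in [0, 1]
#' @param j_max clear-sky overhead maximum, s-1
#' @param e cosine exponent
#' @return photolysis rate, s-1
#' @export
photolysis_j <- function(solar_zenith, cloud_factor = 1,
                         j_max = 8e-3, e = 0.8) {
  stopifnot(all(solar_zenith >= 0), all(solar_zenith <= 180),
            all(cloud_factor >= 0), all(cloud_factor <= 1))
  ifelse(solar_zenith < 90,
         j_max * cos(solar_zenith * pi / 180)^e * cloud_factor, 0)
}

#' Reaction rate parameters
#' @param k1 NO + O3 rate, ppb-1 s-1
#' @param j NO2 photolysis rate, s-1
#' @param temp temperature, K (metadata)
#' @return object of class `rate_params`
#' @export
rate_params <- function(k1, j, temp = 293.15) {
  stopifnot(k1 >= 0, j >= 0)
  structure(list(k1 = k1, j = j, temp = temp), class = "rate_params")
}

#' Photostationary partition of NOx and Ox
#'
#' Solves the steady state `j * no2 = k1 * no * o3` under the constraints
#' `no2 = ox - o3`, `no = nox - ox + o3`, i.e. the physical root of
#' `k1 * o3^2 + (k1 * (nox - ox) + j) * o3 - j * ox = 0` in
#' `[max(0, ox - nox), ox]`.
#'
#' @param nox total NOx, ppb (vectorised)
#' @param ox total Ox, ppb (vectorised)
#' @param rates a [rate_params()]
#' @return a [chem_state()]
#' @export
photostationary_partition <- function(nox, ox, rates) {
  stopifnot(all(nox >= 0), all(ox >= 0))
  n <- max(length(nox), length(ox))
  nox <- rep_len(nox, n); ox <- rep_len(ox, n)
  k1 <- rates$k1; j <- rates$j
  lo <- pmax(0, ox - nox)
  if (k1 == 0) {
    o3 <- if (j > 0) ox else lo     # no titration: all Ox beyond NO2 is O3
    o3 <- rep_len(o3, n)
  } else {
    b <- k1 * (nox - ox) + j
    disc <- b^2 + 4 * k1 * j * ox
    o3 <- (-b + sqrt(disc)) / (2 * k1)
  }
  o3 <- pmin(pmax(o3, lo), ox)
  if (any(!is.finite(o3))) stop("no physical photostationary root found")
  chem_state(no = nox - (ox - o3), no2 = ox - o3, o3 = o3)
}

# dO3/dt with NOx, Ox held fixed
d_o3_dt <- function(o3, nox, ox, k1, j) {
  j * (ox - o3) - k1 * (nox - ox + o3) * o3
}

#' Advance the chemistry over a time interval
#'
#' Integrates the single prognostic variable O3 with classical fourth-order
#' Runge-Kutta on adaptive substeps (capped at one tenth of the fastest
#' relaxation time), then recovers NO2 and NO from the conserved NOx and
#' Ox totals, which are therefore conserved to machine precision. All
#' inputs are vectorised; per-element horizons `t` are allowed.
#'
#' @param state a [chem_state()]
#' @param rates a [rate_params()]
#' @param t integration horizon, s (scalar or per element, >= 0)
#' @return a [chem_state()]
#' @export
advance_chemistry <- function(state, rates, t) {
  stopifnot(inherits(state, "chem_state"))
  if (any(t < 0)) stop("integration horizon t must be non-negative")
  n <- length(state$o3)
  t <- rep_len(t, n)
  nox <- state$nox; ox <- state$ox
  k1 <- rates$k1; j <- rates$j
  if (all(t == 0) || (k1 == 0 && j == 0)) {
    return(chem_state(state$no, state$no2, state$o3))
  }
  # fastest linearised rate; substep = 1/20 of its timescale keeps the
  # classical RK4 truncation error well below 1e-6 ppb
  rate_scale <- j + k1 * pmax(nox, ox)
  dt_max <- 0.05 / pmax(rate_scale, 1e-12)
  nsteps <- pmax(ceiling(t / dt_max), 1)
  nmax <- max(nsteps)
  h <- t / nsteps
  o3 <- state$o3
  lo <- pmax(0, ox - nox)
  for (s in seq_len(nmax)) {
    act <- s <= nsteps
    hh <- ifelse(act, h, 0)
    k_1 <- d_o3_dt(o3, nox, ox, k1, j)
    k_2 <- d_o3_dt(o3 + hh / 2 * k_1, nox, ox, k1, j)
    k_3 <- d_o3_dt(o3 + hh / 2 * k_2, nox, ox, k1, j)
    k_4 <- d_o3_dt(o3 + hh * k_3, nox, ox, k1, j)
    o3 <- o3 + hh / 6 * (k_1 + 2 * k_2 + 2 * k_3 + k_4)
    o3 <- pmin(pmax(o3, lo), ox)   # tolerance guard at physical bounds
  }
  chem_state(no = nox - (ox - o3), no2 = ox - o3, o3 = o3)
}

#' Apply the chemistry over a gridded pre-chemistry state
#'
#' Advances every cell independently over its own time of flight. Cells
#' with zero road increment (time of flight 0) pass through unchanged.
#'
#' @param combined list from [combine_fields()] (matrices `no`, `no2`,
#'   `o3`, `nox`, `ox`, ppb)
#' @param tof matrix of per-cell time of flight, s
#' @param rates a [rate_params()]
#' @return list of matrices `no`, `no2`, `o3` (ppb)
#' @export
apply_chemistry_field <- function(combined, tof, rates) {
  dims <- dim(combined$no)
  if (!identical(dims, dim(tof))) stop("grid mismatch between field and tof")
  st <- chem_state(as.vector(combined$no), as.vector(combined$no2),
                   as.vector(combined$o3))
  out <- advance_chemistry(st, rates, as.vector(tof))
  list(no = matrix(out$no, dims[1], dims[2]),
       no2 = matrix(out$no2, dims[1], dims[2]),
       o3 = matrix(out$o3, dims[1], dims[2]))
}
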