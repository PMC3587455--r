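# Shared helpers: canned met hours and a small fixture scenario.

met_hour <- function(u10 = 5, wdir = 270, temp = 288, shf = 10,
                     pblh = 800, when = "2006-01-02 12:00:00") {
  data.frame(timestamp = as.POSIXct(when, tz = "UTC"),
             u10 = u10, wdir = wdir, temp = temp, shf = shf, pblh = pblh)
}

# neutral conditions (Pasquill class D), wind from the west
met_neutral <- function() met_hour(u10 = 5, wdir = 270, shf = 10)

# truncate a background-field list to its first n hours
lapply_background_head <- function(bg, n) {
  bg$hours <- bg$hours[seq_len(n)]
  for (sp in c("no", "no2", "o3")) {
    bg[[sp]] <- bg[[sp]][, , seq_len(n), drop = FALSE]
  }
  bg
}

# Richardson-extrapolated forward-Euler integration of the O3 relaxation:
# two Euler passes at h and h/2, extrapolated to O(h^2). Independent of the
# package's RK4 path; used as the integrator oracle.
euler_o3_oracle <- function(no, no2, o3, k1, j, t_end, h = 5e-4) {
  nox <- no + no2; ox <- o3 + no2
  run_euler <- function(step) {
    nst <- pmax(ceiling(t_end / step), 1L)
    dt <- t_end / nst
    y <- o3
    for (s in seq_len(max(nst))) {
      hh <- ifelse(s <= nst, dt, 0)
      y <- y + hh * (j * (ox - y) - k1 * (nox - ox + y) * y)
    }
    y
  }
  2 * run_euler(h / 2) - run_euler(h)
}

random_sources <- function(n, extent = c(100, 700), seed = 42,
                           categories = ROAD_CATEGORIES) {
  set.seed(seed)
  if (n == 0) {
    return(data.frame(link_id = character(0), x = numeric(0), y = numeric(0),
                      bearing = numeric(0), length = numeric(0),
                      category = character(0), no_rate = numeric(0),
                      no2_rate = numeric(0), stringsAsFactors = FALSE))
  }
  data.frame(link_id = "t",
             x = runif(n, extent[1], extent[2]),
             y = runif(n, extent[1], extent[2]),
             bearing = runif(n, 0, 180),
             length = runif(n, 4, 10),
             category = sample(categories, n, replace = TRUE),
             no_rate = runif(n, 0.1, 1),
             no2_rate = runif(n, 0.02, 0.2),
             stringsAsFactors = FALSE)
}
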