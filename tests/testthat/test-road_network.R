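test_that("segment_link partitions arc length into 10 m sections", {
  straight <- function(len) {
    road_link("a", rbind(c(0, 0), c(0, len)), nox_rate = 1, f_no2 = 0.2)
  }
  s100 <- segment_link(straight(100))
  expect_equal(nrow(s100), 10)
  expect_equal(s100$length, rep(10, 10))
  expect_equal(s100$y, seq(5, 95, by = 10))
  expect_equal(s100$bearing, rep(0, 10))

  # 95 m: nine full sections plus a 5 m remainder kept as its own source
  s95 <- segment_link(straight(95))
  expect_equal(s95$length, c(rep(10, 9), 5))
  expect_equal(sum(s95$length), 95)

  # closed square ring, perimeter 160 m
  ring <- road_link("r", rbind(c(0, 0), c(40, 0), c(40, 40), c(0, 40), c(0, 0)),
                    nox_rate = 1, f_no2 = 0.2)
  sring <- segment_link(ring)
  expect_equal(nrow(sring), 16)
  expect_equal(sring$length, rep(10, 16))
})

test_that("source lengths sum to the polyline arc length for random polylines", {
  set.seed(7)
  for (i in 1:20) {
    nv <- sample(2:6, 1)
    xy <- matrix(cumsum(runif(2 * nv, 5, 60)), ncol = 2)
    link <- road_link("p", xy, nox_rate = 0.5, f_no2 = 0.2)
    src <- segment_link(link)
    expect_equal(sum(src$length), link_length(link), tolerance = 1e-6)
    expect_true(all(src$length <= 10 + 1e-9))
    expect_true(all(src$bearing >= 0 & src$bearing < 180))
  }
})

test_that("degenerate geometry is rejected", {
  expect_error(road_link("z", rbind(c(0, 0), c(0, 0)), 1, 0.2),
               "distinct")
  expect_error(road_link("z", matrix(c(0, 0), 1, 2), 1, 0.2), "2")
  expect_error(road_link("z", rbind(c(0, 0), c(0, 1)), -1, 0.2), "nox_rate")
  expect_error(road_link("z", rbind(c(0, 0), c(0, 1)), 1, 1.2), "f_no2")
})

test_that("canyon classification picks the nearest axis, mod 180", {
  expect_equal(classify_category(10, TRUE), "canyon_NS")
  expect_equal(classify_category(90, TRUE), "canyon_EW")
  expect_equal(classify_category(140, TRUE), "canyon_SENW")
  expect_equal(classify_category(50, TRUE), "canyon_SWNE")
  expect_equal(classify_category(170, TRUE), "canyon_NS")   # wraps past 180
  # ties midway between axes break to the lower axis angle
  expect_equal(classify_category(22.5, TRUE), "canyon_NS")
  expect_equal(classify_category(67.5, TRUE), "canyon_SWNE")
  # out-of-range bearings are normalised, never rejected
  expect_equal(classify_category(190, TRUE), "canyon_NS")
  expect_equal(classify_category(-45, TRUE), "canyon_SENW")
})

test_that("classification is invariant under bearing + 180", {
  set.seed(11)
  b <- runif(50, 0, 180)
  expect_equal(classify_category(b, TRUE), classify_category(b + 180, TRUE))
})

test_that("non-canyon roads are typed by link metadata", {
  expect_equal(classify_category(33, FALSE, typical = TRUE), "typical")
  expect_equal(classify_category(33, FALSE, typical = FALSE), "open")
})

test_that("NOx split conserves NO2-equivalent mass", {
  # primary NO2 fraction 0.20 (a kerbside inventory value)
  r <- split_nox_emission(1.0, 0.20)
  expect_equal(r$no2_rate, 0.20)
  expect_equal(r$no_rate, 0.80 * 30.006 / 46.0055, tolerance = 1e-6)
  expect_equal(unlist(split_nox_emission(1, 0)),
               c(no_rate = 30.006 / 46.0055, no2_rate = 0), tolerance = 1e-6)
  expect_equal(unlist(split_nox_emission(1, 1)),
               c(no_rate = 0, no2_rate = 1))
  # conservation: no2 + no * (46/30) = nox for random inputs
  set.seed(3)
  nox <- runif(100, 0, 5); f <- runif(100)
  s <- split_nox_emission(nox, f)
  expect_equal(s$no2_rate + s$no_rate * 46.0055 / 30.006, nox,
               tolerance = 1e-12)
  expect_error(split_nox_emission(-1, 0.2), "non-negative")
})

test_that("temporal profiles validate and scale emissions", {
  expect_error(temporal_profile(hour_of_week = rep(2, 168)), "average")
  expect_error(temporal_profile(month = rep(0.5, 12)), "average")
  flat <- temporal_profile()
  ts <- as.POSIXct("2006-06-15 08:00:00", tz = "UTC")
  expect_equal(emission_at_hour(2.5, flat, ts), 2.5)

  hw <- rep(1, 168); hw[1] <- 1.5; hw <- hw / mean(hw)
  mo <- rep(1, 12); mo[6] <- 0.8; mo <- mo / mean(mo)
  p <- temporal_profile(hw, mo)
  monday_jan <- as.POSIXct("2007-01-01 00:00:00", tz = "UTC")  # a Monday
  expect_equal(emission_at_hour(1, p, monday_jan), hw[1] * mo[1])

  # exhaustive mean over all 168 x 12 combinations preserves the base rate
  set.seed(5)
  hw2 <- runif(168, 0.2, 2); hw2 <- hw2 / mean(hw2)
  mo2 <- runif(12, 0.5, 1.5); mo2 <- mo2 / mean(mo2)
  p2 <- temporal_profile(hw2, mo2)
  all_combos <- outer(hw2, mo2)
  expect_equal(mean(all_combos), 1, tolerance = 1e-12)
})

test_that("build_sources expands links with categories and split rates", {
  links <- list(
    road_link("a", rbind(c(0, 0), c(0, 100)), nox_rate = 1, f_no2 = 0.2,
              canyon = TRUE),
    road_link("b", rbind(c(0, 0), c(100, 0)), nox_rate = 0.5, f_no2 = 0.16,
              canyon = FALSE, typical = FALSE))
  src <- build_sources(links)
  expect_equal(nrow(src), 20)
  expect_true(all(src$category[src$link_id == "a"] == "canyon_NS"))
  expect_true(all(src$category[src$link_id == "b"] == "open"))
  expect_equal(unique(src$no2_rate[src$link_id == "a"]), 0.2)
})

test_that("roads survive a GeoJSON round trip", {
  links <- list(road_link("a", rbind(c(10.5, 20), c(30, 44.25)),
                          nox_rate = 0.7, f_no2 = 0.22, canyon = TRUE,
                          canyon_width = 28, canyon_height = 22))
  path <- tempfile(fileext = ".geojson")
  write_roads_geojson(links, path)
  back <- read_roads_geojson(path)
  expect_equal(back[[1]]$xy, links[[1]]$xy)
  expect_equal(back[[1]]$nox_rate, 0.7)
  expect_equal(back[[1]]$f_no2, 0.22)
  expect_true(back[[1]]$canyon)
  expect_equal(back[[1]]$canyon_width, 28)
  unlink(path)
})

test_that("WKT CSV roads parse", {
  path <- tempfile(fileext = ".csv")
  writeLines(c("id,wkt,nox_rate,f_no2,canyon",
               "r1,\"LINESTRING (0 0, 50 50, 100 50)\",0.4,0.18,TRUE"), path)
  links <- read_roads_csv(path)
  expect_equal(links[[1]]$xy, rbind(c(0, 0), c(50, 50), c(100, 50)))
  expect_equal(links[[1]]$f_no2, 0.18)
  expect_true(links[[1]]$canyon)
  unlink(path)
})
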