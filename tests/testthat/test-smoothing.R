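test_that("splines reproduce polynomial data exactly", {
  # linear data: the interpolating cubic of a line is that line
  d <- make_series(list(a = function(t) 2 * t + 1), times = 0:4)
  sf <- fit_splines(d)
  tt <- seq(0, 4, length.out = 41)
  expect_equal(eval_spline(sf, tt)$value, 2 * tt + 1, tolerance = 1e-12)
  expect_equal(eval_derivative(sf, c(0.3, 2.5, 3.9))$deriv, rep(2, 3),
               tolerance = 1e-12)
  # midpoint of an interval lies on the line
  expect_equal(eval_spline(sf, 1.5)$value, 4, tolerance = 1e-12)

  # with 4 points the not-a-knot spline is the unique interpolating cubic
  d3 <- make_series(list(a = function(t) t^3), times = c(0, 1, 2, 3))
  sf3 <- fit_splines(d3)
  tt <- seq(0, 3, length.out = 31)
  expect_equal(eval_spline(sf3, tt)$value, tt^3, tolerance = 1e-10)
  expect_equal(eval_derivative(sf3, 2)$deriv, 12, tolerance = 1e-10)
})

test_that("not-a-knot spline matches a brute-force linear-system oracle", {
  x <- seq(0, pi, length.out = 8)
  d <- make_series(list(s = sin), times = x)
  sf <- fit_splines(d)
  oracle <- brute_force_nak(x, sin(x))
  tt <- seq(0, pi, length.out = 100)
  expect_lt(max(abs(eval_spline(sf, tt)$value - oracle(tt))), 1e-10)
  expect_lt(max(abs(eval_derivative(sf, tt)$deriv - oracle(tt, deriv = 1))),
            1e-10)
  # closed forms: sin(pi/2) = 1 within 1e-3 at 8 knots; derivative tracks cos
  expect_equal(eval_spline(sf, pi / 2)$value, 1, tolerance = 1e-3)
  interior <- seq(0.1, pi - 0.1, length.out = 50)
  err8 <- max(abs(eval_derivative(sf, interior)$deriv - cos(interior)))
  expect_lt(err8, 1e-2)
  # derivative error shrinks as knots increase
  x16 <- seq(0, pi, length.out = 16)
  sf16 <- fit_splines(make_series(list(s = sin), times = x16))
  err16 <- max(abs(eval_derivative(sf16, interior)$deriv - cos(interior)))
  expect_lt(err16, err8 / 2)
})

test_that("splines interpolate the data at every knot", {
  bench <- recovery_benchmark()$bench
  sf <- recovery_benchmark()$splines
  for (sid in unique(bench$data$series)[1:5]) {
    sub <- bench$data[bench$data$series == sid, ]
    at_knots <- eval_spline(sf, sort(unique(sub$time)), series = sid)
    merged <- dplyr::inner_join(sub, at_knots, by = c("gene", "series", "time"),
                                suffix = c("", "_spline"))
    expect_lt(max(abs(merged$value - merged$value_spline)), 1e-9)
  }
})

test_that("analytic spline derivative agrees with central differences", {
  x <- seq(0, 2, length.out = 9)
  d <- make_series(list(a = function(t) exp(-t) + t^2), times = x)
  sf <- fit_splines(d)
  interior <- c(0.4, 0.9, 1.3, 1.7)
  exact <- eval_derivative(sf, interior)$deriv
  for (h in c(1e-4, 1e-5)) {
    fd <- (eval_spline(sf, interior + h)$value -
             eval_spline(sf, interior - h)$value) / (2 * h)
    expect_equal(fd, exact, tolerance = 1e-5)
  }
  # the smaller h must be at least as close (convergence)
  fd4 <- (eval_spline(sf, interior + 1e-4)$value -
            eval_spline(sf, interior - 1e-4)$value) / 2e-4
  fd5 <- (eval_spline(sf, interior + 1e-5)$value -
            eval_spline(sf, interior - 1e-5)$value) / 2e-5
  expect_lte(max(abs(fd5 - exact)), max(abs(fd4 - exact)) + 1e-12)
})

test_that("third derivative is continuous at the second and penultimate knots", {
  x <- seq(0, 3, length.out = 7)
  withr::with_seed(3, {
    y <- cumsum(rnorm(7))
  })
  y <- y - min(y) + 0.1
  d <- tibble::tibble(gene = "a", series = "s1", time = x, value = y)
  sf <- fit_splines(d)
  sfit <- sf$fits[["s1"]]
  third <- function(iv) 6 * sfit$coefs[iv, 4, "a"]  # constant per interval
  rel <- function(a, b) abs(a - b) / max(abs(a), abs(b), 1e-12)
  expect_lt(rel(third(1), third(2)), 1e-6)
  expect_lt(rel(third(5), third(6)), 1e-6)
})

test_that("degenerate inputs are rejected with informative errors", {
  too_few <- tibble::tibble(gene = "a", series = "short", time = 0:2,
                            value = c(1, 2, 3))
  expect_error(fit_splines(too_few), "short")
  bad_times <- tibble::tibble(gene = "a", series = "s1",
                              time = c(0, 1, 1, 2, 3), value = 1:5)
  expect_error(fit_splines(bad_times), "non-increasing")
  d <- make_series(list(a = function(t) t), times = 0:4)
  sf <- fit_splines(d)
  expect_error(eval_spline(sf, 4.5), "extrapolation")
  expect_error(eval_derivative(sf, -0.5), "extrapolation")
})

test_that("presmooth is a centered moving average with edge replication", {
  d <- make_series(list(a = function(t) t^2), times = 0:5)
  expect_equal(presmooth(d, window = 1), check_expression(d))
  const <- make_series(list(a = function(t) rep(5, length(t))), times = 0:5)
  expect_equal(presmooth(const, window = 3)$value, rep(5, 6))
  # oracle: directly coded edge-replicating convolution of [0,3,0,3,0]
  v <- c(0, 3, 0, 3, 0)
  padded <- c(v[1], v, v[5])
  oracle <- vapply(1:5, function(i) mean(padded[i:(i + 2)]), numeric(1))
  d2 <- tibble::tibble(gene = "a", series = "s1", time = 0:4, value = v)
  expect_equal(presmooth(d2, window = 3)$value, oracle)
  expect_equal(oracle, c(1, 1, 2, 1, 1))
  expect_error(presmooth(d, window = 2), "odd")
  expect_error(presmooth(d, window = 0), "odd")
})
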