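test_that("B spans the curve and matches a root-finding oracle", {
  d <- device_params(g_min = 100, g_max = 170.3, p_max = 100, a_p = 30, a_d = 30)
  B <- b_coeff(d, 30)
  # independent route: solve the span condition G_LTP(p_max) = g_max for B
  root <- uniroot(function(b) b * (1 - exp(-100 / 30)) + 100 - 170.3,
                  interval = c(1, 1e4), tol = 1e-12)$root
  expect_equal(B, root, tolerance = 1e-9)

  # linear limit: B -> a/p_max * (g_max - g_min)
  d2 <- device_params(g_min = 0.001, g_max = 1.001, p_max = 100, a_p = 1e6, a_d = 1e6)
  expect_equal(b_coeff(d2, 1e6), 1e6 / 100 * 1, tolerance = 1e-4)

  # negative a: B < 0 but the span still holds
  dn <- device_params(a_p = -30, a_d = -30)
  expect_lt(b_coeff(dn, -30), 0)
  expect_equal(g_ltp(dn, dn$p_max), dn$g_max, tolerance = 1e-12)
  expect_error(b_coeff(d, 0), "nonzero")
})

test_that("LTP/LTD boundary identities hold at machine precision", {
  for (a in c(5, 30, 300, -30, -5)) {
    d <- device_params(g_min = 100, g_max = 170.3, p_max = 100, a_p = a, a_d = a)
    expect_equal(g_ltp(d, 0), d$g_min)
    expect_equal(g_ltp(d, d$p_max), d$g_max)
    expect_equal(g_ltd(d, 0), d$g_max)
    expect_equal(g_ltd(d, d$p_max), d$g_min)
  }
  expect_error(g_ltp(device_params(), -1), "outside")
  expect_error(g_ltd(device_params(), 101), "outside")
})

test_that("LTP is strictly increasing and LTD strictly decreasing", {
  # strong curvature at p_max = 100; milder curvature exhaustively to 1000
  # (beyond ~30 decay constants the per-pulse change underflows double precision)
  cases <- list(c(5, 100), c(30, 100), c(-40, 100), c(100, 1000), c(1000, 1000))
  for (cs in cases) {
    d <- device_params(g_min = 100, g_max = 170.3, p_max = cs[2],
                       a_p = cs[1], a_d = cs[1])
    p <- 0:cs[2]
    expect_true(all(diff(g_ltp(d, p)) > 0))
    expect_true(all(diff(g_ltd(d, p)) < 0))
  }
})

test_that("near-linear limit converges to the straight line between endpoints", {
  d <- device_params(g_min = 0.001, g_max = 1.001, p_max = 100, a_p = 1e6, a_d = 1e6)
  p <- 0:100
  line <- d$g_min + (d$g_max - d$g_min) * p / d$p_max
  expect_lt(max(abs(g_ltp(d, p) - line)), 1e-3 * (d$g_max - d$g_min))
  expect_lt(max(abs(g_ltd(d, p) - rev(line))), 1e-3 * (d$g_max - d$g_min))
})

test_that("mirrored-curve identity: with a_d = a_p, LTD is the exact LTP mirror", {
  d <- device_params(g_min = 100, g_max = 170.3, p_max = 100, a_p = 30, a_d = 30)
  # exhaustive tabulation over all integer pulse counts
  for (p in 0:100)
    expect_equal(g_ltd(d, p), d$g_min + d$g_max - g_ltp(d, p), tolerance = 1e-12)
})

test_that("simulated LTP/D cycle is seed-reproducible and noiseless-exact", {
  d <- tiny_device(30, 30)
  tr0 <- simulate_ltpd_cycle(d, pulse_protocol(), noise_sd = 0)
  expect_equal(nrow(tr0), 200L)
  pot <- tr0[tr0$phase == "potentiation", ]
  dep <- tr0[tr0$phase == "depression", ]
  expect_equal(pot$conductance_uS, g_ltp(d, 1:100))
  expect_equal(dep$conductance_uS, g_ltd(d, 1:100))

  t1 <- simulate_ltpd_cycle(d, noise_sd = 0.5, seed = 42)
  t2 <- simulate_ltpd_cycle(d, noise_sd = 0.5, seed = 42)
  t3 <- simulate_ltpd_cycle(d, noise_sd = 0.5, seed = 43)
  expect_identical(t1, t2)
  expect_false(identical(t1, t3))
  expect_lt(max(abs(t1$conductance_uS - tr0$conductance_uS)), 3 * 0.5 + 1e-9)
  expect_error(simulate_ltpd_cycle(d, noise_sd = -1), "noise_sd")
})

test_that("nonlinearity fit recovers generating constants", {
  d <- tiny_device(30, -40)
  tr <- simulate_ltpd_cycle(d, noise_sd = 0)
  f <- fit_nonlinearity(tr)
  expect_equal(f$a_p, 30, tolerance = 0.01)
  expect_equal(f$a_d, -40, tolerance = 0.01)
  expect_equal(f$g_min, min(tr$conductance_uS))
  expect_equal(f$g_max, max(tr$conductance_uS))

  # near-linear trace: fitted |a| large, residuals tiny
  dl <- device_params(g_min = 100, g_max = 170.3, p_max = 100, a_p = 1e6, a_d = 1e6)
  fl <- fit_nonlinearity(simulate_ltpd_cycle(dl, noise_sd = 0))
  expect_gte(abs(fl$a_p), 1e3)
  span <- dl$g_max - dl$g_min
  expect_lt(sqrt(max(attr(fl, "rss")) / 100), 1e-3 * span)
})

test_that("fit recovery under 1% noise: median relative error < 10% over 50 seeds", {
  d <- tiny_device(30, -40)
  span <- d$g_max - d$g_min
  err <- vapply(1:50, function(s) {
    f <- suppressWarnings(
      fit_nonlinearity(simulate_ltpd_cycle(d, noise_sd = 0.01 * span, seed = s)))
    max(abs(f$a_p - 30) / 30, abs(f$a_d - (-40)) / 40)
  }, 0)
  expect_lt(median(err), 0.10)
})

test_that("EPSC relaxation and PPF follow the exponential model", {
  expect_equal(epsc_relaxation(10, 5, tau = 700, t = 0), 15)
  expect_equal(epsc_relaxation(10, 5, tau = 700, t = 1e9), 10, tolerance = 1e-9)
  expect_equal(epsc_relaxation(10, 5, tau = 3, t = 3), 10 + 5 / exp(1))
  expect_error(epsc_relaxation(10, 5, tau = 0), "tau")

  expect_equal(ppf_index(10, 10), 100)
  expect_equal(ppf_index(10, 12), 120)
  expect_error(ppf_index(0, 1), "a1")

  # second pulse arriving before relaxation rides on the residual: facilitation
  tau <- 700; dt <- 100; dg <- 5
  a1 <- dg
  a2 <- (epsc_relaxation(0, dg, tau, dt) + dg) - 0
  expect_gt(ppf_index(a1, a2), 100)
})
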