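Tp <- 60 * 86400

test_that("double gyre respects its closed forms", {
  expect_equal(max(abs(make_double_gyre(0, 0.1, Tp, nt = 3)$u)), 0)
  expect_equal(max(abs(make_double_gyre(0, 0.1, Tp, nt = 3)$v)), 0)

  # steady gyre (epsilon = 0): velocity vanishes at both gyre centers
  gy <- make_double_gyre(1e5, 0, Tp, domain = c(0, 2e6, 0, 1e6),
                         nx = 161, ny = 81, nt = 3)
  for (cx in c(5e5, 1.5e6)) {
    uv <- sample_field(gy, cx, 5e5, Tp / 3)
    expect_lt(max(abs(uv)), 1e-12)
  }
})

test_that("stream-function fields are discretely divergence-free", {
  gy <- make_double_gyre(8e4, 0.1, Tp, nx = 81, ny = 41,
                         t_range = c(0, Tp), nt = 21)
  vmax <- max(sqrt(gy$u^2 + gy$v^2))
  dv <- discrete_divergence(gy, k = 7)
  idx <- withr::with_seed(11, cbind(sample(nrow(dv), 100, TRUE),
                                    sample(ncol(dv), 100, TRUE)))
  expect_lt(max(abs(dv[idx])), 1e-6 * vmax)
})

test_that("uniform wind evaluates its closed form", {
  w <- make_uniform_wind(c(0, 0), 1, Tp, c(1, 0), nx = 3, ny = 3,
                         t_range = c(0, Tp), nt = 5)
  v <- sample_field(w, c(1e5, 1.9e6), c(2e5, 8e5), Tp / 4)
  expect_equal(unname(v[, 1]), c(1, 1))
  expect_equal(unname(v[, 2]), c(0, 0))
  w0 <- make_uniform_wind(c(0, 0), 0)
  expect_equal(max(abs(w0$u)) + max(abs(w0$v)), 0)
  wc <- make_uniform_wind(c(-4, 2), 0)
  expect_equal(as.numeric(sample_field(wc, 3e5, 3e5, 0.5)), c(-4, 2))
})

test_that("interpolation is exact on nodes and has linear precision", {
  gy <- make_double_gyre(8e4, 0.1, Tp, nx = 21, ny = 11,
                         t_range = c(0, Tp), nt = 7)
  for (idx in list(c(4, 5, 2), c(21, 11, 7), c(1, 1, 1))) {
    v <- sample_field(gy, gy$x[idx[1]], gy$y[idx[2]], gy$t[idx[3]])
    expect_identical(as.numeric(v[1, 1]), gy$u[idx[1], idx[2], idx[3]])
    expect_identical(as.numeric(v[1, 2]), gy$v[idx[1], idx[2], idx[3]])
  }
  # field linear in (x, y, t) is reproduced exactly at interior points
  g <- list(x = seq(0, 1e6, length.out = 6), y = seq(0, 5e5, length.out = 6),
            t = seq(0, 100, length.out = 4))
  lin <- function(x, y, t) 1e-7 * x + 2e-7 * y - 3e-4 * t + 0.05
  arr <- array(0, c(6, 6, 4))
  for (i in 1:6) for (j in 1:6) for (k in 1:4)
    arr[i, j, k] <- lin(g$x[i], g$y[j], g$t[k])
  fld <- flow_field(g$x, g$y, g$t, arr, -arr, "ocean")
  pts <- withr::with_seed(5, cbind(runif(50, 0, 1e6), runif(50, 0, 5e5),
                                   runif(50, 0, 100)))
  got <- sample_field(fld, pts[, 1], pts[, 2], pts[, 3])
  expect_equal(unname(got[, 1]), lin(pts[, 1], pts[, 2], pts[, 3]),
               tolerance = 1e-12)
  # midpoint of two nodes along x equals the nodal average
  mid <- sample_field(fld, (g$x[2] + g$x[3]) / 2, g$y[2], g$t[2])
  expect_equal(as.numeric(mid[1, 1]), (arr[2, 2, 2] + arr[3, 2, 2]) / 2,
               tolerance = 1e-14)
})

test_that("out-of-bounds queries raise instead of clamping", {
  gy <- make_double_gyre(8e4, 0.1, Tp, nt = 3)
  expect_error(sample_field(gy, -1, 5e5, Tp / 2), "outside")
  expect_error(sample_field(gy, 1e6, 5e5, 2 * Tp), "outside")
  expect_error(field_derivatives(gy, gy, 1e4, 5e5, Tp / 2), "interior")
})

test_that("field derivatives match analytic references", {
  flds <- uniform_fields(0.3, -0.1)
  d <- field_derivatives(flds$ocean, flds$ocean, 1e6, 5e5, 5e6)
  expect_equal(max(abs(d$grad_v)), 0)
  expect_equal(d$vorticity, 0)
  expect_equal(max(abs(d$material_v)), 0)

  # solid-body rotation: vorticity = 2 * Omega
  Om <- 1e-6
  g <- list(x = seq(-1e5, 1e5, length.out = 41),
            y = seq(-1e5, 1e5, length.out = 41),
            t = c(0, 5e5, 1e6))
  u <- array(0, c(41, 41, 3)); v <- array(0, c(41, 41, 3))
  for (i in 1:41) for (j in 1:41) {
    u[i, j, ] <- -Om * g$y[j]
    v[i, j, ] <- Om * g$x[i]
  }
  rot <- flow_field(g$x, g$y, g$t, u, v, "ocean")
  d <- field_derivatives(rot, rot, 2e4, -3e4, 5e5)
  expect_equal(d$vorticity, 2 * Om, tolerance = 1e-12)

  # double gyre: finite differences approach the analytic psi-derivatives
  # at second order (halving the grid shrinks the error by >= 3.5x)
  ana_grad <- function(x, y, t, A, eps, Tp, dom) {
    Lx <- dom[2] - dom[1]; Ly <- dom[4] - dom[3]
    X <- 2 * (x - dom[1]) / Lx; Y <- (y - dom[3]) / Ly
    s <- sin(2 * pi * t / Tp); a <- eps * s; b <- 1 - 2 * eps * s
    f <- a * X^2 + b * X; fX <- 2 * a * X + b
    # du/dx and dv/dy of u = -(pi A/Ly) sin(pi f) cos(pi Y)
    dudx <- -(pi * A / Ly) * pi * cos(pi * f) * fX * (2 / Lx) * cos(pi * Y)
    dudy <- (pi * A / Ly) * sin(pi * f) * pi * sin(pi * Y) / Ly
    c(dudx = dudx, dudy = dudy)
  }
  A <- 8e4; dom <- c(0, 2e6, 0, 1e6)
  pt <- c(6.1e5, 4.2e5, 2.3e6)
  err <- sapply(c(41, 81), function(nx) {
    gy <- make_double_gyre(A, 0.1, Tp, dom, nx = nx, ny = (nx - 1) / 2 + 1,
                           t_range = c(0, 3e6), nt = nx)
    d <- field_derivatives(gy, gy, pt[1], pt[2], pt[3])
    ref <- ana_grad(pt[1], pt[2], pt[3], A, 0.1, Tp, dom)
    max(abs(c(d$grad_v[1, 1, 1] - ref["dudx"], d$grad_v[1, 1, 2] - ref["dudy"])))
  })
  expect_gt(err[1] / err[2], 3.5)
})

test_that("flow fields round-trip through the text serialization", {
  gy <- make_double_gyre(8e4, 0.1, Tp, nx = 9, ny = 5, t_range = c(0, Tp),
                         nt = 4)
  f <- file.path(tempdir(), "gy.csv")
  write_flow_field(gy, f)
  back <- read_flow_field(f)
  expect_equal(back$u, gy$u, tolerance = 0)
  expect_equal(back$v, gy$v, tolerance = 0)
  expect_identical(back$kind, "ocean")
  # second write is byte-identical
  f2 <- file.path(tempdir(), "gy2.csv")
  write_flow_field(back, f2)
  expect_identical(readLines(f), readLines(f2))
})

test_that("analytic fields agree with their gridded counterparts on nodes", {
  gy <- make_double_gyre(8e4, 0.1, Tp, nx = 21, ny = 11,
                         t_range = c(0, Tp), nt = 7)
  an <- analytic_double_gyre(8e4, 0.1, Tp)
  got <- sample_analytic(an, gy$x[7], gy$y[4], gy$t[3])
  expect_equal(as.numeric(got[1, 1]), gy$u[7, 4, 3], tolerance = 1e-14)
  expect_equal(as.numeric(got[1, 2]), gy$v[7, 4, 3], tolerance = 1e-14)
})

test_that("grid validation rejects malformed axes", {
  expect_error(flow_field(c(0, 1, 1.5), c(0, 1), c(0, 1),
                          array(0, c(3, 2, 2)), array(0, c(3, 2, 2))),
               "uniformly spaced")
  expect_error(flow_field(c(1, 0), c(0, 1), c(0, 1),
                          array(0, c(2, 2, 2)), array(0, c(2, 2, 2))),
               "strictly increasing")
  expect_error(flow_field(c(0, 1), c(0, 1), c(0, 1),
                          array(NA_real_, c(2, 2, 2)), array(0, c(2, 2, 2))),
               "finite")
})
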