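Tp <- 60 * 86400

test_that("carrying field mixes ocean and wind by the windage fraction", {
  expect_equal(carrying_field(c(1, 2), c(9, 9), 0), c(1, 2))
  expect_equal(carrying_field(c(1, 2), c(9, 9), 1 - 1e-15), c(9, 9),
               tolerance = 1e-12)
  # the optimized windage of about 0.34%
  expect_equal(carrying_field(c(1, 0), c(0, 10), 0.0034), c(0.9966, 0.034))
})

test_that("inertial correction implements its formula", {
  # uniform equal ocean/wind, R = 1: all terms cancel
  derivs0 <- list(vorticity = 0,
                  material_v = matrix(0, 1, 2), material_u = matrix(0, 1, 2))
  p1 <- clump_params(alpha = 0.3, R = 1, tau = 10, f0 = 1e-4, beta = 0)
  expect_equal(inertial_correction(derivs0, c(2, 1), c(2, 1), p1, 0),
               matrix(0, 1, 2))
  # uniform flow, beta = 0: residual Coriolis term (R - 1) f0 v_perp
  p2 <- clump_params(alpha = 0, R = 0.25, tau = 10, f0 = 1e-4, beta = 0)
  got <- inertial_correction(derivs0, c(2, 1), c(2, 1), p2, 7e5)
  expect_equal(got, (0.25 - 1) * 1e-4 * matrix(c(-1, 2), 1, 2))
  # synthetic derivatives: term-by-term match of an independent evaluation
  dr <- list(vorticity = 3e-6,
             material_v = matrix(c(1e-6, -2e-6), 1, 2),
             material_u = matrix(c(5e-7, 4e-7), 1, 2))
  v <- c(0.2, -0.1); u <- c(0.15, -0.05); y <- 2e5
  p <- clump_params(alpha = 0.1, R = 0.6, tau = 100, f0 = 5e-5, beta = 2e-11)
  f <- 5e-5 + 2e-11 * y
  expected <- 0.6 * dr$material_v +
    0.6 * (f + 3e-6 / 3) * matrix(c(-v[2], v[1]), 1, 2) -
    dr$material_u -
    (f + 0.6 * 3e-6 / 3) * matrix(c(-u[2], u[1]), 1, 2)
  expect_equal(inertial_correction(dr, v, u, p, y), expected, tolerance = 1e-14)
})

test_that("stiffness follows the logistic switch-off", {
  sp <- spring_params(ell = 5e3, kappa0 = 1e-8, d = 500)
  expect_equal(stiffness(2 * 5e3, sp), 1e-8 / 2)
  expect_lt(stiffness(2 * 5e3 + 20 * 500, sp), 1e-8 * 3e-9)
  sp2 <- spring_params(ell = 5e3, kappa0 = 1e-8, d = 500)
  expect_equal(stiffness(0, sp2), 1e-8 / (exp(-20) + 1), tolerance = 1e-8)
})

test_that("spring forces are restorative, pairwise balanced, and cut off", {
  sp <- spring_params(ell = 5e3, kappa0 = 1e-8, d = 500)
  # rest length: no force
  F <- spring_force(rbind(c(0, 0), c(5e3, 0)), matrix(c(1, 2), 1), sp)
  expect_equal(max(abs(F)), 0)
  # separation 2*ell along x: |F| = kappa0 * ell / 2 toward the partner
  F <- spring_force(rbind(c(0, 0), c(1e4, 0)), matrix(c(1, 2), 1), sp)
  expect_equal(F[1, ], c(1e-8 * 5e3 / 2, 0))
  expect_equal(F[2, ], -F[1, ])
  # random raft: total force is zero to 1e-12 relative
  pos <- withr::with_seed(3, matrix(runif(40, 0, 3e4), 20, 2))
  edges <- which(upper.tri(matrix(0, 20, 20)), arr.ind = TRUE)
  F <- spring_force(pos, edges, sp)
  expect_lt(max(abs(colSums(F))), 1e-12 * max(abs(F)))
  # beyond the cutoff: exactly zero
  F <- spring_force(rbind(c(0, 0), c(sp$cutoff_radius + 1, 0)),
                    matrix(c(1, 2), 1), sp)
  expect_equal(max(abs(F)), 0)
  # coincident clumps: zero with a warning
  expect_warning(
    F <- spring_force(rbind(c(1, 1), c(1, 1)), matrix(c(1, 2), 1), sp),
    "coincident")
  expect_equal(max(abs(F)), 0)
})

test_that("clump velocity law has the right limits", {
  flds <- uniform_fields(0.3, 0, 0, 0)
  # tau = 0: passive tracer of the carrying field
  p0 <- clump_params(alpha = 0.25, R = 0.9, tau = 0, f0 = 1e-4, beta = 1e-11)
  v <- clump_velocity(c(1e6, 5e5), 6e6, flds$ocean, flds$wind, p0)
  expect_equal(unname(v[1, ]), c(0.75 * 0.3, 0))
  # uniform v = w, beta = 0: xdot = (U, tau (R-1) f0 U)
  fl2 <- uniform_fields(0.3, 0, 0.3, 0)
  p1 <- clump_params(alpha = 0.4, R = 0.5, tau = 1800, f0 = 5e-5, beta = 0)
  v <- clump_velocity(c(1e6, 5e5), 6e6, fl2$ocean, fl2$wind, p1)
  expect_equal(unname(v[1, ]), c(0.3, 1800 * (0.5 - 1) * 5e-5 * 0.3),
               tolerance = 1e-12)
})

test_that("compiled integrator reproduces the R reference velocity law", {
  gy <- make_double_gyre(8e4, 0.1, Tp, nx = 81, ny = 41,
                         t_range = c(-1e6, 1.3e7), nt = 81)
  wd <- make_uniform_wind(c(-4, 0), 2, Tp, c(0, 1), nx = 81, ny = 41,
                          t_range = c(-1e6, 1.3e7), nt = 81)
  pp <- clump_params(alpha = 0.01, R = 0.5, tau = 1800, f0 = 5e-5, beta = 2e-11)
  sp <- spring_params(5e3, 1e-8, 500)
  st <- make_raft(c(1.3e6, 6e5), 3, 3, 5e3)
  h <- 4628.571428571428
  rk4_step <- function(pos, t) {
    f <- function(q, tt) clump_velocity(q, tt, gy, wd, pp, sp, edges = st$edges)
    k1 <- f(pos, t); k2 <- f(pos + h / 2 * k1, t + h / 2)
    k3 <- f(pos + h / 2 * k2, t + h / 2); k4 <- f(pos + h * k3, t + h)
    pos + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  ref <- rk4_step(st$positions, 0)
  got <- integrate_raft(st, gy, wd, pp, sp, 0, h, h, h)$positions[, 2, ]
  expect_lt(max(abs(ref - got)), 1e-10)
})

test_that("integration limits: straight lines, equilibrium, determinism", {
  flds <- uniform_fields(0.3, 0)
  st <- raft_state(matrix(c(2e5, 5e5), 1))
  p0 <- clump_params()
  tr <- integrate_raft(st, flds$ocean, flds$wind, p0, NULL, 0, 864000,
                       8640, 86400)
  expect_lt(max(abs(tr$positions[1, , 1] - (2e5 + 0.3 * tr$times))), 1e-10)
  expect_lt(max(abs(tr$positions[1, , 2] - 5e5)), 1e-10)

  # two linked clumps at rest length in quiescent flow stay put
  fl0 <- uniform_fields(0, 0)
  sp <- spring_params(5e3, 1e-8, 500)
  st2 <- raft_state(rbind(c(1e6, 5e5), c(1e6 + 5e3, 5e5)), matrix(c(1, 2), 1))
  tr2 <- integrate_raft(st2, fl0$ocean, fl0$wind,
                        clump_params(tau = 1800), sp,
                        0, 100 * 8640, 8640, 10 * 8640)
  expect_lt(max(abs(tr2$positions[, 11, ] - st2$positions)), 1e-12)

  # bit-identical reruns
  gy <- analytic_double_gyre(8e4, 0.1, Tp)
  wd <- analytic_uniform_wind(c(-4, 0), 2, Tp, c(0, 1))
  pp <- clump_params(0.01, 0.5, 1800, 5e-5, 2e-11)
  st3 <- make_raft(c(1.3e6, 6e5), 4, 4, 5e3)
  a <- integrate_raft(st3, gy, wd, pp, sp, 0, 20 * 8640, 8640, 2 * 8640)
  b <- integrate_raft(st3, gy, wd, pp, sp, 0, 20 * 8640, 8640, 2 * 8640)
  expect_identical(a, b)
})

test_that("RK4 self-convergence on the double gyre is at least order 3.5", {
  gy <- analytic_double_gyre(8e4, 0.1, Tp)
  wd <- analytic_uniform_wind(c(-4, 0), 2, Tp, c(0, 1))
  pp <- clump_params(0.01, 0.5, 1800, 5e-5, 2e-11)
  st <- raft_state(rbind(c(1.3e6, 6e5), c(6e5, 4e5), c(1.1e6, 5e5)))
  t_end <- 864000
  pos_at <- function(n) integrate_raft(st, gy, wd, pp, NULL, 0, t_end,
                                       t_end / n, t_end)$positions[, 2, ]
  ref <- pos_at(112)                       # quarter-step reference
  err_h <- max(abs(pos_at(28) - ref))
  err_h2 <- max(abs(pos_at(56) - ref))
  expect_gt(err_h / err_h2, 2^3.5)
})

test_that("passive-tracer limit is approached linearly in tau", {
  gy <- analytic_double_gyre(8e4, 0.1, Tp)
  wd <- analytic_uniform_wind(c(-4, 0), 2, Tp, c(0, 1))
  st <- raft_state(rbind(c(1.3e6, 6e5), c(9e5, 4e5)))
  t_end <- 864000
  base <- integrate_raft(st, gy, wd, clump_params(0.01, 0.5, 0, 5e-5, 2e-11),
                         NULL, 0, t_end, t_end / 100, t_end)$positions[, 2, ]
  errs <- sapply(Tp * c(1e-2, 1e-3, 1e-4), function(tau) {
    p <- clump_params(0.01, 0.5, tau, 5e-5, 2e-11)
    max(abs(integrate_raft(st, gy, wd, p, NULL, 0, t_end, t_end / 100,
                           t_end)$positions[, 2, ] - base))
  })
  ratios <- errs[-3] / errs[-1]
  expect_true(all(ratios > 5 & ratios < 20))   # ~10x per decade of tau
})

test_that("links break permanently and the link set is non-increasing", {
  # two clumps sheared apart in a linear shear flow
  g <- list(x = seq(0, 1e6, length.out = 21), y = seq(0, 1e6, length.out = 21),
            t = c(0, 1e7))
  u <- array(0, c(21, 21, 2))
  for (j in 1:21) u[, j, ] <- 1e-5 * (g$y[j] - 5e5)   # shear du/dy
  sh <- flow_field(g$x, g$y, g$t, u, array(0, c(21, 21, 2)), "ocean")
  wd <- uniform_fields(0, 0)$wind
  sp <- spring_params(5e3, 1e-10, 500)
  st <- raft_state(rbind(c(5e5, 4.9e5), c(5e5, 5.1e5)), matrix(c(1, 2), 1))
  tr <- integrate_raft(st, sh, wd, clump_params(tau = 10), sp,
                       0, 40 * 8640, 8640, 4 * 8640)
  expect_false(tr$edge_active[1])
  sep <- sqrt(sum((tr$positions[1, 11, ] - tr$positions[2, 11, ])^2))
  expect_gt(sep, sp$cutoff_radius)
})

test_that("clumps beach on land cells and freeze", {
  # uniform westward flow into a meridional wall with a strait
  flds <- uniform_fields(-0.5, 0)
  oc <- flds$ocean                         # 5 x 5 grid, cells of 5e5 x 2.5e5
  mask <- matrix(FALSE, 4, 4)
  mask[3, c(1, 2, 4)] <- TRUE              # wall in x cell 3, gap in y cell 3
  st <- raft_state(rbind(c(1.6e6, 1e5), c(1.6e6, 6.4e5), c(1.6e6, 9e5)))
  tr <- integrate_raft(st, oc, flds$wind, clump_params(), NULL,
                       0, 100 * 8640, 8640, 10 * 8640, land_mask = mask)
  K <- dim(tr$positions)[2]
  expect_equal(unname(tr$status[, K]), c(1L, 0L, 1L))   # gap clump sails on
  for (m in c(1, 3)) {
    k0 <- min(which(tr$status[m, ] == 1L))
    expect_equal(tr$positions[m, K, ], tr$positions[m, k0, ])
    expect_gte(tr$positions[m, K, 1], 1.4e6)  # frozen at the wall face
    expect_lte(tr$positions[m, K, 1], 1.55e6)
  }
  expect_lt(tr$positions[2, K, 1], 1.25e6)   # the strait clump passed through
})

test_that("trajectory CSV serialization records every clump and time", {
  flds <- uniform_fields(0.1, 0)
  st <- make_raft(c(1e6, 5e5), 2, 2, 5e3)
  sp <- spring_params(5e3, 1e-8, 500)
  tr <- integrate_raft(st, flds$ocean, flds$wind, clump_params(), sp,
                       0, 4 * 8640, 8640, 8640)
  f <- file.path(tempdir(), "traj.csv")
  write_trajectories(tr, f)
  df <- read.csv(f)
  expect_equal(nrow(df), 4 * 5)
  expect_equal(sort(unique(df$k)), 0:4)
  prov <- yaml::read_yaml(paste0(f, ".yaml"))
  expect_equal(prov$clumps, 4)
})
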