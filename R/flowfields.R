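#' Gridded time-dependent velocity field
#'
#' A `flow_field` holds one 2-D vector field (near-surface ocean current
#' or 10-m wind) sampled on a regular space--time grid on the planar
#' beta-plane: coordinates in meters (x east, y north), time in seconds
#' since the scenario epoch, components in m/s.
#'
#' @param x,y,t strictly increasing, uniformly spaced coordinate vectors
#'   (meters, meters, seconds).
#' @param u,v component arrays of dimension `c(length(x), length(y),
#'   length(t))`; `u` is the eastward and `v` the northward component.
#' @param kind `"ocean"` or `"wind"`.
#' @return An object of class `flow_field`.
#' @export
flow_field <- function(x, y, t, u, v, kind = c("ocean", "wind")) {
  kind <- match.arg(kind)
  check_axis(x, "x"); check_axis(y, "y"); check_axis(t, "t")
  dm <- c(length(x), length(y), length(t))
  if (!identical(dim(u), as.integer(dm)) || !identical(dim(v), as.integer(dm)))
    stop("component arrays must have dimension (nx, ny, nt)")
  if (!all(is.finite(u)) || !all(is.finite(v)))
    stop("field components must be finite everywhere")
  structure(list(x = as.numeric(x), y = as.numeric(y), t = as.numeric(t),
                 u = u, v = v, kind = kind),
            class = "flow_field")
}

check_axis <- function(a, name) {
  if (length(a) < 2L || any(diff(a) <= 0))
    stop("invalid grid: coordinate '", name, "' must be strictly increasing")
  h <- diff(a)
  if (max(h) - min(h) > 1e-9 * max(abs(h)))
    stop("invalid grid: coordinate '", name, "' must be uniformly spaced")
  invisible(a)
}

#' @export
print.flow_field <- function(x, ...) {
  cat(sprintf("<flow_field:%s> %d x %d x %d grid\n", x$kind,
              length(x$x), length(x$y), length(x$t)))
  cat(sprintf("  x: [%g, %g] m   y: [%g, %g] m   t: [%g, %g] s\n",
              min(x$x), max(x$x), min(x$y), max(x$y), min(x$t), max(x$t)))
  cat(sprintf("  max speed %.4g m/s\n", max(sqrt(x$u^2 + x$v^2))))
  invisible(x)
}

grid_axes <- function(domain, nx, ny, t_range, nt) {
  list(x = seq(domain[1], domain[2], length.out = nx),
       y = seq(domain[3], domain[4], length.out = ny),
       t = seq(t_range[1], t_range[2], length.out = nt))
}

# analytic double-gyre velocity; x is rescaled to [0, 2], y to [0, 1]
double_gyre_uv <- function(x, y, t, amplitude, epsilon, period, domain) {
  Lx <- domain[2] - domain[1]
  Ly <- domain[4] - domain[3]
  X <- 2 * (x - domain[1]) / Lx
  Y <- (y - domain[3]) / Ly
  s <- sin(2 * pi * t / period)
  a <- epsilon * s
  b <- 1 - 2 * epsilon * s
  f <- a * X^2 + b * X
  dfdX <- 2 * a * X + b
  u <- -(pi * amplitude / Ly) * sin(pi * f) * cos(pi * Y)
  v <- (2 * pi * amplitude / Lx) * cos(pi * f) * dfdX * sin(pi * Y)
  list(u = u, v = v)
}

#' Periodically perturbed double-gyre ocean field
#'
#' Samples the classical time-periodic double-gyre stream function
#' \deqn{\psi(x, y, t) = A \sin(\pi f(X, t)) \sin(\pi Y),\quad
#'       f(X, t) = a(t) X^2 + b(t) X,}
#' with \eqn{a(t) = \epsilon \sin(2\pi t/T)}, \eqn{b(t) = 1 -
#' 2\epsilon\sin(2\pi t/T)}, \eqn{X \in [0, 2]}, \eqn{Y \in [0, 1]}
#' rescaled from the physical rectangle, onto a regular grid.  The
#' velocity is \eqn{(-\partial_y\psi, \partial_x\psi)}, hence
#' divergence-free: a closed basin of two counter-rotating gyres whose
#' separatrix flaps with amplitude `epsilon`.  This is the synthetic
#' stand-in for reanalysis surface currents.
#'
#' @param amplitude stream-function amplitude \eqn{A} (m^2/s); the peak
#'   speed is about \eqn{\pi A / L_y}.
#' @param epsilon perturbation strength, `0 <= epsilon < 1`; `0` gives
#'   the steady double gyre.
#' @param period perturbation period \eqn{T} (s).
#' @param domain rectangle `c(xmin, xmax, ymin, ymax)` in meters.
#' @param nx,ny,nt grid sizes; `t_range` the sampled time window (s).
#' @param t_range length-2 numeric time window.
#' @return A `flow_field` with `kind = "ocean"`.
#' @export
make_double_gyre <- function(amplitude, epsilon = 0.1, period,
                             domain = c(0, 2e6, 0, 1e6),
                             nx = 81, ny = 41,
                             t_range = c(0, period), nt = 41) {
  if (amplitude < 0) stop("amplitude must be >= 0")
  if (epsilon < 0 || epsilon >= 1) stop("epsilon must be in [0, 1)")
  if (period <= 0) stop("period must be > 0")
  g <- grid_axes(domain, nx, ny, t_range, nt)
  gr <- expand.grid(x = g$x, y = g$y, t = g$t)
  uv <- double_gyre_uv(gr$x, gr$y, gr$t, amplitude, epsilon, period, domain)
  flow_field(g$x, g$y, g$t,
             array(uv$u, c(nx, ny, nt)), array(uv$v, c(nx, ny, nt)),
             kind = "ocean")
}

#' Spatially uniform, optionally oscillating wind field
#'
#' Builds \eqn{w(t) = w_0 + A_w \sin(2\pi t/T)\,\hat w} sampled on a
#' regular grid, spatially uniform so that windage effects on clump
#' trajectories remain analytically checkable.
#'
#' @param w0 mean wind vector `c(wx, wy)` (m/s).
#' @param oscillation_amplitude amplitude \eqn{A_w} (m/s) of the
#'   sinusoidal component along `direction`.
#' @param period oscillation period (s); required when
#'   `oscillation_amplitude != 0`.
#' @param direction unit direction \eqn{\hat w} of the oscillation
#'   (normalized internally).
#' @inheritParams make_double_gyre
#' @return A `flow_field` with `kind = "wind"`.
#' @export
make_uniform_wind <- function(w0 = c(0, 0), oscillation_amplitude = 0,
                              period = NULL, direction = c(1, 0),
                              domain = c(0, 2e6, 0, 1e6),
                              nx = 2, ny = 2, t_range = c(0, 1), nt = 2) {
  if (oscillation_amplitude != 0 && (is.null(period) || period <= 0))
    stop("period must be > 0 when oscillation_amplitude != 0")
  nrm <- sqrt(sum(direction^2))
  dir <- if (nrm > 0) direction / nrm else c(1, 0)
  g <- grid_axes(domain, nx, ny, t_range, nt)
  osc <- if (oscillation_amplitude != 0)
    oscillation_amplitude * sin(2 * pi * g$t / period) else rep(0, nt)
  u <- outer(array(1, c(nx, ny)), w0[1] + osc * dir[1])
  v <- outer(array(1, c(nx, ny)), w0[2] + osc * dir[2])
  flow_field(g$x, g$y, g$t, array(u, c(nx, ny, nt)), array(v, c(nx, ny, nt)),
             kind = "wind")
}

#' Sample a flow field at arbitrary points
#'
#' Bilinear interpolation in space and linear interpolation in time;
#' nodal values are reproduced exactly and fields linear in (x, y, t)
#' are reproduced to rounding.  Queries outside the grid's space--time
#' bounding box raise an error rather than being clamped: domain exits
#' are the Markov chain's business (the nirvana state), not the
#' interpolator's.
#'
#' @param field a [flow_field()].
#' @param x,y,t query coordinates (vectors of equal length, or scalars
#'   recycled).
#' @return A two-column matrix of (u, v) at each query point (m/s).
#' @export
sample_field <- function(field, x, y, t) {
  n <- max(length(x), length(y), length(t))
  x <- rep_len(x, n); y <- rep_len(y, n); t <- rep_len(t, n)
  for (ax in list(list(x, field$x, "x"), list(y, field$y, "y"),
                  list(t, field$t, "t"))) {
    bad <- ax[[1]] < min(ax[[2]]) | ax[[1]] > max(ax[[2]])
    if (any(bad))
      stop("query outside the grid along '", ax[[3]], "' (no extrapolation): ",
           paste(utils::head(signif(ax[[1]][bad], 6), 3), collapse = ", "))
  }
  interp3(field, x, y, t)
}

# clamped trilinear kernel shared by sample_field (bounds pre-checked)
interp3 <- function(field, x, y, t) {
  nx <- length(field$x); ny <- length(field$y); nt <- length(field$t)
  dx <- (field$x[nx] - field$x[1]) / (nx - 1)
  dy <- (field$y[ny] - field$y[1]) / (ny - 1)
  dt <- (field$t[nt] - field$t[1]) / (nt - 1)
  fx <- pmin(pmax((x - field$x[1]) / dx, 0), nx - 1)
  fy <- pmin(pmax((y - field$y[1]) / dy, 0), ny - 1)
  ft <- pmin(pmax((t - field$t[1]) / dt, 0), nt - 1)
  i <- pmin(floor(fx), nx - 2); wx <- fx - i
  j <- pmin(floor(fy), ny - 2); wy <- fy - j
  k <- pmin(floor(ft), nt - 2); wt <- ft - k
  u <- numeric(length(x)); v <- numeric(length(x))
  for (dk in 0:1) {
    ck <- if (dk == 1) wt else 1 - wt
    for (dj in 0:1) {
      cj <- if (dj == 1) wy else 1 - wy
      for (di in 0:1) {
        ci <- if (di == 1) wx else 1 - wx
        idx <- (i + di + 1) + nx * (j + dj) + nx * ny * (k + dk)
        w <- ci * cj * ck
        u <- u + w * field$u[idx]
        v <- v + w * field$v[idx]
      }
    }
  }
  cbind(u = u, v = v)
}

#' Field derivatives at a point
#'
#' Evaluates, at interior query points, the spatial gradients and time
#' derivatives of the ocean velocity `v` and of the carrying field `u`,
#' the vertical vorticity \eqn{\omega = \partial_x v_y - \partial_y
#' v_x}, and the material derivatives \eqn{Dv/Dt = \partial_t v +
#' (v\cdot\nabla)v} and \eqn{Du/Dt = \partial_t u + (u\cdot\nabla)u}.
#' All derivatives are central differences of the interpolant with step
#' equal to one grid cell of the respective field, so they converge at
#' second order in the grid spacing for smooth fields.
#'
#' @param field_ocean the ocean [flow_field()] (`v`).
#' @param field_carrying the carrying field `u = (1 - alpha) v + alpha
#'   w` as a `flow_field` (see [carrying_flow_field()]).
#' @param x,y,t query points, at least one grid cell inside the
#'   space--time bounding box of both fields.
#' @return A list with components `v`, `u` (n x 2 sampled values),
#'   `grad_v`, `grad_u` (n x 2 x 2 arrays, `[, a, b]` =
#'   \eqn{\partial_b} of component a), `dt_v`, `dt_u` (n x 2),
#'   `vorticity` (n), `material_v`, `material_u` (n x 2).
#' @export
field_derivatives <- function(field_ocean, field_carrying, x, y, t) {
  n <- max(length(x), length(y), length(t))
  x <- rep_len(x, n); y <- rep_len(y, n); t <- rep_len(t, n)
  dv <- one_field_derivs(field_ocean, x, y, t)
  du <- one_field_derivs(field_carrying, x, y, t)
  vort <- dv$grad[, 2, 1] - dv$grad[, 1, 2]
  mat <- function(d)
    cbind(d$dt[, 1] + d$val[, 1] * d$grad[, 1, 1] + d$val[, 2] * d$grad[, 1, 2],
          d$dt[, 2] + d$val[, 1] * d$grad[, 2, 1] + d$val[, 2] * d$grad[, 2, 2])
  list(v = dv$val, u = du$val,
       grad_v = dv$grad, grad_u = du$grad,
       dt_v = dv$dt, dt_u = du$dt,
       vorticity = as.numeric(vort),
       material_v = mat(dv), material_u = mat(du))
}

one_field_derivs <- function(field, x, y, t) {
  nx <- length(field$x); ny <- length(field$y); nt <- length(field$t)
  hx <- (field$x[nx] - field$x[1]) / (nx - 1)
  hy <- (field$y[ny] - field$y[1]) / (ny - 1)
  ht <- (field$t[nt] - field$t[1]) / (nt - 1)
  if (any(x - hx < field$x[1] | x + hx > field$x[nx] |
          y - hy < field$y[1] | y + hy > field$y[ny] |
          t - ht < field$t[1] | t + ht > field$t[nt]))
    stop("derivative query must be at least one grid cell interior")
  val <- sample_field(field, x, y, t)
  ddx <- (sample_field(field, x + hx, y, t) -
          sample_field(field, x - hx, y, t)) / (2 * hx)
  ddy <- (sample_field(field, x, y + hy, t) -
          sample_field(field, x, y - hy, t)) / (2 * hy)
  ddt <- (sample_field(field, x, y, t + ht) -
          sample_field(field, x, y, t - ht)) / (2 * ht)
  grad <- array(0, c(length(x), 2, 2))
  grad[, 1, 1] <- ddx[, 1]; grad[, 1, 2] <- ddy[, 1]
  grad[, 2, 1] <- ddx[, 2]; grad[, 2, 2] <- ddy[, 2]
  list(val = val, grad = grad, dt = ddt)
}

#' Combine ocean and wind into the carrying flow field
#'
#' Forms `u = (1 - alpha) v + alpha w` node-by-node.  Both fields must
#' share the same grid.
#'
#' @param ocean,wind `flow_field`s on identical grids.
#' @param alpha dimensionless windage in `[0, 1)`.
#' @return A `flow_field` (tagged `"ocean"`) holding the carrying field.
#' @export
carrying_flow_field <- function(ocean, wind, alpha) {
  if (!isTRUE(all.equal(ocean$x, wind$x)) ||
      !isTRUE(all.equal(ocean$y, wind$y)) ||
      !isTRUE(all.equal(ocean$t, wind$t)))
    stop("ocean and wind grids must match to form the carrying field")
  flow_field(ocean$x, ocean$y, ocean$t,
             (1 - alpha) * ocean$u + alpha * wind$u,
             (1 - alpha) * ocean$v + alpha * wind$v,
             kind = "ocean")
}

# ---- plain-text serialization -------------------------------------------
# CF-style naming (dimensions time/y/x; variables uo/vo for ocean and
# u10/v10 for wind; units "m s-1"; kindtag attribute) in a CSV + YAML
# header pair, so fields survive text-only round trips.

#' Write / read a flow field as CSV + YAML header
#'
#' `write_flow_field()` writes `file` (CSV: columns `time_index`,
#' `y_index`, `x_index` and the two component variables, named `uo`/`vo`
#' for ocean and `u10`/`v10` for wind) plus `<file>.yaml` describing the
#' uniform axes, units (`"m s-1"`) and the `kindtag` attribute.  Values
#' are printed with 17 significant digits so the round trip is exact.
#'
#' @param field a [flow_field()].
#' @param file CSV path; the header is written next to it.
#' @return `write_flow_field()` returns `file` invisibly;
#'   `read_flow_field()` returns the reconstructed `flow_field`.
#' @export
write_flow_field <- function(field, file) {
  nm <- if (field$kind == "ocean") c("uo", "vo") else c("u10", "v10")
  hdr <- list(
    kindtag = field$kind,
    dims = list(
      time = list(n = length(field$t), start = field$t[1],
                  step = if (length(field$t) > 1) diff(field$t)[1] else 0),
      y = list(n = length(field$y), start = field$y[1], step = diff(field$y)[1]),
      x = list(n = length(field$x), start = field$x[1], step = diff(field$x)[1])),
    variables = list(u = nm[1], v = nm[2]),
    units = "m s-1")
  yaml::write_yaml(hdr, paste0(file, ".yaml"))
  idx <- expand.grid(x_index = seq_along(field$x),
                     y_index = seq_along(field$y),
                     time_index = seq_along(field$t))
  df <- data.frame(time_index = idx$time_index, y_index = idx$y_index,
                   x_index = idx$x_index,
                   u = sprintf("%.17g", as.numeric(field$u)),
                   v = sprintf("%.17g", as.numeric(field$v)))
  names(df)[4:5] <- nm
  utils::write.csv(df, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @rdname write_flow_field
#' @export
read_flow_field <- function(file) {
  hdr <- yaml::read_yaml(paste0(file, ".yaml"))
  df <- utils::read.csv(file)
  ax <- function(d) d$start + d$step * (seq_len(d$n) - 1)
  x <- ax(hdr$dims$x); y <- ax(hdr$dims$y)
  t <- if (hdr$dims$time$n > 1) ax(hdr$dims$time) else hdr$dims$time$start
  dm <- c(hdr$dims$x$n, hdr$dims$y$n, hdr$dims$time$n)
  ord <- order(df$time_index, df$y_index, df$x_index)
  flow_field(x, y, t,
             array(df[[hdr$variables$u]][ord], dm),
             array(df[[hdr$variables$v]][ord], dm),
             kind = hdr$kindtag)
}

#' Analytic forcing fields
#'
#' Closed-form counterparts of [make_double_gyre()] and
#' [make_uniform_wind()]: instead of sampling onto a grid, these carry
#' the formula itself, which the integrator evaluates exactly at every
#' stage point.  With gridded forcing the bilinear interpolant is only
#' piecewise smooth and its kinks dominate the time-stepping error; the
#' analytic fields are infinitely smooth, so they expose the
#' integrator's nominal fourth-order convergence and give a
#' kink-free reference for accuracy studies.
#'
#' @inheritParams make_double_gyre
#' @return An object of class `analytic_field`.
#' @export
analytic_double_gyre <- function(amplitude, epsilon = 0.1, period,
                                 domain = c(0, 2e6, 0, 1e6)) {
  if (amplitude < 0) stop("amplitude must be >= 0")
  if (epsilon < 0 || epsilon >= 1) stop("epsilon must be in [0, 1)")
  if (period <= 0) stop("period must be > 0")
  structure(list(type = 1L, amplitude = amplitude, epsilon = epsilon,
                 period = period, domain = domain, kind = "ocean"),
            class = "analytic_field")
}

#' @rdname analytic_double_gyre
#' @inheritParams make_uniform_wind
#' @export
analytic_uniform_wind <- function(w0 = c(0, 0), oscillation_amplitude = 0,
                                  period = NULL, direction = c(1, 0),
                                  domain = c(0, 2e6, 0, 1e6)) {
  if (oscillation_amplitude != 0 && (is.null(period) || period <= 0))
    stop("period must be > 0 when oscillation_amplitude != 0")
  nrm <- sqrt(sum(direction^2))
  structure(list(type = 2L, w0 = w0,
                 oscillation_amplitude = oscillation_amplitude,
                 period = if (is.null(period)) 1 else period,
                 direction = if (nrm > 0) direction / nrm else c(1, 0),
                 domain = domain, kind = "wind"),
            class = "analytic_field")
}

#' @export
print.analytic_field <- function(x, ...) {
  cat(sprintf("<analytic_field:%s> %s\n", x$kind,
              if (x$type == 1L) "double gyre" else "uniform wind"))
  invisible(x)
}

# descriptor handed to the compiled integrator
as_field_descriptor <- function(field) {
  if (inherits(field, "flow_field")) return(c(list(type = 0L), unclass(field)))
  if (inherits(field, "analytic_field")) return(unclass(field))
  stop("expected a flow_field or analytic_field")
}

#' Evaluate an analytic field
#'
#' @param field an [analytic_double_gyre()] or [analytic_uniform_wind()].
#' @param x,y,t query coordinates.
#' @return Two-column matrix of (u, v).
#' @export
sample_analytic <- function(field, x, y, t) {
  n <- max(length(x), length(y), length(t))
  x <- rep_len(x, n); y <- rep_len(y, n); t <- rep_len(t, n)
  if (field$type == 1L) {
    uv <- double_gyre_uv(x, y, t, field$amplitude, field$epsilon,
                         field$period, field$domain)
    return(cbind(u = uv$u, v = uv$v))
  }
  osc <- if (field$oscillation_amplitude != 0)
    field$oscillation_amplitude * sin(2 * pi * t / field$period) else 0
  cbind(u = field$w0[1] + osc * field$direction[1],
        v = field$w0[2] + osc * field$direction[2])
}

#' Discrete divergence of an ocean field at grid nodes
#'
#' Central differences of the nodal values; used to check that stream
#' function derived fields are (numerically) divergence-free.
#'
#' @param field a `flow_field`.
#' @param k time index (1-based).
#' @return Matrix of \eqn{\partial_x u + \partial_y v} at interior nodes.
#' @export
discrete_divergence <- function(field, k = 1L) {
  nx <- length(field$x); ny <- length(field$y)
  hx <- diff(field$x)[1]; hy <- diff(field$y)[1]
  u <- field$u[, , k]; v <- field$v[, , k]
  dudx <- (u[3:nx, 2:(ny - 1)] - u[1:(nx - 2), 2:(ny - 1)]) / (2 * hx)
  dvdy <- (v[2:(nx - 1), 3:ny] - v[2:(nx - 1), 1:(ny - 2)]) / (2 * hy)
  dudx + dvdy
}
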