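#' Inertial clump parameters
#'
#' Physical parameters of the Maxey--Riley clump law on the beta-plane:
#' `alpha` is the dimensionless windage (fraction of the carrying
#' velocity contributed by wind), `R` the dimensionless exposure of the
#' spherical clump to air, `tau` the inertial (Stokes) response time in
#' seconds, and `f = f0 + beta * y` the Coriolis parameter.
#'
#' @param alpha windage, `0 <= alpha < 1`.
#' @param R exposure, in `[0, 1]`.
#' @param tau inertial response time (s), `>= 0`; `tau = 0` recovers a
#'   passive tracer of the carrying field.
#' @param f0 Coriolis parameter at the reference latitude (1/s).
#' @param beta Coriolis gradient (1/(m s)).
#' @return A list of class `clump_params`.
#' @export
clump_params <- function(alpha = 0, R = 0, tau = 0, f0 = 0, beta = 0) {
  if (alpha < 0 || alpha >= 1) stop("alpha must be in [0, 1)")
  if (R < 0 || R > 1) stop("R must be in [0, 1]")
  if (tau < 0) stop("tau must be >= 0")
  structure(list(alpha = alpha, R = R, tau = tau, f0 = f0, beta = beta),
            class = "clump_params")
}

#' Nonlinear spring parameters
#'
#' The link between two clumps at separation `x` exerts a restoring
#' force with stiffness \eqn{\kappa(x) = \kappa_0 / (e^{(x - 2\ell)/d} +
#' 1)}: approximately `kappa0` up to separation `2 * ell` and
#' essentially zero beyond, so clumps fully detach at large stretch.
#' Because the spring force enters the velocity law multiplied by `tau`,
#' the force carries units of m/s^2 and `kappa0` of 1/s^2.
#'
#' @param ell natural spring length (m), `> 0`.
#' @param kappa0 stiffness amplitude (1/s^2).
#' @param d stiffness cutoff scale (m), `> 0`; intended `d << ell`
#'   (warned when `d > ell / 5`).
#' @param cutoff_radius separation beyond which a link is treated as
#'   broken and pruned permanently; the default `2 * ell + 10 * d`
#'   leaves forces continuous to about `5e-5 * kappa0`.
#' @return A list of class `spring_params`.
#' @export
spring_params <- function(ell, kappa0, d, cutoff_radius = 2 * ell + 10 * d) {
  if (ell <= 0) stop("ell must be > 0")
  if (d <= 0) stop("d must be > 0")
  if (d > ell / 5) warning("stiffness cutoff scale d should be << ell (d <= ell/5)")
  structure(list(ell = ell, kappa0 = kappa0, d = d,
                 cutoff_radius = cutoff_radius),
            class = "spring_params")
}

#' Carrying velocity
#'
#' `u = (1 - alpha) v + alpha w`, componentwise.  `v` and `w` may be
#' length-2 vectors or n x 2 matrices of ocean and wind velocities.
#'
#' @param v,w velocities (m/s).
#' @param alpha windage.
#' @return Velocity of the same shape as the inputs.
#' @export
carrying_field <- function(v, w, alpha) {
  (1 - alpha) * v + alpha * w
}

#' Inertial correction velocity
#'
#' The finite-size (Maxey--Riley) correction
#' \deqn{u_\tau = R\,Dv/Dt + R (f + \omega/3) v^\perp - Du/Dt -
#'       (f + R\omega/3) u^\perp,}
#' with \eqn{f = f_0 + \beta y} and \eqn{a^\perp = (-a_y, a_x)}.  The
#' clump velocity law adds `tau * u_tau` to the carrying velocity.
#'
#' @param derivs output of [field_derivatives()] evaluated at the
#'   clump positions.
#' @param v,u ocean and carrying velocities at the same points (n x 2).
#' @param params a [clump_params()].
#' @param y northward coordinate(s) (m) for the beta term.
#' @return n x 2 matrix of correction velocities (m/s^2 times seconds
#'   pending the `tau` factor; the raw `u_tau` has units of m/s^2).
#' @export
inertial_correction <- function(derivs, v, u, params, y) {
  v <- rbind2mat(v); u <- rbind2mat(u)
  f <- params$f0 + params$beta * y
  om <- derivs$vorticity
  perp <- function(a) cbind(-a[, 2], a[, 1])
  params$R * derivs$material_v +
    (params$R * (f + om / 3)) * perp(v) -
    derivs$material_u -
    (f + params$R * om / 3) * perp(u)
}

rbind2mat <- function(a) if (is.matrix(a)) a else matrix(a, ncol = 2)

#' Spring stiffness profile
#'
#' \eqn{\kappa(x) = \kappa_0 / (e^{(x - 2\ell)/d} + 1)}: a logistic
#' switch-off centered at twice the natural length.
#'
#' @param separation clump separation(s) (m), `>= 0`.
#' @param springs a [spring_params()].
#' @return Stiffness value(s) (same units as `kappa0`).
#' @export
stiffness <- function(separation, springs) {
  springs$kappa0 / (exp((separation - 2 * springs$ell) / springs$d) + 1)
}

#' Per-clump spring forces over a raft
#'
#' \deqn{F_m = -\sum_{m' \in \mathrm{neighbor}(m)} \kappa(x_{mm'})
#'       (1 - \ell / x_{mm'})\, \mathbf{x}_{mm'}}
#' with \eqn{\mathbf{x}_{mm'} = \mathbf{x}_m - \mathbf{x}_{m'}}.
#' Pairwise contributions are equal and opposite, so the total force
#' over any raft vanishes.  Links stretched beyond the cutoff radius
#' contribute exactly zero; coincident linked clumps contribute zero
#' with a warning (the unit vector is singular there).
#'
#' @param positions M x 2 matrix of clump positions (m).
#' @param edges two-column integer matrix of links (each pair once).
#' @param springs a [spring_params()].
#' @return M x 2 matrix of forces (m/s^2).
#' @export
spring_force <- function(positions, edges, springs) {
  M <- nrow(positions)
  F <- matrix(0, M, 2)
  if (is.null(edges) || nrow(edges) == 0) return(F)
  a <- edges[, 1]; b <- edges[, 2]
  dx <- positions[a, 1] - positions[b, 1]
  dy <- positions[a, 2] - positions[b, 2]
  r <- sqrt(dx^2 + dy^2)
  if (any(r == 0))
    warning("coincident linked clumps: zero force contribution for those links")
  keep <- r > 0 & r <= springs$cutoff_radius
  if (any(keep)) {
    coef <- -stiffness(r[keep], springs) * (1 - springs$ell / r[keep])
    fx <- coef * dx[keep]; fy <- coef * dy[keep]
    ak <- a[keep]; bk <- b[keep]
    F[, 1] <- F[, 1] + rowsum_into(fx, ak, M) - rowsum_into(fx, bk, M)
    F[, 2] <- F[, 2] + rowsum_into(fy, ak, M) - rowsum_into(fy, bk, M)
  }
  F
}

rowsum_into <- function(vals, idx, n) {
  out <- numeric(n)
  s <- rowsum(vals, idx)
  out[as.integer(rownames(s))] <- s[, 1]
  out
}

#' Clump velocity law (reference implementation)
#'
#' \eqn{\dot x_m = u + \tau u_\tau + \tau F_m} evaluated at the clump
#' positions, with fields interpolated from gridded ocean and wind.
#' This is the R-level reference for the compiled integrator; the two
#' share the interpolation and differencing rules.
#'
#' @param positions M x 2 clump positions.
#' @param t time (s).
#' @param ocean,wind `flow_field`s (identical grids when `tau > 0`).
#' @param params a [clump_params()].
#' @param springs a [spring_params()] (needed when `edges` given).
#' @param edges link matrix, or `NULL` for isolated clumps.
#' @param forces precomputed M x 2 spring forces, overriding `edges`.
#' @return M x 2 matrix of velocities (m/s).
#' @export
clump_velocity <- function(positions, t, ocean, wind, params,
                           springs = NULL, edges = NULL, forces = NULL) {
  positions <- rbind2mat(positions)
  v <- sample_field(ocean, positions[, 1], positions[, 2], t)
  w <- sample_field(wind, positions[, 1], positions[, 2], t)
  u <- carrying_field(v, w, params$alpha)
  vel <- u
  if (params$tau > 0) {
    cf <- carrying_flow_field(ocean, wind, params$alpha)
    derivs <- field_derivatives(ocean, cf, positions[, 1], positions[, 2], t)
    vel <- vel + params$tau *
      inertial_correction(derivs, v, u, params, positions[, 2])
  }
  if (is.null(forces)) {
    forces <- if (!is.null(edges)) spring_force(positions, edges, springs)
              else matrix(0, nrow(positions), 2)
  }
  vel + params$tau * forces
}

#' Seed a raft on a regular lattice
#'
#' Places `nrow x ncol` clumps on a square or hexagonal lattice of pitch
#' `ell` centered at `center`, and links every pair within `1.5 * ell`
#' (nearest neighbors, plus diagonals on the hexagonal lattice).
#'
#' @param center length-2 center (m).
#' @param nrow,ncol lattice extent.
#' @param ell lattice pitch = natural spring length (m).
#' @param lattice `"hex"` or `"square"`.
#' @return A list of class `raft_state` with `positions` (M x 2) and
#'   `edges` (two-column matrix, each link once, `e[,1] < e[,2]`).
#' @export
make_raft <- function(center, nrow = 5, ncol = 5, ell,
                      lattice = c("hex", "square")) {
  lattice <- match.arg(lattice)
  ix <- rep(seq_len(ncol), times = nrow)
  iy <- rep(seq_len(nrow), each = ncol)
  px <- (ix - (ncol + 1) / 2) * ell
  py <- (iy - (nrow + 1) / 2) * ell
  if (lattice == "hex") {
    px <- px + ifelse(iy %% 2 == 0, ell / 2, 0)
    py <- py * sqrt(3) / 2
  }
  pos <- cbind(center[1] + px, center[2] + py)
  raft_state(pos, lattice_edges(pos, 1.5 * ell))
}

lattice_edges <- function(positions, radius) {
  M <- nrow(positions)
  if (M < 2) return(matrix(integer(0), 0, 2))
  d <- as.matrix(stats::dist(positions))
  idx <- which(upper.tri(d) & d <= radius, arr.ind = TRUE)
  colnames(idx) <- NULL
  idx
}

#' Raft state
#'
#' Positions plus a symmetric link network (stored once per pair) and
#' per-clump status flags.
#'
#' @param positions M x 2 matrix (m).
#' @param edges two-column integer matrix of links; self-links are
#'   rejected, duplicate orientations collapsed.
#' @return A list of class `raft_state`.
#' @export
raft_state <- function(positions, edges = NULL) {
  positions <- rbind2mat(positions)
  if (is.null(edges)) edges <- matrix(integer(0), 0, 2)
  edges <- rbind2mat_int(edges)
  if (nrow(edges) > 0) {
    if (any(edges[, 1] == edges[, 2])) stop("self-links are not allowed")
    edges <- unique(cbind(pmin(edges[, 1], edges[, 2]),
                          pmax(edges[, 1], edges[, 2])))
  }
  structure(list(positions = positions, edges = edges), class = "raft_state")
}

rbind2mat_int <- function(e) {
  e <- if (is.matrix(e)) e else matrix(e, ncol = 2)
  storage.mode(e) <- "integer"
  e
}

#' Combine raft states into one ensemble
#'
#' Concatenates positions and re-indexes edges.
#'
#' @param ... `raft_state` objects.
#' @return A single `raft_state`.
#' @export
bind_rafts <- function(...) {
  parts <- list(...)
  if (length(parts) == 1 && is.list(parts[[1]]) &&
      !inherits(parts[[1]], "raft_state")) parts <- parts[[1]]
  off <- 0L
  pos <- list(); edg <- list()
  for (p in parts) {
    pos[[length(pos) + 1L]] <- p$positions
    if (nrow(p$edges) > 0) edg[[length(edg) + 1L]] <- p$edges + off
    off <- off + nrow(p$positions)
  }
  raft_state(do.call(rbind, pos),
             if (length(edg)) do.call(rbind, edg) else NULL)
}

#' Integrate a raft ensemble through the carrying flow
#'
#' Fixed-step fourth-order Runge--Kutta integration of the coupled
#' 2M-dimensional clump system.  After every step, links stretched
#' beyond the cutoff radius are removed permanently (raft
#' disaggregation), clumps entering a land-mask cell are frozen in
#' place ("beached"), and clumps leaving the field bounding box are
#' frozen with their exit step recorded ("exited").  Positions are
#' sampled every `dt_sample` seconds — the chain times of the
#' downstream Ulam discretization.
#'
#' The integrator is deterministic: identical inputs give bit-identical
#' ensembles.
#'
#' @param state a [raft_state()].
#' @param ocean,wind `flow_field`s.
#' @param params a [clump_params()].
#' @param springs a [spring_params()] (may be `NULL` when the ensemble
#'   has no links).
#' @param t0,t_end integration window (s); `dt_sample` must divide
#'   `t_end - t0` and `dt_int` must divide `dt_sample`.
#' @param dt_int RK4 step (s).
#' @param dt_sample sampling interval \eqn{\Delta t} (s).
#' @param land_mask optional logical matrix over the ocean grid cells
#'   (`(nx-1) x (ny-1)`); `TRUE` cells beach.
#' @return A `trajectory_ensemble`: list with `positions` (M x K x 2),
#'   `times` (length K), `status` (M x K integer: 0 active, 1 beached,
#'   2 exited), `exit_step`, `edges`, `edge_active`, `params`,
#'   `springs`.
#' @export
integrate_raft <- function(state, ocean, wind, params, springs = NULL,
                           t0, t_end, dt_int, dt_sample,
                           land_mask = NULL) {
  n_samp <- (t_end - t0) / dt_sample
  if (abs(n_samp - round(n_samp)) > 1e-8)
    stop("dt_sample must divide t_end - t0")
  n_sub <- dt_sample / dt_int
  if (abs(n_sub - round(n_sub)) > 1e-8)
    stop("dt_int must divide dt_sample")
  n_samp <- round(n_samp); n_sub <- round(n_sub)
  if (is.null(springs)) springs <- spring_params(1, 0, 0.2)
  par <- c(unclass(params), unclass(springs))
  res <- .ebomb_integrate(state$positions,
                          as.integer(state$edges[, 1]),
                          as.integer(state$edges[, 2]),
                          as_field_descriptor(ocean),
                          as_field_descriptor(wind), par,
                          t0, dt_int, n_samp * n_sub, n_sub,
                          land_mask)
  K <- n_samp + 1L
  pos <- aperm(array(res$positions, c(nrow(state$positions), 2, K)),
               c(1, 3, 2))
  structure(list(positions = pos,
                 times = t0 + dt_sample * (0:(K - 1)),
                 status = res$status,
                 exit_step = res$exit_step,
                 edges = state$edges,
                 edge_active = res$edge_active,
                 params = params, springs = springs),
            class = "trajectory_ensemble")
}

#' @export
print.trajectory_ensemble <- function(x, ...) {
  M <- dim(x$positions)[1]; K <- dim(x$positions)[2]
  fin <- x$status[, K]
  cat(sprintf("<trajectory_ensemble> %d clumps, %d sample times (dt = %g s)\n",
              M, K, diff(x$times)[1]))
  cat(sprintf("  final status: %d active, %d beached, %d exited\n",
              sum(fin == 0), sum(fin == 1), sum(fin == 2)))
  cat(sprintf("  links: %d of %d still intact\n",
              sum(x$edge_active), nrow(x$edges)))
  invisible(x)
}

#' Write a trajectory ensemble as CSV
#'
#' Long format with columns `clump_id, k, t, x, y, status`, plus a YAML
#' provenance block (parameters, sampling interval).
#'
#' @param ensemble a `trajectory_ensemble`.
#' @param file CSV path; provenance goes to `<file>.yaml`.
#' @export
write_trajectories <- function(ensemble, file) {
  M <- dim(ensemble$positions)[1]; K <- dim(ensemble$positions)[2]
  df <- data.frame(
    clump_id = rep(seq_len(M), times = K),
    k = rep(0:(K - 1), each = M),
    t = rep(ensemble$times, each = M),
    x = sprintf("%.17g", as.numeric(ensemble$positions[, , 1])),
    y = sprintf("%.17g", as.numeric(ensemble$positions[, , 2])),
    status = as.integer(ensemble$status))
  utils::write.csv(df, file, row.names = FALSE, quote = FALSE)
  yaml::write_yaml(list(clumps = M, samples = K,
                        dt = diff(ensemble$times)[1],
                        t0 = ensemble$times[1],
                        params = unclass(ensemble$params),
                        springs = unclass(ensemble$springs)),
                   paste0(file, ".yaml"))
  invisible(file)
}
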