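#' Box partition of a rectangular domain
#'
#' Square boxes of side `h` tiling `[xlim] x [ylim]`, indexed row-major
#' from the south-west corner (index `1` is the SW box, indices increase
#' eastward first).  Boxes are half-open, `[x0, x0 + h) x [y0, y0 + h)`,
#' so every interior point belongs to exactly one box.
#'
#' @param xlim,ylim domain bounds (m); widths must be integer multiples
#'   of `h`.
#' @param h box side (m), `> 0`.
#' @return An object of class `box_partition` with fields `x0`, `y0`,
#'   `h`, `nx`, `ny`, `N`.
#' @export
box_partition <- function(xlim, ylim, h) {
  if (h <= 0) stop("h must be > 0")
  nx <- (xlim[2] - xlim[1]) / h
  ny <- (ylim[2] - ylim[1]) / h
  if (abs(nx - round(nx)) > 1e-8 || abs(ny - round(ny)) > 1e-8)
    stop("domain widths must be integer multiples of the box side h")
  nx <- as.integer(round(nx)); ny <- as.integer(round(ny))
  if (nx * ny < 2) stop("a partition needs at least 2 boxes")
  structure(list(x0 = xlim[1], y0 = ylim[1], h = h,
                 nx = nx, ny = ny, N = nx * ny),
            class = "box_partition")
}

#' @export
print.box_partition <- function(x, ...) {
  cat(sprintf("<box_partition> %d x %d boxes of side %g m (N = %d)\n",
              x$nx, x$ny, x$h, x$N))
  invisible(x)
}

#' Map points to partition boxes
#'
#' Half-open box membership; points outside the domain bounds map to
#' the exterior marker `0L` (which the chain closure routes to the
#' nirvana state).
#'
#' @param x,y coordinates (vectors).
#' @param partition a [box_partition()].
#' @return Integer vector of box indices, `0L` for exterior points.
#' @export
assign_box <- function(x, y, partition) {
  ix <- floor((x - partition$x0) / partition$h) + 1
  iy <- floor((y - partition$y0) / partition$h) + 1
  ok <- ix >= 1 & ix <= partition$nx & iy >= 1 & iy <= partition$ny &
    is.finite(x) & is.finite(y)
  out <- integer(length(x))
  out[ok] <- as.integer((iy[ok] - 1) * partition$nx + ix[ok])
  out
}

#' Box centers
#'
#' @param partition a [box_partition()].
#' @return N x 2 matrix of box-center coordinates (m).
#' @export
box_centers <- function(partition) {
  ix <- ((seq_len(partition$N) - 1) %% partition$nx) + 1
  iy <- ((seq_len(partition$N) - 1) %/% partition$nx) + 1
  cbind(partition$x0 + (ix - 0.5) * partition$h,
        partition$y0 + (iy - 0.5) * partition$h)
}

#' Estimate one transition matrix by box counting
#'
#' Ulam estimate of the transfer operator between chain times `t_k` and
#' `t_{k+1}`: \eqn{\hat P_{ij}(k)} is the fraction of clumps in box i at
#' `t_k` found in box j at `t_{k+1}`.  Transitions into the exterior are
#' tallied separately (they feed the nirvana closure); boxes unoccupied
#' at `t_k` are reported empty.
#'
#' @param ensemble a `trajectory_ensemble` sampled at the chain times.
#' @param partition a [box_partition()].
#' @param k 0-based chain time index in `0 .. K-2`.
#' @return List with `P_hat` (sparse N x N, rows of occupied boxes sum
#'   to `1 - exterior fraction`), `exterior` (per-row exterior count),
#'   `counts` (sparse raw counts), `n_from` (row occupancy), `occupied`.
#' @export
estimate_transitions <- function(ensemble, partition, k) {
  K <- dim(ensemble$positions)[2]
  if (k < 0 || k > K - 2) stop("k must be in 0 .. K-2")
  from <- assign_box(ensemble$positions[, k + 1, 1],
                     ensemble$positions[, k + 1, 2], partition)
  to <- assign_box(ensemble$positions[, k + 2, 1],
                   ensemble$positions[, k + 2, 2], partition)
  transition_counts(from, to, partition$N)
}

# shared by estimate_transitions and the direct state-sequence path
transition_counts <- function(from, to, N) {
  keep <- from > 0
  from <- from[keep]; to <- to[keep]
  n_from <- tabulate(from, nbins = N)
  inside <- to > 0
  counts <- Matrix::sparseMatrix(i = from[inside], j = to[inside], x = 1,
                                 dims = c(N, N))
  exterior <- tabulate(from[!inside], nbins = N)
  occupied <- n_from > 0
  P_hat <- counts
  P_hat@x <- P_hat@x / n_from[P_hat@i + 1L]
  list(P_hat = P_hat, exterior = exterior, counts = counts,
       n_from = n_from, occupied = occupied)
}

#' Close an estimated transition matrix over the nirvana state
#'
#' Extends \eqn{\hat P(k)} to the `(N+1) x (N+1)` stochastic matrix on
#' `D + omega`: the outflow column collects each row's probability
#' imbalance (mass that left the domain), the omega row re-injects it
#' through the inflow distribution (uniform `1/N` by default,
#' emulating a background concentration), and `P[omega, omega] = 0`.
#' Rows of boxes with no occupants are routed wholly to omega, whence
#' the inflow re-injects them — stochasticity is preserved without
#' inventing local dynamics.
#'
#' @param est output of [estimate_transitions()].
#' @param inflow `"uniform"` or a probability vector of length N.
#' @return Sparse `(N+1) x (N+1)` row-stochastic matrix (dgCMatrix).
#' @export
close_chain <- function(est, inflow = "uniform") {
  N <- length(est$n_from)
  inflow <- resolve_inflow(inflow, N)
  P_hat <- est$P_hat
  row_sum <- Matrix::rowSums(P_hat)
  outflow <- 1 - row_sum
  if (any(outflow < -1e-12))
    stop("estimation bug: a row of P_hat sums to more than 1")
  outflow <- pmax(outflow, 0)
  tri <- Matrix::summary(P_hat)
  occ <- est$occupied
  i <- c(tri$i, which(occ), which(!occ), rep(N + 1L, N))
  j <- c(tri$j, rep(N + 1L, sum(occ)), rep(N + 1L, sum(!occ)), seq_len(N))
  x <- c(tri$x, outflow[occ], rep(1, sum(!occ)), inflow)
  keep <- x != 0
  Matrix::sparseMatrix(i = i[keep], j = j[keep], x = x[keep],
                       dims = c(N + 1L, N + 1L))
}

resolve_inflow <- function(inflow, N) {
  if (identical(inflow, "uniform")) return(rep(1 / N, N))
  if (!is.numeric(inflow) || length(inflow) != N ||
      any(inflow < 0) || abs(sum(inflow) - 1) > 1e-9)
    stop("inflow must be \"uniform\" or a probability vector over the boxes")
  inflow
}

#' Time-inhomogeneous Markov chain on a box partition
#'
#' Container for the sequence `P(0), ..., P(K-2)` of `(N+1) x (N+1)`
#' row-stochastic matrices over the extended state space D + omega
#' (state `N + 1` is the nirvana state), together with the chain times
#' and, when estimated from trajectories, the raw counts and occupancy.
#'
#' @param P list of sparse `(N+1) x (N+1)` row-stochastic matrices.
#' @param times chain times `t_0 < ... < t_{K-1}` (s); `length(P)` must
#'   be `K - 1`.
#' @param partition the [box_partition()], or `NULL` for abstract
#'   chains (fixtures, tests).
#' @param counts optional list of raw count matrices.
#' @param occupancy optional N x K matrix of box occupancies.
#' @param inflow inflow model tag or vector.
#' @return An object of class `bloom_chain`.
#' @export
bloom_chain <- function(P, times = seq_len(length(P) + 1) - 1,
                        partition = NULL, counts = NULL,
                        occupancy = NULL, inflow = "uniform") {
  if (length(P) < 1) stop("need at least one transition matrix")
  S <- nrow(P[[1]])
  for (k in seq_along(P)) {
    Pk <- methods::as(methods::as(P[[k]], "dMatrix"), "CsparseMatrix")
    P[[k]] <- Pk
    if (nrow(Pk) != S || ncol(Pk) != S) stop("inconsistent matrix dimensions")
    if (any(Pk@x < 0)) stop("negative transition probability")
    if (max(abs(Matrix::rowSums(Pk) - 1)) > 1e-12)
      stop("every row of every P(k) must sum to 1 (within 1e-12)")
  }
  if (length(times) != length(P) + 1)
    stop("length(times) must equal length(P) + 1")
  structure(list(P = P, times = as.numeric(times), n_states = S,
                 partition = partition, counts = counts,
                 occupancy = occupancy, inflow = inflow,
                 absorbing = NULL),
            class = "bloom_chain")
}

#' @export
print.bloom_chain <- function(x, ...) {
  cat(sprintf("<bloom_chain> %d states (+nirvana included), %d transition steps\n",
              x$n_states, length(x$P)))
  cat(sprintf("  times: t0 = %g s, dt = %g s\n", x$times[1],
              if (length(x$times) > 1) diff(x$times)[1] else NA))
  if (!is.null(x$absorbing))
    cat("  absorbing target:", paste(x$absorbing, collapse = " "), "\n")
  invisible(x)
}

#' Build the chain from a trajectory ensemble
#'
#' Applies [estimate_transitions()] and [close_chain()] at every chain
#' step.  Beached clumps keep counting in their frozen box; exited
#' clumps count as exterior from their exit time on.
#'
#' @param ensemble a `trajectory_ensemble`.
#' @param partition a [box_partition()].
#' @param inflow `"uniform"` or a probability vector of length N.
#' @return A [bloom_chain()] with counts and occupancy attached.
#' @export
build_chain <- function(ensemble, partition, inflow = "uniform") {
  K <- dim(ensemble$positions)[2]
  P <- vector("list", K - 1)
  counts <- vector("list", K - 1)
  occupancy <- matrix(0L, partition$N, K)
  for (k in 0:(K - 2)) {
    est <- estimate_transitions(ensemble, partition, k)
    P[[k + 1]] <- close_chain(est, inflow)
    counts[[k + 1]] <- est$counts
    occupancy[, k + 1] <- est$n_from
  }
  occupancy[, K] <- tabulate(
    assign_box(ensemble$positions[, K, 1], ensemble$positions[, K, 2],
               partition), nbins = partition$N)
  bloom_chain(P, ensemble$times, partition = partition, counts = counts,
              occupancy = occupancy, inflow = inflow)
}

#' Push a probability density forward along the chain
#'
#' \eqn{\lambda(k+1) = \lambda(k) P(k)}.
#'
#' @param chain a [bloom_chain()].
#' @param lambda0 probability vector over the `N + 1` states (must sum
#'   to 1 within 1e-9).
#' @param k_stop final 0-based step (default the whole horizon).
#' @return A `density_series`: `(k_stop + 1) x (N+1)` matrix, rows
#'   `lambda(0) .. lambda(k_stop)`.
#' @export
pushforward <- function(chain, lambda0, k_stop = length(chain$P)) {
  S <- chain$n_states
  if (length(lambda0) != S) stop("lambda0 must have length N + 1")
  if (any(lambda0 < 0) || abs(sum(lambda0) - 1) > 1e-9)
    stop("lambda0 must be a probability vector (sum 1 within 1e-9)")
  if (k_stop > length(chain$P)) stop("k_stop exceeds the chain horizon")
  out <- matrix(0, k_stop + 1, S)
  lam <- as.numeric(lambda0)
  out[1, ] <- lam
  for (k in seq_len(k_stop)) {
    lam <- as.numeric(Matrix::crossprod(chain$P[[k]], lam))
    out[k + 1, ] <- lam
  }
  structure(out, class = "density_series")
}

#' Initial density over a box set
#'
#' Builds the starting probability vector for pushforward experiments:
#' mass spread over the given boxes either uniformly or with
#' seeded-random weights (the seed is recorded as an attribute).
#'
#' @param chain a [bloom_chain()] (only its state count is used).
#' @param boxes box indices receiving mass.
#' @param weights `"uniform"` or `"random"`.
#' @param seed integer seed used when `weights = "random"`.
#' @return Probability vector of length `N + 1`.
#' @export
initial_density <- function(chain, boxes, weights = c("uniform", "random"),
                            seed = 1L) {
  weights <- match.arg(weights)
  S <- chain$n_states
  if (any(boxes < 1 | boxes > S - 1)) stop("boxes must lie in 1 .. N")
  lam <- numeric(S)
  if (weights == "uniform") {
    lam[boxes] <- 1 / length(boxes)
  } else {
    w <- withr_seed_runif(seed, length(boxes))
    lam[boxes] <- w / sum(w)
    attr(lam, "seed") <- as.integer(seed)
  }
  lam
}

# draw uniforms under a local seed without disturbing the global RNG
withr_seed_runif <- function(seed, n) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  stats::runif(n)
}

# ---- chain serialization (sparse triplet text format) -------------------

#' Write / read a chain as a directory of text files
#'
#' `write_chain()` writes `partition.yaml` (or a state-count stub for
#' abstract chains), one `P_<k>.csv` per step with 0-based sparse
#' triplets `i, j, value` (the nirvana state is index N), matching
#' `counts_<k>.csv` files when counts are attached, and `manifest.yaml`
#' (K, dt, t0, inflow, file list).  Values carry 17 significant digits,
#' so write–read–write round trips are bit-identical.
#'
#' @param chain a [bloom_chain()].
#' @param dir output directory (created if needed).
#' @return `write_chain()` the directory, invisibly; `read_chain()` the
#'   reconstructed chain.
#' @export
write_chain <- function(chain, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  S <- chain$n_states
  files <- character(0)
  for (k in seq_along(chain$P)) {
    tri <- Matrix::summary(chain$P[[k]])
    df <- data.frame(i = tri$i - 1L, j = tri$j - 1L,
                     value = sprintf("%.17g", tri$x))
    df <- df[order(df$i, df$j), ]
    f <- sprintf("P_%03d.csv", k - 1L)
    utils::write.csv(df, file.path(dir, f), row.names = FALSE, quote = FALSE)
    files <- c(files, f)
  }
  if (!is.null(chain$counts)) {
    for (k in seq_along(chain$counts)) {
      tri <- Matrix::summary(chain$counts[[k]])
      df <- data.frame(i = tri$i - 1L, j = tri$j - 1L,
                       value = sprintf("%.17g", tri$x))
      df <- df[order(df$i, df$j), ]
      f <- sprintf("counts_%03d.csv", k - 1L)
      utils::write.csv(df, file.path(dir, f), row.names = FALSE, quote = FALSE)
      files <- c(files, f)
    }
  }
  part <- chain$partition
  yaml::write_yaml(
    if (is.null(part)) list(abstract = TRUE, n_states = S)
    else list(abstract = FALSE, x0 = part$x0, y0 = part$y0, h = part$h,
              nx = part$nx, ny = part$ny),
    file.path(dir, "partition.yaml"))
  yaml::write_yaml(list(K = length(chain$times),
                        t0 = chain$times[1],
                        dt = if (length(chain$times) > 1)
                          diff(chain$times)[1] else 0,
                        inflow = if (is.character(chain$inflow))
                          chain$inflow else "custom",
                        n_states = S,
                        files = as.list(files)),
                   file.path(dir, "manifest.yaml"))
  invisible(dir)
}

#' @rdname write_chain
#' @export
read_chain <- function(dir) {
  man <- yaml::read_yaml(file.path(dir, "manifest.yaml"))
  pt <- yaml::read_yaml(file.path(dir, "partition.yaml"))
  S <- man$n_states
  K <- man$K
  P <- vector("list", K - 1)
  counts <- NULL
  for (k in seq_len(K - 1)) {
    df <- utils::read.csv(file.path(dir, sprintf("P_%03d.csv", k - 1L)))
    P[[k]] <- Matrix::sparseMatrix(i = df$i + 1L, j = df$j + 1L, x = df$value,
                                   dims = c(S, S))
  }
  cfiles <- grep("^counts_", unlist(man$files), value = TRUE)
  if (length(cfiles)) {
    counts <- vector("list", length(cfiles))
    for (k in seq_along(cfiles)) {
      df <- utils::read.csv(file.path(dir, cfiles[k]))
      counts[[k]] <- Matrix::sparseMatrix(i = df$i + 1L, j = df$j + 1L,
                                          x = df$value, dims = c(S - 1, S - 1))
    }
  }
  partition <- if (isTRUE(pt$abstract)) NULL
  else box_partition(c(pt$x0, pt$x0 + pt$nx * pt$h),
                     c(pt$y0, pt$y0 + pt$ny * pt$h), pt$h)
  times <- man$t0 + man$dt * (seq_len(K) - 1)
  bloom_chain(P, times, partition = partition, counts = counts,
              inflow = man$inflow)
}
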