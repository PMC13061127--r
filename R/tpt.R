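#' Source/target specification for transition path analysis
#'
#' Validates a pair of disjoint, nonempty state sets over `D + omega`.
#' The default source is the nirvana state itself — transition paths
#' then describe background mass entering the domain and reaching the
#' bloom set without first returning to the background — but any box
#' set may serve as the source (e.g. to contrast a hypothesized remote
#' origin against a decoy region).
#'
#' @param chain a [bloom_chain()].
#' @param source `"nirvana"` or a vector of box indices A.
#' @param target vector of box indices B.
#' @return List with integer vectors `A` and `B`.
#' @export
tpt_spec <- function(chain, source = "nirvana", target) {
  S <- chain$n_states
  A <- if (identical(source, "nirvana")) S else as.integer(source)
  B <- as.integer(target)
  if (length(A) == 0 || length(B) == 0) stop("source and target must be nonempty")
  if (any(B < 1 | B > S - 1)) stop("target boxes must lie in 1 .. N")
  if (any(A < 1 | A > S)) stop("source states must lie in 1 .. N+1")
  if (length(intersect(A, B))) stop("source and target sets must be disjoint")
  list(A = A, B = B)
}

#' Time-dependent forward committor
#'
#' \eqn{q^+_i(k)}: the probability that the chain, in state i at time
#' k, next reaches the target B before the source A within the horizon.
#' Solved by backward iteration
#' \eqn{q^+_i(k) = \sum_j P_{ij}(k) q^+_j(k+1)} for \eqn{i \notin A
#' \cup B}, with \eqn{q^+|_A = 0}, \eqn{q^+|_B = 1}, and final
#' condition \eqn{q^+(K-1) = 1_B}.
#'
#' @param chain a [bloom_chain()].
#' @param source,target as in [tpt_spec()] (or pass `spec`).
#' @param spec optionally a prebuilt [tpt_spec()].
#' @return K x (N+1) matrix, row `k+1` holding \eqn{q^+(k)}.
#' @export
forward_committor <- function(chain, source = "nirvana", target = NULL,
                              spec = NULL) {
  if (is.null(spec)) spec <- tpt_spec(chain, source, target)
  S <- chain$n_states; K <- length(chain$times)
  q <- matrix(0, K, S)
  q[K, spec$B] <- 1
  for (k in (K - 1):1) {
    q[k, ] <- as.numeric(chain$P[[k]] %*% q[k + 1, ])
    q[k, spec$A] <- 0
    q[k, spec$B] <- 1
  }
  q
}

#' Time-reversed chain
#'
#' Transition matrices of the chain traversed backward in time:
#' \deqn{P^-_{ij}(k) = \frac{\lambda_j(k-1)}{\lambda_i(k)}
#'       P_{ji}(k-1), \qquad \lambda_i(k) > 0,}
#' where \eqn{\lambda(k)} is the pushforward of `lambda0`.  States with
#' \eqn{\lambda_i(k) = 0} cannot be visited at time k; their reversed
#' rows are masked (set to the unit self-loop and flagged).  Masked
#' states never contribute to reactive currents because every current
#' term carries the \eqn{\lambda_i(k)} factor.
#'
#' @param chain a [bloom_chain()].
#' @param lambda0 initial probability vector over `N + 1` states.
#' @return A `reversed_chain`: list with `P_rev` (list indexed by k =
#'   1 .. K-1; entry k maps time k to k-1), `lambda` (K x (N+1)),
#'   `mask` (K x (N+1) logical, `TRUE` where `lambda == 0`).
#' @export
reverse_chain <- function(chain, lambda0) {
  lam <- unclass(pushforward(chain, lambda0))
  S <- chain$n_states; K <- length(chain$times)
  P_rev <- vector("list", K - 1)
  mask <- lam == 0
  for (k in seq_len(K - 1)) {
    lprev <- lam[k, ]; lnow <- lam[k + 1, ]
    inv <- ifelse(lnow > 0, 1 / lnow, 0)
    Pr <- Matrix::t(chain$P[[k]])
    Pr <- Matrix::Diagonal(S, inv) %*% Pr %*% Matrix::Diagonal(S, lprev)
    dead <- which(lnow == 0)
    if (length(dead))
      Pr <- Pr + Matrix::sparseMatrix(i = dead, j = dead, x = 1,
                                      dims = c(S, S))
    P_rev[[k]] <- Pr
  }
  structure(list(P_rev = P_rev, lambda = lam, mask = mask),
            class = "reversed_chain")
}

#' Time-dependent backward committor
#'
#' \eqn{q^-_i(k)}: the probability that the chain, in state i at time
#' k, last left the source A more recently than the target B.  Solved
#' by forward iteration on the reversed chain,
#' \eqn{q^-_i(k) = \sum_j P^-_{ij}(k) q^-_j(k-1)} for \eqn{i \notin A
#' \cup B}, with \eqn{q^-|_A = 1}, \eqn{q^-|_B = 0}, initial condition
#' \eqn{q^-(0) = 1_A}.  Unreachable (masked) states get \eqn{q^- = 0},
#' which is harmless: they carry zero probability.
#'
#' @param chain a [bloom_chain()].
#' @param reversed the matching [reverse_chain()] output.
#' @inheritParams forward_committor
#' @return K x (N+1) matrix, row `k+1` holding \eqn{q^-(k)}.
#' @export
backward_committor <- function(chain, reversed, source = "nirvana",
                               target = NULL, spec = NULL) {
  if (is.null(spec)) spec <- tpt_spec(chain, source, target)
  S <- chain$n_states; K <- length(chain$times)
  q <- matrix(0, K, S)
  q[1, spec$A] <- 1
  for (k in 2:K) {
    q[k, ] <- as.numeric(reversed$P_rev[[k - 1]] %*% q[k - 1, ])
    q[k, spec$A] <- 1
    q[k, spec$B] <- 0
    dead <- reversed$mask[k, ] & !(seq_len(S) %in% c(spec$A, spec$B))
    q[k, dead] <- 0
  }
  q
}

#' Time-dependent reactive current
#'
#' The average flux of transition trajectories through the pair (i, j)
#' between times k and k+1 — trajectories that last came from the
#' source and will next reach the target:
#' \deqn{f^{AB}_{ij}(k) = q^-_i(k)\,\lambda_i(k)\,P_{ij}(k)\,
#'       q^+_j(k+1).}
#'
#' @param chain a [bloom_chain()].
#' @param lambda K x (N+1) density series (from [reverse_chain()]).
#' @param q_plus,q_minus committor matrices.
#' @return List (length K-1) of sparse `(N+1) x (N+1)` current
#'   matrices, entry k holding \eqn{f(k-1)}.
#' @export
reactive_current <- function(chain, lambda, q_plus, q_minus) {
  S <- chain$n_states; K <- length(chain$times)
  out <- vector("list", K - 1)
  for (k in seq_len(K - 1)) {
    row_w <- q_minus[k, ] * lambda[k, ]
    col_w <- q_plus[k + 1, ]
    out[[k]] <- Matrix::Diagonal(S, row_w) %*% chain$P[[k]] %*%
      Matrix::Diagonal(S, col_w)
  }
  out
}

#' Effective (net) transition current
#'
#' \eqn{f^+_{ij}(k) = \max\{f^{AB}_{ij}(k) - f^{AB}_{ji}(k),\ 0\}}:
#' the detour-minimizing net current.  By construction
#' \eqn{f^+_{ij} f^+_{ji} = 0} for every pair.
#'
#' @param f_reactive output of [reactive_current()].
#' @return List of sparse matrices of the same shape.
#' @export
effective_current <- function(f_reactive) {
  lapply(f_reactive, function(f) {
    d <- f - Matrix::t(f)
    d@x[d@x < 0] <- 0
    Matrix::drop0(d)
  })
}

#' Current vector field at box centers
#'
#' Attaches to each partition box the vector
#' \eqn{f^+(x_i, t_k) = \sum_{j \ne i} f^+_{ij}(k)\, e_{ij}}, where
#' \eqn{e_{ij}} is the unit vector from the center of box i to the
#' center of box j — the magnitude and direction of the effective
#' current out of each box.  The nirvana state has no geometric
#' position: flux exchanged with it is reported separately as per-box
#' injection/ejection scalars.
#'
#' @param f_eff output of [effective_current()].
#' @param partition the [box_partition()] the chain lives on.
#' @return List with `vf` (array (K-1) x N x 2), `omega_in` ((K-1) x N:
#'   current injected from nirvana into each box), `omega_out`
#'   ((K-1) x N).
#' @export
current_vector_field <- function(f_eff, partition) {
  N <- partition$N
  ctr <- box_centers(partition)
  Km1 <- length(f_eff)
  vf <- array(0, c(Km1, N, 2))
  omega_in <- matrix(0, Km1, N)
  omega_out <- matrix(0, Km1, N)
  for (k in seq_len(Km1)) {
    tri <- Matrix::summary(f_eff[[k]])
    om <- N + 1L
    w_in <- tri$i == om & tri$j <= N
    w_out <- tri$j == om & tri$i <= N
    if (any(w_in)) omega_in[k, tri$j[w_in]] <- tri$x[w_in]
    if (any(w_out)) omega_out[k, tri$i[w_out]] <- tri$x[w_out]
    keep <- tri$i <= N & tri$j <= N & tri$i != tri$j & tri$x != 0
    if (!any(keep)) next
    i <- tri$i[keep]; j <- tri$j[keep]; v <- tri$x[keep]
    ex <- ctr[j, 1] - ctr[i, 1]; ey <- ctr[j, 2] - ctr[i, 2]
    nrm <- sqrt(ex^2 + ey^2)
    vf[k, , 1] <- rowsum_into(v * ex / nrm, i, N)
    vf[k, , 2] <- rowsum_into(v * ey / nrm, i, N)
  }
  list(vf = vf, omega_in = omega_in, omega_out = omega_out)
}

#' Full transition path analysis of a chain
#'
#' Convenience wrapper: committors, reversed chain, reactive and
#' effective currents, and (when the chain has a partition) the box
#' vector field, for a source/target pair.
#'
#' @param chain a [bloom_chain()].
#' @param source `"nirvana"` (default) or a box set A.
#' @param target box set B.
#' @param lambda0 initial density; default puts all mass on the nirvana
#'   state, so the analysis describes background mass entering D.
#' @return An object of class `tpt_current` with components `spec`,
#'   `q_plus`, `q_minus`, `lambda`, `f_reactive`, `f_eff`,
#'   `vector_field` (or `NULL`), `times`.
#' @export
tpt_current <- function(chain, source = "nirvana", target, lambda0 = NULL) {
  spec <- tpt_spec(chain, source, target)
  S <- chain$n_states
  if (is.null(lambda0)) {
    lambda0 <- numeric(S)
    lambda0[S] <- 1
  }
  qp <- forward_committor(chain, spec = spec)
  rev <- reverse_chain(chain, lambda0)
  qm <- backward_committor(chain, rev, spec = spec)
  fr <- reactive_current(chain, rev$lambda, qp, qm)
  fe <- effective_current(fr)
  vf <- if (!is.null(chain$partition))
    current_vector_field(fe, chain$partition) else NULL
  structure(list(spec = spec, q_plus = qp, q_minus = qm,
                 lambda = rev$lambda, mask = rev$mask,
                 f_reactive = fr, f_eff = fe,
                 vector_field = vf, times = chain$times,
                 partition = chain$partition),
            class = "tpt_current")
}

#' @export
print.tpt_current <- function(x, ...) {
  K <- length(x$times)
  tot <- sum(vapply(x$f_reactive, function(f) sum(f@x), numeric(1)))
  cat(sprintf("<tpt_current> horizon K = %d, |A| = %d, |B| = %d\n",
              K, length(x$spec$A), length(x$spec$B)))
  cat(sprintf("  time-integrated reactive current: %.6g\n", tot))
  invisible(x)
}

#' Time-integrated reactive current into the target
#'
#' \eqn{\sum_k \sum_i \sum_{j \in B} f^{AB}_{ij}(k)}: the total
#' transition flux delivered into the target over the horizon.  Used to
#' contrast candidate source regions (a strong corridor delivers orders
#' of magnitude more current than a decoy).
#'
#' @param tpt a `tpt_current`.
#' @return Scalar flux.
#' @export
current_into_target <- function(tpt) {
  B <- tpt$spec$B
  sum(vapply(tpt$f_reactive,
             function(f) sum(f[, B, drop = FALSE]@x), numeric(1)))
}

#' Per-box outgoing effective current
#'
#' Row sums of the effective current restricted to partition boxes,
#' optionally restricted to a window of time steps.
#'
#' @param tpt a `tpt_current` built on a chain with a partition.
#' @param steps 1-based step indices to include (default all).
#' @return Vector of length N: time-summed outgoing effective current.
#' @export
outgoing_effective_current <- function(tpt, steps = NULL) {
  if (is.null(steps)) steps <- seq_along(tpt$f_eff)
  S <- nrow(tpt$f_eff[[1]])
  out <- numeric(S - 1)
  for (k in steps) {
    rs <- Matrix::rowSums(tpt$f_eff[[k]])
    out <- out + rs[seq_len(S - 1)]
  }
  out
}
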