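#' Make a target box set absorbing
#'
#' Replaces row i of every transition matrix by the unit self-loop for
#' each i in the target set B, leaving all other rows (including the
#' nirvana row) untouched.  First-visit events to an absorbing B are
#' mutually exclusive, which is what turns cumulative occupation
#' probabilities into first-hitting-time distributions.
#'
#' @param chain a [bloom_chain()].
#' @param target_boxes indices of B, a subset of `1 .. N`.
#' @return A `bloom_chain` with `absorbing` set.
#' @export
make_absorbing <- function(chain, target_boxes) {
  S <- chain$n_states
  B <- as.integer(target_boxes)
  if (any(B < 1 | B > S - 1)) stop("target boxes must lie in 1 .. N")
  loop <- Matrix::sparseMatrix(i = B, j = B, x = 1, dims = c(S, S))
  sel <- Matrix::Diagonal(S, x = as.numeric(!(seq_len(S) %in% B)))
  chain$P <- lapply(chain$P, function(Pk) sel %*% Pk + loop)
  chain$absorbing <- B
  chain
}

#' Cumulative hitting probabilities of a target set
#'
#' For every candidate origin box, the probability that the chain —
#' made absorbing on B — occupies B at time `t_k`:
#' \deqn{p_{B,\bar b}(k) = \sum_{b \in B}
#'   \Big(\prod_{l=0}^{k-1} P(l)\Big)_{\bar b\, b},}
#' evaluated for all candidates at once by accumulating the matrix
#' product over the candidate rows.  With B absorbing this equals
#' \eqn{\Pr(T_B \le t_k \mid X_0 = \bar b)}, the cumulative
#' distribution of the first-hitting time.
#'
#' @param chain a `bloom_chain` already absorbing on `target_boxes`
#'   (see [make_absorbing()]); an error is raised otherwise.
#' @param target_boxes the target set B.
#' @param candidates candidate origin states (default: all non-target
#'   boxes; the nirvana state is never a candidate).
#' @return A `hitting_profile`: list with `candidates`, `times`, and
#'   the `cumulative` matrix (candidates x K, nondecreasing along k,
#'   first column zero).
#' @export
hitting_probability <- function(chain, target_boxes, candidates = NULL) {
  S <- chain$n_states
  B <- as.integer(target_boxes)
  if (is.null(chain$absorbing) || !setequal(chain$absorbing, B))
    stop("chain must first be made absorbing on the target set; see make_absorbing()")
  if (is.null(candidates)) candidates <- setdiff(seq_len(S - 1), B)
  candidates <- as.integer(candidates)
  if (any(candidates %in% B)) stop("candidates must be disjoint from the target")
  K <- length(chain$times)
  Q <- Matrix::sparseMatrix(i = seq_along(candidates), j = candidates, x = 1,
                            dims = c(length(candidates), S))
  cum <- matrix(0, length(candidates), K)
  for (k in seq_len(K - 1)) {
    Q <- Q %*% chain$P[[k]]
    cum[, k + 1] <- Matrix::rowSums(Q[, B, drop = FALSE])
  }
  structure(list(candidates = candidates, times = chain$times,
                 cumulative = cum, target = B),
            class = "hitting_profile")
}

#' First-hitting-time probability mass function
#'
#' Differences the cumulative hitting curve:
#' \eqn{p(t_0 \mid \bar b) = 0} and \eqn{p(t_k \mid \bar b) =
#' p_{B,\bar b}(k) - p_{B,\bar b}(k-1)} for `k >= 1`.  Negative
#' differences within `-1e-12` (rounding) are clipped to zero; anything
#' larger flags a monotonicity violation upstream.
#'
#' @param profile a `hitting_profile` from [hitting_probability()].
#' @return The profile with a `pmf` matrix added (same shape as
#'   `cumulative`).
#' @export
first_hit_pmf <- function(profile) {
  cum <- profile$cumulative
  pmf <- cbind(0, t(apply(cum, 1, diff)))
  if (ncol(cum) == 2) pmf <- cbind(0, cum[, 2] - cum[, 1])
  if (any(pmf < -1e-12))
    stop("monotonicity violation in the cumulative hitting probabilities ",
         "(is the chain really absorbing on the target?)")
  pmf[pmf < 0] <- 0
  profile$pmf <- pmf
  profile
}

#' Bayesian inversion of a bloom observation
#'
#' Inverts an observed bloom — a set of partition boxes B where a high
#' concentration was recorded at chain time index `k_obs` — into a
#' posterior over candidate origin boxes:
#' \deqn{p(\bar b \mid t_{k_B}) \propto p(t_{k_B} \mid \bar b)\,
#'       p(\bar b),}
#' where the likelihood is the first-hitting-time pmf of B evaluated at
#' the observation time, and the prior defaults to uniform (no prior
#' knowledge of the origin).  The maximum likelihood estimator is the
#' argmax, with deterministic lowest-index tie-breaking; the full tie
#' set is reported.  When every candidate has zero likelihood the
#' result is flagged `no_path` instead of silently returning a uniform
#' posterior.
#'
#' Candidates default to the boxes with at least one clump occupancy
#' over the horizon (when the chain carries occupancy information);
#' boxes never visited are reported as unvisited with zero posterior.
#' The nirvana state is never a candidate: a bloom cannot originate in
#' the virtual background state.
#'
#' @param chain a [bloom_chain()] (not yet absorbing; the absorbing
#'   transform is applied internally to a copy).
#' @param target_boxes the observed bloom box set B.
#' @param k_obs 0-based observation time index `k_B` in `1 .. K-1`.
#' @param prior `"uniform"` or a nonnegative vector over the candidate
#'   set (normalized internally).
#' @param candidates optional explicit candidate set.
#' @return An object of class `origin_posterior`: list with
#'   `candidates`, `likelihood`, `prior`, `posterior`, `mle`
#'   (box index), `tie_set`, `no_path`, `k_obs`, `profile`.
#' @export
origin_posterior <- function(chain, target_boxes, k_obs,
                             prior = "uniform", candidates = NULL) {
  K <- length(chain$times)
  if (k_obs < 1 || k_obs > K - 1)
    stop("k_obs must lie in 1 .. K-1 (0-based chain time index)")
  B <- as.integer(target_boxes)
  if (is.null(candidates)) {
    candidates <- setdiff(seq_len(chain$n_states - 1), B)
    if (!is.null(chain$occupancy)) {
      visited <- which(rowSums(chain$occupancy) > 0)
      candidates <- intersect(candidates, visited)
    }
  }
  prof <- first_hit_pmf(hitting_probability(make_absorbing(chain, B), B,
                                            candidates))
  lik <- prof$pmf[, k_obs + 1]
  pr <- if (identical(prior, "uniform")) rep(1, length(candidates))
  else {
    if (!is.numeric(prior) || length(prior) != length(candidates) ||
        any(prior < 0) || sum(prior) <= 0)
      stop("prior must be \"uniform\" or a nonnegative vector over the candidates")
    prior
  }
  pr <- pr / sum(pr)
  w <- lik * pr
  no_path <- sum(w) == 0
  post <- if (no_path) rep(NA_real_, length(w)) else w / sum(w)
  if (no_path) {
    mle <- NA_integer_; ties <- integer(0)
  } else {
    top <- max(post)
    ties <- candidates[post >= top - 1e-12 * max(top, 1)]
    mle <- min(ties)
  }
  structure(list(candidates = candidates, likelihood = lik,
                 prior = pr, posterior = post,
                 mle = mle, tie_set = ties, no_path = no_path,
                 k_obs = as.integer(k_obs), target = B,
                 profile = prof, partition = chain$partition),
            class = "origin_posterior")
}

#' @export
print.origin_posterior <- function(x, ...) {
  cat(sprintf("<origin_posterior> %d candidates, bloom observed at k = %d\n",
              length(x$candidates), x$k_obs))
  if (x$no_path) {
    cat("  no path: every candidate has zero likelihood\n")
  } else {
    cat(sprintf("  MLE origin box: %d (posterior %.4g)\n", x$mle,
                x$posterior[match(x$mle, x$candidates)]))
    if (length(x$tie_set) > 1)
      cat("  ties:", paste(x$tie_set, collapse = " "), "\n")
  }
  invisible(x)
}

#' @export
summary.origin_posterior <- function(object, n = 5, ...) {
  ord <- order(object$posterior, decreasing = TRUE)
  top <- utils::head(ord, n)
  df <- data.frame(box = object$candidates[top],
                   likelihood = object$likelihood[top],
                   posterior = object$posterior[top])
  if (!is.null(object$partition)) {
    ctr <- box_centers(object$partition)
    df$x <- ctr[df$box, 1]; df$y <- ctr[df$box, 2]
  }
  df
}

#' Write a posterior as CSV plus a YAML summary
#'
#' One row per candidate (box index, box center when a partition is
#' attached, prior, likelihood, posterior, MLE flag); the YAML summary
#' records the MLE, tie set and observation index.
#'
#' @param posterior an `origin_posterior`.
#' @param file CSV path; summary goes to `<file>.yaml`.
#' @export
write_posterior <- function(posterior, file) {
  df <- data.frame(box = posterior$candidates,
                   prior = posterior$prior,
                   likelihood = posterior$likelihood,
                   posterior = posterior$posterior,
                   is_mle = posterior$candidates %in% posterior$mle)
  if (!is.null(posterior$partition)) {
    ctr <- box_centers(posterior$partition)
    df <- cbind(df[1], x = ctr[df$box, 1], y = ctr[df$box, 2], df[-1])
  }
  utils::write.csv(df, file, row.names = FALSE, quote = FALSE)
  yaml::write_yaml(list(mle = posterior$mle,
                        tie_set = as.integer(posterior$tie_set),
                        k_obs = posterior$k_obs,
                        no_path = posterior$no_path,
                        target = as.integer(posterior$target)),
                   paste0(file, ".yaml"))
  invisible(file)
}
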