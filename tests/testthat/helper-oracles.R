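# Brute-force oracles: exhaustive path enumeration over small chains and
# direct Monte-Carlo simulation.  These never call the package's own
# recursion-based implementations.

# all state paths over `steps` future steps as a matrix (rows = paths)
all_paths <- function(S, steps) {
  if (steps == 0) return(matrix(integer(0), 1, 0))
  as.matrix(expand.grid(rep(list(seq_len(S)), steps)))
}

# dense transition matrices from a bloom_chain
dense_P <- function(chain) lapply(chain$P, as.matrix)

# first-hitting pmf of target set B from a start state, by enumeration
# over all paths of the *unmodified* chain (first visit counted once)
enum_first_hit_pmf <- function(P, start, B, K) {
  S <- nrow(P[[1]])
  pmf <- numeric(K)
  if (start %in% B) {
    pmf[1] <- 1
    return(pmf)
  }
  paths <- all_paths(S, K - 1)
  w <- rep(1, nrow(paths))
  prev <- rep(start, nrow(paths))
  first <- rep(NA_integer_, nrow(paths))
  for (k in seq_len(K - 1)) {
    w <- w * P[[k]][cbind(prev, paths[, k])]
    hitnow <- is.na(first) & paths[, k] %in% B
    first[hitnow] <- k
    prev <- paths[, k]
  }
  for (k in seq_len(K - 1)) pmf[k + 1] <- sum(w[which(first == k)])
  pmf
}

# forward committor by enumeration: Pr(first entry into A∪B at or after
# k is into B | X_k = i)
enum_forward_committor <- function(P, A, B) {
  S <- nrow(P[[1]])
  K <- length(P) + 1
  q <- matrix(0, K, S)
  for (r in K:1) {
    for (i in seq_len(S)) {
      if (i %in% B) { q[r, i] <- 1; next }
      if (i %in% A) { q[r, i] <- 0; next }
      if (r == K) { q[r, i] <- 0; next }
      paths <- all_paths(S, K - r)
      w <- rep(1, nrow(paths))
      prev <- rep(i, nrow(paths))
      for (c in seq_len(ncol(paths))) {
        w <- w * P[[r + c - 1]][cbind(prev, paths[, c])]
        prev <- paths[, c]
      }
      inA <- matrix(paths %in% A, nrow(paths))
      inB <- matrix(paths %in% B, nrow(paths))
      first_hit_B <- logical(nrow(paths))
      undecided <- rep(TRUE, nrow(paths))
      for (c in seq_len(ncol(paths))) {
        first_hit_B <- first_hit_B | (undecided & inB[, c])
        undecided <- undecided & !inA[, c] & !inB[, c]
      }
      q[r, i] <- sum(w[first_hit_B])
    }
  }
  q
}

# path weights and per-time source/target history over all full paths
enum_path_table <- function(P, lambda0) {
  S <- nrow(P[[1]])
  K <- length(P) + 1
  paths <- all_paths(S, K)      # columns are times 0..K-1 (1-based rows r)
  w <- lambda0[paths[, 1]]
  for (r in 2:K) w <- w * P[[r - 1]][cbind(paths[, r - 1], paths[, r])]
  list(paths = paths, w = w, S = S, K = K)
}

# backward committor by enumeration under the path measure from lambda0
enum_backward_committor <- function(P, lambda0, A, B) {
  tab <- enum_path_table(P, lambda0)
  K <- tab$K; S <- tab$S
  q <- matrix(NA_real_, K, S)
  lastA <- matrix(0L, length(tab$w), K)
  lastB <- matrix(0L, length(tab$w), K)
  for (r in seq_len(K)) {
    pa <- ifelse(tab$paths[, r] %in% A, r, if (r > 1) lastA[, r - 1] else 0L)
    pb <- ifelse(tab$paths[, r] %in% B, r, if (r > 1) lastB[, r - 1] else 0L)
    lastA[, r] <- pa; lastB[, r] <- pb
  }
  for (r in seq_len(K)) {
    for (i in seq_len(S)) {
      sel <- tab$paths[, r] == i
      tot <- sum(tab$w[sel])
      if (tot == 0) next
      ev <- lastA[, r] > lastB[, r]      # last came from A, not B
      q[r, i] <- sum(tab$w[sel & ev]) / tot
    }
  }
  q
}

# reactive current by enumeration: Pr(X_k = i, X_{k+1} = j, the chain
# last left A (not B) by time k, and first enters A∪B after k+1 in B —
# with X_{k+1} in B itself counting as entering B)
enum_reactive_current <- function(P, lambda0, A, B) {
  tab <- enum_path_table(P, lambda0)
  K <- tab$K; S <- tab$S
  n <- length(tab$w)
  lastA <- matrix(0L, n, K); lastB <- matrix(0L, n, K)
  for (r in seq_len(K)) {
    lastA[, r] <- ifelse(tab$paths[, r] %in% A, r,
                         if (r > 1) lastA[, r - 1] else 0L)
    lastB[, r] <- ifelse(tab$paths[, r] %in% B, r,
                         if (r > 1) lastB[, r - 1] else 0L)
  }
  nxt <- matrix(0L, n, K)   # 1 = next decided in B, -1 = in A, 0 = neither
  for (r in K:1) {
    nxt[, r] <- ifelse(tab$paths[, r] %in% B, 1L,
                       ifelse(tab$paths[, r] %in% A, -1L,
                              if (r < K) nxt[, r + 1] else 0L))
  }
  out <- vector("list", K - 1)
  for (r in seq_len(K - 1)) {
    f <- matrix(0, S, S)
    ev <- (lastA[, r] > lastB[, r]) & (nxt[, r + 1] == 1L)
    for (i in seq_len(S)) for (j in seq_len(S)) {
      sel <- ev & tab$paths[, r] == i & tab$paths[, r + 1] == j
      f[i, j] <- sum(tab$w[sel])
    }
    out[[r]] <- f
  }
  out
}

# Monte-Carlo first-hit histogram: n sampled paths of the chain
mc_first_hit <- function(P, start, B, K, n, seed) {
  S <- nrow(P[[1]])
  cur <- rep(start, n)
  hit_time <- ifelse(cur %in% B, 0L, NA_integer_)
  withr::with_seed(seed, {
    for (k in seq_len(K - 1)) {
      nxt <- integer(n)
      for (s in unique(cur)) {
        idx <- cur == s
        nxt[idx] <- sample.int(S, sum(idx), replace = TRUE, prob = P[[k]][s, ])
      }
      cur <- nxt
      hit_time[is.na(hit_time) & cur %in% B] <- k
    }
  })
  tabulate(hit_time + 1L, nbins = K) / n
}

# direct evaluation of the cumulative occupation probability: the
# restricted matrix product, one candidate at a time
direct_cumulative <- function(P, start, B, K) {
  S <- nrow(P[[1]])
  v <- numeric(S); v[start] <- 1
  out <- numeric(K)
  out[1] <- sum(v[B])
  for (k in seq_len(K - 1)) {
    v <- as.numeric(v %*% P[[k]])
    out[k + 1] <- sum(v[B])
  }
  out
}

# random chain with some zero entries (exercises sparsity) built without
# touching the global RNG
random_sparse_chain <- function(S, K, seed, zero_frac = 0.3) {
  withr::with_seed(seed, {
    P <- lapply(seq_len(K - 1), function(k) {
      M <- matrix(stats::runif(S * S), S, S)
      M[matrix(stats::runif(S * S) < zero_frac, S)] <- 0
      M <- M + diag(1e-3, S)          # keep rows nonzero
      Matrix::Matrix(M / rowSums(M), sparse = TRUE)
    })
    bloom_chain(P)
  })
}
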