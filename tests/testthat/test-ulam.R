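test_that("box assignment follows the half-open convention", {
  part <- box_partition(c(0, 4e5), c(0, 2e5), 1e5)   # 4 x 2 boxes
  expect_equal(part$N, 8L)
  # SW corner of box 1
  expect_identical(assign_box(0, 0, part), 1L)
  # a point on an interior shared edge belongs to the box it bounds below
  expect_identical(assign_box(1e5, 0, part), 2L)
  expect_identical(assign_box(1.5e5, 1e5, part), 6L)
  # outside the bounds: exterior marker
  expect_identical(assign_box(-1, 1e4, part), 0L)
  expect_identical(assign_box(4e5, 1e4, part), 0L)   # top edge is exterior
  expect_identical(assign_box(2e5, 2e5, part), 0L)
  # row-major from the SW corner
  expect_equal(unname(box_centers(part)[1, ]), c(5e4, 5e4))
  expect_equal(unname(box_centers(part)[5, ]), c(5e4, 1.5e5))
})

fake_ensemble <- function(pos_list) {
  K <- length(pos_list)
  M <- nrow(pos_list[[1]])
  pos <- array(NA_real_, c(M, K, 2))
  for (k in seq_len(K)) pos[, k, ] <- pos_list[[k]]
  list(positions = pos, times = (seq_len(K) - 1) * 100,
       status = matrix(0L, M, K))
}

test_that("transition estimation counts box hops", {
  part <- box_partition(c(0, 4e5), c(0, 1e5), 1e5)   # 4 x 1 boxes
  # 4 clumps in box 1; at t+1 three land in box 2, one stays
  ens <- fake_ensemble(list(
    cbind(c(1e4, 2e4, 3e4, 4e4), rep(5e4, 4)),
    cbind(c(1.1e5, 1.2e5, 1.3e5, 5e4), rep(5e4, 4))))
  est <- estimate_transitions(ens, part, 0)
  expect_equal(est$P_hat[1, 1], 0.25)
  expect_equal(est$P_hat[1, 2], 0.75)
  expect_equal(est$n_from, c(4, 0, 0, 0))
  # stationary clumps: identity on occupied rows
  ens2 <- fake_ensemble(list(cbind(c(5e4, 2.5e5), c(5e4, 5e4)),
                             cbind(c(5e4, 2.5e5), c(5e4, 5e4))))
  est2 <- estimate_transitions(ens2, part, 0)
  expect_equal(est2$P_hat[1, 1], 1)
  expect_equal(est2$P_hat[3, 3], 1)
  # exterior transitions are tallied apart; occupied rows decompose exactly
  ens3 <- fake_ensemble(list(cbind(c(1e4, 2e4), c(5e4, 5e4)),
                             cbind(c(1.5e5, -5e4), c(5e4, 5e4))))
  est3 <- estimate_transitions(ens3, part, 0)
  expect_equal(Matrix::rowSums(est3$P_hat)[1] + est3$exterior[1] / 2, 1)
})

test_that("the nirvana closure yields exactly stochastic matrices", {
  part <- box_partition(c(0, 4e5), c(0, 1e5), 1e5)
  ens <- fake_ensemble(list(cbind(c(1e4, 2e4, 3e4), rep(5e4, 3)),
                            cbind(c(1.5e5, -1, 3e4), rep(5e4, 3))))
  est <- estimate_transitions(ens, part, 0)
  P <- close_chain(est, "uniform")
  expect_equal(dim(P), c(5L, 5L))
  expect_equal(as.numeric(Matrix::rowSums(P)), rep(1, 5), tolerance = 1e-15)
  # outflow of row 1 collects the exterior transition
  expect_equal(P[1, 5], 1 / 3)
  # empty rows route wholly to nirvana
  expect_equal(P[2, 5], 1)
  expect_equal(P[4, 5], 1)
  # the nirvana row is the uniform inflow with a zero self-loop
  expect_equal(as.numeric(P[5, ]), c(rep(1 / 4, 4), 0))
  # already stochastic estimate: zero outflow column
  ens4 <- fake_ensemble(list(cbind(c(1e4, 1.5e5, 2.5e5, 3.5e5), rep(5e4, 4)),
                             cbind(c(1e4, 1.5e5, 2.5e5, 3.5e5), rep(5e4, 4))))
  P4 <- close_chain(estimate_transitions(ens4, part, 0), "uniform")
  expect_equal(max(abs(P4[1:4, 5])), 0)
})

test_that("close_chain validates inflow and over-full rows", {
  part <- box_partition(c(0, 2e5), c(0, 1e5), 1e5)
  ens <- fake_ensemble(list(cbind(c(5e4), 5e4), cbind(c(5e4), 5e4)))
  est <- estimate_transitions(ens, part, 0)
  expect_error(close_chain(est, c(0.7, 0.7)), "probability vector")
  bad <- est
  bad$P_hat[1, 1] <- 1.5
  expect_error(close_chain(bad, "uniform"), "estimation bug")
})

test_that("pushforward conserves probability and matches hand products", {
  # 2-box chain plus nirvana, constant matrices
  P <- Matrix::Matrix(matrix(c(0.5, 0.5, 0,
                               0, 1, 0,
                               1, 0, 0), 3, 3, byrow = TRUE), sparse = TRUE)
  ch <- bloom_chain(list(P, P), times = 0:2)
  lam <- pushforward(ch, c(1, 0, 0))
  expect_equal(unname(lam[3, ]), c(0.25, 0.75, 0))
  # identity chain leaves the density untouched
  I3 <- Matrix::Diagonal(3)
  chI <- bloom_chain(list(I3, I3, I3))
  lamI <- pushforward(chI, c(0.2, 0.5, 0.3))
  expect_equal(unname(lamI[4, ]), c(0.2, 0.5, 0.3))
  # conservation on random chains
  for (s in 1:5) {
    ch <- random_chain(7, 9, seed = s)
    lam <- pushforward(ch, rep(1 / 7, 7))
    expect_lt(max(abs(rowSums(lam) - 1)), 1e-12)
    expect_true(all(lam >= 0))
  }
  expect_error(pushforward(ch, c(1, 1, rep(0, 5))), "probability vector")
})

test_that("initial densities are supported on the requested boxes", {
  ch <- random_chain(6, 4, seed = 2)
  lam <- initial_density(ch, c(2, 4))
  expect_equal(lam[c(2, 4)], c(0.5, 0.5))
  expect_equal(sum(lam), 1)
  lr1 <- initial_density(ch, c(1, 3, 5), weights = "random", seed = 9)
  lr2 <- initial_density(ch, c(1, 3, 5), weights = "random", seed = 9)
  expect_identical(lr1, lr2)
  expect_equal(sum(lr1), 1)
  expect_true(all(lr1[c(2, 4, 6)] == 0))
})

test_that("Ulam estimates converge to a known 2-state time-varying chain", {
  # direct simulation of the Markov process (not via the raft model)
  M <- 1e4
  K <- 6
  gen <- function(k) {
    p <- 0.7 + 0.2 * sin(2 * pi * k / K)
    q <- 0.4 + 0.3 * cos(2 * pi * k / K)
    matrix(c(p, 1 - p, 1 - q, q), 2, 2, byrow = TRUE)
  }
  part <- box_partition(c(0, 2e5), c(0, 1e5), 1e5)
  centers <- box_centers(part)
  states <- matrix(0L, M, K)
  withr::with_seed(42, {
    states[, 1] <- sample(1:2, M, TRUE)
    for (k in 1:(K - 1)) {
      Pk <- gen(k - 1)
      u <- runif(M)
      states[, k + 1] <- ifelse(u < Pk[cbind(states[, k], 1)], 1L, 2L)
    }
  })
  ens <- fake_ensemble(lapply(seq_len(K), function(k)
    centers[states[, k], , drop = FALSE]))
  for (k in 0:(K - 2)) {
    est <- estimate_transitions(ens, part, k)
    expect_lt(max(abs(as.matrix(est$P_hat) - gen(k))), 3 / sqrt(M))
  }
})

test_that("chain serialization round-trips bit-identically", {
  ch <- random_chain(5, 4, seed = 7)
  d1 <- file.path(tempdir(), "chain_a")
  d2 <- file.path(tempdir(), "chain_b")
  write_chain(ch, d1)
  back <- read_chain(d1)
  write_chain(back, d2)
  for (f in list.files(d1))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  for (k in seq_along(ch$P))
    expect_equal(as.matrix(back$P[[k]]), as.matrix(ch$P[[k]]), tolerance = 0)
})

test_that("chains built from a scenario reproduce gross transport", {
  scn <- make_scenario(2, small_config())
  lam0 <- initial_density(scn$chain, scn$source_boxes)
  lam <- pushforward(scn$chain, lam0, scn$k_bloom)
  mass <- sum(lam[scn$k_bloom + 1, scn$bloom_boxes])
  expect_gt(mass, 0)
  expect_equal(mass, scn$pilot_mass)
  # every estimated matrix is row-stochastic and nonnegative
  for (P in scn$chain$P) {
    expect_lt(max(abs(Matrix::rowSums(P) - 1)), 1e-12)
    expect_true(all(P@x >= 0))
  }
})
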