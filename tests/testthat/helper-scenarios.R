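# Shared fixtures built in code.

# small, fast scenario configuration for unit tests (not the reference
# study conditions): fewer clumps, shorter horizon, coarser field grid
small_config <- function() {
  cfg <- default_config()
  cfg$scenario$grid_nx <- 41L
  cfg$scenario$grid_ny <- 21L
  cfg$scenario$grid_nt <- 41L
  cfg$scenario$n_rafts <- 12L
  cfg$scenario$n_background <- 60L
  cfg$scenario$k_bloom_window <- c(6L, 14L)
  cfg$chain$K <- 16L
  cfg$ebomb$alpha <- 0.03      # stronger windage: early plume detachment
  cfg
}

# the reference-condition scenario suite used by the recovery and
# current-emanation checks; computed once per test run
scenario_suite <- local({
  cache <- NULL
  function(n_seeds = 10) {
    if (!is.null(cache) && length(cache) >= n_seeds)
      return(cache[seq_len(n_seeds)])
    cache <<- lapply(seq_len(n_seeds), function(s) {
      scn <- make_scenario(s)
      post <- origin_posterior(scn$chain, scn$bloom_boxes, scn$k_bloom)
      tp <- tpt_current(scn$chain, "nirvana", scn$bloom_boxes)
      first_q <- seq_len((length(scn$chain$times) - 1) %/% 4)
      oc <- outgoing_effective_current(tp, first_q)
      list(scenario = scn, posterior = post,
           recovered = post$mle %in% scn$source_boxes,
           emanation_box = which.max(oc),
           emanation_ok = which.max(oc) %in% scn$source_boxes)
    })
    cache
  }
})

# uniform fields on a shared grid (for reference-path comparisons)
uniform_fields <- function(U = 0, V = 0, W1 = 0, W2 = 0,
                           domain = c(0, 2e6, 0, 1e6),
                           t_range = c(-1e6, 1.3e7)) {
  mk <- function(a, b, kind) {
    g <- list(x = seq(domain[1], domain[2], length.out = 5),
              y = seq(domain[3], domain[4], length.out = 5),
              t = seq(t_range[1], t_range[2], length.out = 5))
    flow_field(g$x, g$y, g$t, array(a, c(5, 5, 5)), array(b, c(5, 5, 5)), kind)
  }
  list(ocean = mk(U, V, "ocean"), wind = mk(W1, W2, "wind"))
}
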