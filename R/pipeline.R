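#' Run the full origin-inference pipeline
#'
#' Orchestrates scenario generation (fields, raft simulation, chain
#' reduction), Bayesian origin inversion and transition path analysis
#' from a single validated configuration, with per-stage caching and a
#' reproducible report.  Stage results are cached in
#' `<out_dir>/cache` keyed by a checksum of the configuration sections
#' they depend on, so editing the inference section reuses the
#' simulated scenario while editing any upstream value invalidates the
#' downstream stages.
#'
#' @param config a [default_config()]-shaped list, or the path of a
#'   YAML file holding one.
#' @param out_dir output directory (default: a fresh temporary
#'   directory).  Stage outputs are written here: `scenario/` (fields +
#'   scenario.yaml), `trajectories.csv`, `chain/`, `posterior.csv`,
#'   `tpt.yaml`, `report.yaml`.
#' @return An object of class `run_report`: stage summaries, the
#'   output file manifest with md5 checksums, and provenance (config
#'   hash, seed, which stages were cache hits).
#' @export
run_pipeline <- function(config = default_config(), out_dir = tempfile("run")) {
  if (is.character(config) && length(config) == 1)
    config <- yaml::read_yaml(config)
  validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cache <- file.path(out_dir, "cache")
  dir.create(cache, showWarnings = FALSE)

  t_all <- proc.time()[["elapsed"]]
  hashes <- list()
  cached <- c(scenario = FALSE, bayes = FALSE, tpt = FALSE)

  # -- stage 1: scenario (fields + simulation + chain) ---------------------
  hashes$scenario <- hash_obj(config[c("scenario", "ebomb", "chain")])
  sc_file <- file.path(cache, paste0("scenario_", hashes$scenario, ".rds"))
  if (file.exists(sc_file)) {
    scenario <- readRDS(sc_file)
    cached["scenario"] <- TRUE
  } else {
    scenario <- make_scenario(config$scenario$seed, config)
    saveRDS(scenario, sc_file)
  }

  inf <- config$inference
  target <- if (identical(inf$target, "from-scenario"))
    scenario$bloom_boxes else as.integer(inf$target)
  k_obs <- if (identical(inf$k_obs, "from-scenario"))
    scenario$k_bloom else as.integer(inf$k_obs)

  # -- stage 2: Bayesian inversion ----------------------------------------
  hashes$bayes <- hash_obj(list(hashes$scenario, target, k_obs, inf$prior))
  ba_file <- file.path(cache, paste0("bayes_", hashes$bayes, ".rds"))
  if (file.exists(ba_file)) {
    posterior <- readRDS(ba_file)
    cached["bayes"] <- TRUE
  } else {
    posterior <- origin_posterior(scenario$chain, target, k_obs,
                                  prior = inf$prior)
    saveRDS(posterior, ba_file)
  }

  # -- stage 3: transition path analysis ----------------------------------
  hashes$tpt <- hash_obj(list(hashes$scenario, target, inf$tpt_source))
  tp_file <- file.path(cache, paste0("tpt_", hashes$tpt, ".rds"))
  if (file.exists(tp_file)) {
    tpt <- readRDS(tp_file)
    cached["tpt"] <- TRUE
  } else {
    tpt <- tpt_current(scenario$chain, source = inf$tpt_source,
                       target = target)
    saveRDS(tpt, tp_file)
  }

  # -- outputs -------------------------------------------------------------
  write_scenario(scenario, file.path(out_dir, "scenario"))
  write_trajectories(scenario$ensemble, file.path(out_dir, "trajectories.csv"))
  write_chain(scenario$chain, file.path(out_dir, "chain"))
  write_posterior(posterior, file.path(out_dir, "posterior.csv"))
  early <- seq_len(max(1L, (length(scenario$chain$times) - 1) %/% 4))
  out_cur <- outgoing_effective_current(tpt, early)
  yaml::write_yaml(list(source = inf$tpt_source,
                        target = as.integer(target),
                        current_into_target = current_into_target(tpt),
                        max_outgoing_box_first_quarter =
                          as.integer(which.max(out_cur))),
                   file.path(out_dir, "tpt.yaml"))

  files <- setdiff(list.files(out_dir, recursive = TRUE),
                   c("report.yaml", file.path("cache",
                                              list.files(file.path(out_dir, "cache")))))
  manifest <- data.frame(path = files,
                         md5 = unname(tools::md5sum(file.path(out_dir, files))))
  report <- list(
    provenance = list(config_hash = hash_obj(config),
                      seed = config$scenario$seed,
                      stage_hashes = hashes,
                      cached = as.list(cached)),
    scenario = list(source_boxes = as.integer(scenario$source_boxes),
                    bloom_boxes = as.integer(scenario$bloom_boxes),
                    k_bloom = scenario$k_bloom,
                    pilot_mass = scenario$pilot_mass),
    posterior = list(mle = posterior$mle,
                     tie_set = as.integer(posterior$tie_set),
                     no_path = posterior$no_path,
                     recovered = posterior$mle %in% scenario$source_boxes),
    tpt = list(current_into_target = current_into_target(tpt),
               max_outgoing_box_first_quarter = as.integer(which.max(out_cur))),
    elapsed_s = proc.time()[["elapsed"]] - t_all,
    files = manifest)
  yaml::write_yaml(report_to_yaml(report), file.path(out_dir, "report.yaml"))
  structure(c(report, list(out_dir = out_dir)), class = "run_report")
}

report_to_yaml <- function(report) {
  report$files <- Map(function(p, m) list(path = p, md5 = m),
                      report$files$path, report$files$md5)
  names(report$files) <- NULL
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>\n")
  cat(sprintf("  MLE origin box: %s (in source region: %s)\n",
              x$posterior$mle, x$posterior$recovered))
  cat(sprintf("  max outgoing current box (first quarter): %d\n",
              x$tpt$max_outgoing_box_first_quarter))
  cat(sprintf("  %d output files, %.1f s elapsed\n",
              nrow(x$files), x$elapsed_s))
  invisible(x)
}

hash_obj <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeBin(serialize(x, NULL, version = 3), f)
  unname(tools::md5sum(f))
}

validate_config <- function(config) {
  needed <- c("scenario", "ebomb", "chain", "inference")
  missing <- setdiff(needed, names(config))
  if (length(missing))
    stop("config schema error: missing section(s) ",
         paste(missing, collapse = ", "))
  extra <- setdiff(names(config), needed)
  if (length(extra))
    stop("config schema error: unknown section(s) ",
         paste(extra, collapse = ", "))
  ref <- default_config()
  for (s in needed) {
    unknown <- setdiff(names(config[[s]]), names(ref[[s]]))
    if (length(unknown))
      stop("config schema error: unknown key(s) in '", s, "': ",
           paste(unknown, collapse = ", "))
  }
  eb <- config$ebomb; ch <- config$chain
  if (eb$alpha < 0 || eb$alpha >= 1) stop("config: alpha must be in [0, 1)")
  if (eb$tau_s < 0) stop("config: tau_s must be >= 0")
  if (ch$box_size_m <= 0) stop("config: box_size_m must be > 0")
  if (ch$K < 2) stop("config: K must be >= 2")
  invisible(config)
}

#' Write the documented toy-chain fixtures
#'
#' Materializes, in the chain serialization format, the small chains
#' used across examples and tests: `hit3` (the three-state hitting
#' chain: state 1 moves surely to state 2, state 2 reaches the
#' absorbing state 3 with probability 1/2 per step) and three random
#' five-state chains `rand5_seed<k>` with fixed seeds.  A top-level
#' `manifest.yaml` lists every file written.
#'
#' @param dir output directory.
#' @return The directory, invisibly.
#' @export
make_fixtures <- function(dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (file.access(dir, 2) != 0) stop("cannot write to ", dir)
  write_chain(hit3_chain(), file.path(dir, "hit3"))
  for (s in 1:3)
    write_chain(random_chain(5, 6, seed = s),
                file.path(dir, sprintf("rand5_seed%d", s)))
  files <- list.files(dir, recursive = TRUE)
  files <- setdiff(files, "manifest.yaml")
  yaml::write_yaml(list(files = as.list(sort(files))),
                   file.path(dir, "manifest.yaml"))
  invisible(dir)
}

#' The three-state hitting toy chain
#'
#' States {1, 2, 3} plus nirvana; 1 -> 2 surely, 2 -> 3 with
#' probability 1/2 (else stays), 3 absorbing; uniform nirvana inflow.
#' Starting from state 1 the first-hitting pmf of {3} is
#' (0, 0, 1/2, 1/4, ...); from state 2 it is (0, 1/2, 1/4, ...).
#'
#' @param K number of chain times (default 8).
#' @return A [bloom_chain()] over 4 states.
#' @export
hit3_chain <- function(K = 8L) {
  P <- Matrix::sparseMatrix(
    i = c(1, 2, 2, 3, 4, 4, 4),
    j = c(2, 2, 3, 3, 1, 2, 3),
    x = c(1, 0.5, 0.5, 1, 1 / 3, 1 / 3, 1 / 3),
    dims = c(4, 4))
  bloom_chain(rep(list(P), K - 1), times = seq_len(K) - 1)
}

#' Random time-inhomogeneous stochastic chain
#'
#' Independent uniform entries, rows normalized — a generic strictly
#' positive chain for property tests and fixtures.  Deterministic in
#' the seed; the global RNG state is left untouched.
#'
#' @param n_states total number of states (including the last one,
#'   playing the nirvana role).
#' @param K number of chain times.
#' @param seed integer seed.
#' @return A [bloom_chain()].
#' @export
random_chain <- function(n_states, K, seed = 1L) {
  P <- with_seed(seed, lapply(seq_len(K - 1), function(k) {
    M <- matrix(stats::runif(n_states^2), n_states, n_states)
    Matrix::Matrix(M / rowSums(M), sparse = TRUE)
  }))
  bloom_chain(P, times = seq_len(K) - 1)
}
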