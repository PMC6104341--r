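#' Simulation configuration for synthetic creep curves
#'
#' Defines the generative settings for one group of synthetic constant-stress
#' creep curves: model, true parameters, the time grid (default the 120-s
#' hold sampled at 1 Hz used in the compression-rig protocol), additive
#' Gaussian strain noise, replicate count, and the between-replicate
#' parameter spread.
#'
#' @param model_id model identifier, see \code{\link{creep_model}}.
#' @param true_params named numeric vector of generating parameters.
#' @param t_max hold duration in seconds (default 120).
#' @param sample_rate sampling rate in Hz (default 1).
#' @param noise_sd SD of additive i.i.d. Gaussian strain noise (default
#'   0.002, an instrument-scale value giving post-fit residual errors of
#'   order 1e-4 to 1e-3).
#' @param n_replicates replicates per group (default 9).
#' @param replicate_param_cv between-replicate coefficient of variation on
#'   the true parameters (lognormal, mean-preserving; default 0.1),
#'   emulating biological spread between cooked-sample scoops.
#' @param seed integer RNG seed; identical (config, seed) give identical
#'   output.
#' @param group_label optional label attached to generated curves.
#' @return list of class \code{"sim_config"}.
#' @export
sim_config <- function(model_id, true_params, t_max = 120, sample_rate = 1,
                       noise_sd = 0.002, n_replicates = 9L,
                       replicate_param_cv = 0.1, seed = 1L,
                       group_label = NULL) {
  spec <- creep_model(model_id)
  true_params <- .check_params(spec, true_params)
  stopifnot(t_max > 0, sample_rate > 0, noise_sd >= 0, n_replicates >= 1,
            replicate_param_cv >= 0)
  structure(list(model_id = model_id, true_params = true_params,
                 t_max = t_max, sample_rate = sample_rate,
                 noise_sd = noise_sd, n_replicates = as.integer(n_replicates),
                 replicate_param_cv = replicate_param_cv,
                 seed = as.integer(seed), group_label = group_label),
            class = "sim_config")
}

.sim_grid <- function(config) seq(0, config$t_max, by = 1 / config$sample_rate)

# forward model + noise, using whatever RNG state is current
.simulate_curve_raw <- function(config, params = config$true_params) {
  spec <- creep_model(config$model_id)
  t <- .sim_grid(config)
  eps <- creep_strain(spec, params, t)
  if (config$noise_sd > 0)
    eps <- pmax(eps + stats::rnorm(length(t), 0, config$noise_sd), 0)
  creep_curve(t, eps, group = config$group_label,
              metadata = list(truth = list(model_id = config$model_id,
                                           params = as.list(params)),
                              noise_sd = config$noise_sd))
}

#' Simulate one noisy creep curve
#'
#' Evaluates the configured model on the configured time grid and adds
#' i.i.d. Gaussian strain noise; negative noisy strains are clipped at 0.
#' The generating truth is recorded in the curve metadata for recovery
#' tests.
#'
#' @param config a \code{\link{sim_config}}.
#' @return a \code{\link{creep_curve}}.
#' @export
simulate_curve <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  .simulate_curve_raw(config)
}

#' Simulate a replicate set
#'
#' For each replicate the true parameters are jittered lognormally with the
#' configured coefficient of variation (mean-preserving), then a noisy curve
#' is drawn. One RNG stream seeded from \code{config$seed} drives the whole
#' set, so a full replicate set is reproducible from the seed.
#'
#' @param config a \code{\link{sim_config}} with \code{n_replicates >= 1}.
#' @return list of \code{\link{creep_curve}} objects; each records its own
#'   jittered truth.
#' @export
simulate_replicates <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  cv <- config$replicate_param_cv
  sdlog <- sqrt(log(1 + cv^2))
  lapply(seq_len(config$n_replicates), function(i) {
    p <- config$true_params
    if (cv > 0)
      p <- p * stats::rlnorm(length(p), meanlog = -sdlog^2 / 2, sdlog = sdlog)
    cv_curve <- .simulate_curve_raw(config, p)
    cv_curve$metadata$replicate <- i
    cv_curve
  })
}

#' Reference rice fixture curves
#'
#' Three noiseless creep curves of the three-parameter power-law model on a
#' 0-120 s, 1 Hz grid, parameterized from published replicate-mean values
#' for cooked white, brown and germinated brown jasmine rice:
#' \eqn{(k_1, k_2, n)} = (41.88, 6.24, 0.59), (35.00, 7.07, 0.60) and
#' (41.60, 6.76, 0.65) respectively. The initial strain is not published, so
#' a documented fixed \eqn{\varepsilon_0 = 0.6} is assumed; parameter-recovery
#' checks therefore target \eqn{k_1, k_2, n} only.
#'
#' @param eps0 assumed initial strain (default 0.6).
#' @return named list of three noiseless \code{\link{creep_curve}} objects
#'   (\code{white}, \code{brown}, \code{germinated}), truth in metadata.
#' @export
rice_fixtures <- function(eps0 = 0.6) {
  truths <- list(
    white = c(eps0 = eps0, k1 = 41.88, k2 = 6.24, n = 0.59),
    brown = c(eps0 = eps0, k1 = 35.00, k2 = 7.07, n = 0.60),
    germinated = c(eps0 = eps0, k1 = 41.60, k2 = 6.76, n = 0.65)
  )
  lapply(names(truths), function(g) {
    cfg <- sim_config("powerlaw", truths[[g]], noise_sd = 0, group_label = g)
    .simulate_curve_raw(cfg)
  }) |> stats::setNames(names(truths))
}
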