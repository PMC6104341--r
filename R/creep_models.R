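#' Creep model specification
#'
#' Constructs a model specification for one of the three constant-stress creep
#' models handled by this package:
#'
#' \describe{
#'   \item{\code{"peleg"}}{Two-parameter hyperbolic model
#'     \eqn{\varepsilon(t) = t / (k_1 + k_2 t)}. \eqn{k_1} is the degree of
#'     solidity (governs the initial creep rate), \eqn{1/k_2} the asymptotic
#'     strain.}
#'   \item{\code{"purkayastha"}}{Four-parameter model
#'     \eqn{Y(t) = k_0 + k_1 t + t / (k_2 + k_3 t)}: instantaneous term
#'     \eqn{k_0}, steady-state flow \eqn{k_1 t}, and a retarded hyperbolic
#'     term. Fitted to strain traces, \eqn{Y(t)} is read as \eqn{\varepsilon(t)}.}
#'   \item{\code{"powerlaw"}}{Three-parameter power-law creep model
#'     \eqn{\varepsilon(t) = \varepsilon_0 (1 + t^n / (k_1 + k_2 t^n))}, for
#'     non-linear (large-deformation) viscoelasticity. \eqn{\varepsilon_0} is
#'     the initial strain at load application, \eqn{k_1} the degree of solidity
#'     (units \eqn{s^n}), \eqn{1/k_2} sets the relative asymptotic creep
#'     (\eqn{\varepsilon(\infty) = \varepsilon_0 (1 + 1/k_2)}), and the rate
#'     exponent \eqn{n > 0} controls how fast the equilibrium strain is
#'     approached without affecting its value.}
#' }
#'
#' All parameters are constrained strictly positive, except the Purkayastha
#' steady-flow coefficient \eqn{k_1}, which may be zero.
#'
#' @param model_id one of \code{"peleg"}, \code{"purkayastha"},
#'   \code{"powerlaw"}.
#' @param fixed optional named numeric vector of parameters held constant
#'   during fitting, e.g. \code{c(eps0 = 0.6)}.
#' @return an object of class \code{"creep_model"} with elements
#'   \code{model_id}, \code{param_names}, \code{lower}, \code{lower_open}
#'   and \code{fixed}.
#' @examples
#' m <- creep_model("powerlaw", fixed = c(eps0 = 0.6))
#' creep_strain(m, c(eps0 = 0.6, k1 = 41.88, k2 = 6.24, n = 0.59), 0:120)[1:5]
#' @export
creep_model <- function(model_id, fixed = NULL) {
  model_id <- match.arg(model_id, c("peleg", "purkayastha", "powerlaw"))
  pn <- switch(model_id,
    peleg = c("k1", "k2"),
    purkayastha = c("k0", "k1", "k2", "k3"),
    powerlaw = c("eps0", "k1", "k2", "n")
  )
  lower <- rep(0, length(pn))
  names(lower) <- pn
  # open bound (> 0) everywhere except purkayastha k1, which may sit at 0
  lower_open <- rep(TRUE, length(pn))
  names(lower_open) <- pn
  if (model_id == "purkayastha") lower_open["k1"] <- FALSE
  if (!is.null(fixed)) {
    if (is.null(names(fixed)) || !all(names(fixed) %in% pn))
      stop("'fixed' must be a named vector of parameters of the ", model_id,
           " model", call. = FALSE)
    fixed <- fixed[intersect(pn, names(fixed))]
  }
  structure(
    list(model_id = model_id, param_names = pn, lower = lower,
         lower_open = lower_open, fixed = fixed),
    class = "creep_model"
  )
}

#' @export
print.creep_model <- function(x, ...) {
  cat("Creep model:", x$model_id, "\n")
  cat("  parameters:", paste(x$param_names, collapse = ", "), "\n")
  if (length(x$fixed))
    cat("  fixed:", paste(names(x$fixed), "=", x$fixed, collapse = ", "), "\n")
  invisible(x)
}

.check_params <- function(spec, params) {
  pn <- spec$param_names
  if (length(params) != length(pn))
    stop("expected ", length(pn), " parameters (", paste(pn, collapse = ", "),
         "), got ", length(params), call. = FALSE)
  if (is.null(names(params))) names(params) <- pn
  params <- params[pn]
  if (anyNA(params) || any(!is.finite(params)))
    stop("non-finite parameter value", call. = FALSE)
  bad <- ifelse(spec$lower_open, params <= spec$lower, params < spec$lower)
  if (any(bad))
    stop("parameter(s) out of bounds (must be positive): ",
         paste(pn[bad], collapse = ", "), call. = FALSE)
  params
}

.check_times <- function(times) {
  if (!is.numeric(times) || anyNA(times) || any(!is.finite(times)))
    stop("'times' must be finite numeric", call. = FALSE)
  if (any(times < 0)) stop("'times' must be non-negative", call. = FALSE)
  if (is.unsorted(times)) stop("'times' must be sorted increasing", call. = FALSE)
  times
}

# t^n with the t = 0, n < 1 limit defined as 0 (avoids NaN at the grid origin)
.tpow <- function(t, n) ifelse(t > 0, t^n, 0)

#' Evaluate a creep model
#'
#' Computes the model strain (or compliance, for the Purkayastha model read in
#' compliance units) on a grid of retardation times under constant stress.
#'
#' @param spec a \code{\link{creep_model}}.
#' @param params numeric parameter vector in the order of
#'   \code{spec$param_names} (names optional).
#' @param times non-negative, sorted numeric vector of times (seconds).
#' @return numeric vector of strains, one per time point.
#' @export
creep_strain <- function(spec, params, times) {
  params <- .check_params(spec, params)
  t <- .check_times(times)
  switch(spec$model_id,
    peleg = {
      k1 <- params[["k1"]]; k2 <- params[["k2"]]
      ifelse(t > 0, t / (k1 + k2 * t), 0)
    },
    purkayastha = {
      k0 <- params[["k0"]]; k1 <- params[["k1"]]
      k2 <- params[["k2"]]; k3 <- params[["k3"]]
      k0 + k1 * t + t / (k2 + k3 * t)
    },
    powerlaw = {
      e0 <- params[["eps0"]]; k1 <- params[["k1"]]
      k2 <- params[["k2"]]; n <- params[["n"]]
      u <- .tpow(t, n)
      # u/(k1 + k2 u) -> 1/k2 as u overflows
      e0 * (1 + ifelse(is.finite(u), u / (k1 + k2 * u), 1 / k2))
    }
  )
}

#' Analytic Jacobian of a creep model
#'
#' Partial derivatives of the model strain with respect to each parameter,
#' one row per time point, one column per parameter (in
#' \code{spec$param_names} order). At \eqn{t = 0} the power-law exponent
#' column is the limit 0 of \eqn{t^n \log t}.
#'
#' @inheritParams creep_strain
#' @return numeric matrix, \code{length(times)} rows, one column per parameter.
#' @export
creep_jacobian <- function(spec, params, times) {
  params <- .check_params(spec, params)
  t <- .check_times(times)
  J <- switch(spec$model_id,
    peleg = {
      k1 <- params[["k1"]]; k2 <- params[["k2"]]
      d <- (k1 + k2 * t)^2
      cbind(k1 = ifelse(t > 0, -t / d, 0),
            k2 = ifelse(t > 0, -t^2 / d, 0))
    },
    purkayastha = {
      k2 <- params[["k2"]]; k3 <- params[["k3"]]
      d <- (k2 + k3 * t)^2
      cbind(k0 = rep(1, length(t)), k1 = t, k2 = -t / d, k3 = -t^2 / d)
    },
    powerlaw = {
      e0 <- params[["eps0"]]; k1 <- params[["k1"]]
      k2 <- params[["k2"]]; n <- params[["n"]]
      u <- .tpow(t, n)
      D <- k1 + k2 * u
      # q = u/D -> 1/k2 as u overflows; derivative columns written in terms
      # of q so extreme parameter values stay finite
      q <- ifelse(is.finite(u), u / D, 1 / k2)
      qD <- ifelse(is.finite(u), q / D, 0)        # u/D^2
      logt <- ifelse(t > 0, log(t), 0)
      cbind(eps0 = 1 + q,
            k1 = -e0 * qD,
            k2 = -e0 * q^2,
            n = e0 * k1 * logt * qD)
    }
  )
  rownames(J) <- NULL
  J
}

#' Derived rheological quantities
#'
#' Initial strain, asymptotic (equilibrium) strain, initial modulus of
#' elasticity \eqn{E_0 = \sigma_0 / \varepsilon_0}, and the degree of solidity
#' \eqn{k_1} (model-specific meaning). For the Peleg model the initial strain
#' is 0, so the initial modulus is infinite; for the Purkayastha model a
#' positive steady-flow coefficient \eqn{k_1} makes the asymptotic strain
#' infinite (unbounded viscous flow).
#'
#' @inheritParams creep_strain
#' @param stress constant applied stress \eqn{\sigma_0} in Pa (optional;
#'   required for the initial modulus).
#' @return list with \code{initial_strain}, \code{asymptotic_strain},
#'   \code{initial_modulus} (NA when no stress given) and \code{solidity}.
#' @export
creep_derived <- function(spec, params, stress = NULL) {
  params <- .check_params(spec, params)
  if (!is.null(stress)) {
    if (!is.numeric(stress) || length(stress) != 1 || !is.finite(stress) ||
        stress <= 0)
      stop("'stress' must be a single positive number (Pa)", call. = FALSE)
  }
  out <- switch(spec$model_id,
    peleg = list(initial_strain = 0,
                 asymptotic_strain = 1 / params[["k2"]],
                 solidity = params[["k1"]]),
    purkayastha = list(
      initial_strain = params[["k0"]],
      asymptotic_strain = if (params[["k1"]] > 0) Inf else
        params[["k0"]] + 1 / params[["k3"]],
      solidity = params[["k2"]]),
    powerlaw = list(
      initial_strain = params[["eps0"]],
      asymptotic_strain = params[["eps0"]] * (1 + 1 / params[["k2"]]),
      solidity = params[["k1"]])
  )
  out$initial_modulus <- if (is.null(stress)) NA_real_ else
    stress / out$initial_strain
  out[c("initial_strain", "asymptotic_strain", "initial_modulus", "solidity")]
}
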