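#' Gauss-Newton fit control options
#'
#' @param max_iter maximum number of Gauss-Newton iterations.
#' @param rel_obj_tol convergence tolerance on the relative change of the
#'   residual sum of squares S.
#' @param rel_step_tol convergence tolerance on the largest relative parameter
#'   update.
#' @param max_halvings maximum number of step-halvings per iteration; halving
#'   is applied when a candidate update increases S or leaves the positive
#'   orthant.
#' @param scale logical; scale Jacobian columns by the current parameter
#'   magnitudes (unit-free steps, needed when parameters span many orders of
#'   magnitude, as in the four-parameter model).
#' @return list of class \code{"gn_control"}.
#' @export
gn_control <- function(max_iter = 200L, rel_obj_tol = 1e-12,
                       rel_step_tol = 1e-8, max_halvings = 20L,
                       scale = TRUE) {
  stopifnot(max_iter >= 1, rel_obj_tol > 0, rel_step_tol > 0,
            max_halvings >= 0)
  structure(list(max_iter = as.integer(max_iter), rel_obj_tol = rel_obj_tol,
                 rel_step_tol = rel_step_tol,
                 max_halvings = as.integer(max_halvings), scale = scale),
            class = "gn_control")
}

#' One Gauss-Newton step from the normal equations
#'
#' Solves \eqn{(Z^T Z)\lambda = -Z^T r} for the parameter update
#' \eqn{\lambda}, where \eqn{Z} is the Jacobian and \eqn{r} the residual
#' vector (model minus observation). The solve goes through a QR
#' factorization of \eqn{Z}, which solves the normal equations without
#' forming or inverting \eqn{Z^T Z}.
#'
#' @param Z numeric Jacobian matrix, one row per observation, one column per
#'   free parameter; must have full column rank.
#' @param r numeric residual vector, \code{nrow(Z)} long.
#' @return the update vector \eqn{\lambda}, named after \code{colnames(Z)}.
#' @export
gn_step <- function(Z, r) {
  Z <- as.matrix(Z)
  if (nrow(Z) < ncol(Z))
    stop("fewer observations than free parameters", call. = FALSE)
  if (length(r) != nrow(Z))
    stop("residual length does not match Jacobian rows", call. = FALSE)
  qz <- qr(Z)
  if (qz$rank < ncol(Z)) {
    dg <- abs(diag(qr.R(qz)))
    bad <- qz$pivot[which(dg <= max(dg) * 1e-10 | dg == 0)]
    nm <- if (!is.null(colnames(Z))) colnames(Z)[bad] else as.character(bad)
    stop("singular normal equations; degenerate parameter(s): ",
         paste(nm, collapse = ", "), call. = FALSE)
  }
  lambda <- qr.coef(qz, -r)
  names(lambda) <- colnames(Z)
  lambda
}

# residuals used inside the iteration are fitted - observed, so that
# beta + gn_step(Z, r) is the descent update; reported residuals follow the
# observed - fitted convention.
.objective <- function(spec, params, t, y) {
  f <- creep_strain(spec, params, t)
  sum((y - f)^2)
}

.feasible <- function(spec, params) {
  all(ifelse(spec$lower_open, params > spec$lower, params >= spec$lower))
}

#' Fit a creep model by Gauss-Newton least squares
#'
#' Iterates Jacobian / residual / normal-equation updates until the relative
#' change in the residual sum of squares or the largest relative parameter
#' step falls below tolerance. A candidate update that increases S, or leaves
#' the positive orthant, is halved (up to \code{control$max_halvings} times)
#' before being accepted, so S is non-increasing across accepted iterations.
#' Parameters named in \code{spec$fixed} are held constant and excluded from
#' the update.
#'
#' For the Peleg model the \eqn{t = 0} sample is excluded (the model is
#' identically zero there and the linearized form \eqn{t/\varepsilon} is
#' undefined at the origin).
#'
#' @param curve a \code{\link{creep_curve}}.
#' @param spec a \code{\link{creep_model}} (a model id string is also
#'   accepted).
#' @param init optional named initial parameter vector; defaults to
#'   \code{\link{creep_init}}.
#' @param control a \code{\link{gn_control}} list.
#' @return object of class \code{"creep_fit"}: \code{params} (full vector,
#'   fixed values merged back), \code{se} (asymptotic standard errors of the
#'   free parameters), \code{residuals} (observed - fitted), \code{sum_sq},
#'   \code{rse}, \code{r_squared}, \code{n_iter}, \code{converged},
#'   \code{model_id}, \code{fitted}, and for the Peleg model the
#'   linearized-space statistics \code{linearized} (see
#'   \code{\link{fit_peleg_linear}}).
#' @export
creep_fit <- function(curve, spec, init = NULL, control = gn_control()) {
  if (is.character(spec)) spec <- creep_model(spec)
  stopifnot(inherits(curve, "creep_curve"), inherits(spec, "creep_model"))
  t <- curve$time; y <- curve$strain
  if (spec$model_id == "peleg") {
    keep <- t > 0
    t <- t[keep]; y <- y[keep]
  }
  pn <- spec$param_names
  if (is.null(init)) init <- creep_init(spec, curve)
  init <- .check_params(spec, init)
  free <- setdiff(pn, names(spec$fixed))
  if (length(spec$fixed)) init[names(spec$fixed)] <- spec$fixed
  if (length(t) < length(free) + 1)
    stop("need at least ", length(free) + 1, " time points", call. = FALSE)

  beta <- init
  S <- .objective(spec, beta, t, y)
  s_path <- S  # objective after each accepted iteration; non-increasing
  converged <- FALSE
  iter <- 0L
  while (iter < control$max_iter) {
    iter <- iter + 1L
    r <- creep_strain(spec, beta, t) - y
    Z <- creep_jacobian(spec, beta, t)[, free, drop = FALSE]
    s <- if (control$scale) pmax(abs(beta[free]), 1e-10) else
      rep(1, length(free))
    lambda <- tryCatch(
      s * gn_step(sweep(Z, 2, s, `*`), r),
      error = function(e) stop("iteration ", iter, ": ", conditionMessage(e),
                               call. = FALSE))
    # step-halving: back into the feasible region, then until S decreases
    alpha <- 1
    accepted <- FALSE
    for (h in 0:control$max_halvings) {
      cand <- beta
      cand[free] <- beta[free] + alpha * lambda
      if (.feasible(spec, cand)) {
        S_new <- .objective(spec, cand, t, y)
        # non-finite objective (e.g. overflow at an extreme candidate) is
        # treated like an ascent step and halved away
        if (is.finite(S_new) && S_new <= S) {
          accepted <- TRUE
          break
        }
      }
      alpha <- alpha / 2
    }
    if (!accepted) {
      # no descent step found; at a (numerical) optimum when the proposed
      # full step is already negligible
      converged <- max(abs(lambda) / pmax(abs(beta[free]), 1e-10)) <
        control$rel_step_tol
      break
    }
    rel_step <- max(abs(alpha * lambda) / pmax(abs(beta[free]), 1e-10))
    dS <- S - S_new
    beta <- cand
    S <- S_new
    s_path <- c(s_path, S)
    if (dS / max(S, 1e-30) < control$rel_obj_tol ||
        rel_step < control$rel_step_tol) {
      converged <- TRUE
      break
    }
  }

  fitted <- creep_strain(spec, beta, t)
  res <- y - fitted
  p <- length(free)
  se <- rep(NA_real_, p)
  names(se) <- free
  if (length(t) > p) {
    Z <- creep_jacobian(spec, beta, t)[, free, drop = FALSE]
    qz <- qr(Z)
    if (qz$rank == p) {
      R <- qr.R(qz)
      XtXinv <- chol2inv(R)[order(qz$pivot), order(qz$pivot), drop = FALSE]
      se <- sqrt(pmax(diag(XtXinv), 0) * S / (length(t) - p))
      names(se) <- free
    }
  }
  out <- structure(list(
    model_id = spec$model_id, params = beta, free = free, se = se,
    residuals = res, fitted = fitted, time = t, sum_sq = S,
    rse = residual_standard_error(res, p),
    r_squared = r_squared(y, fitted),
    n_iter = iter, converged = converged, init = init, s_path = s_path
  ), class = "creep_fit")
  if (spec$model_id == "peleg")
    out$linearized <- tryCatch(fit_peleg_linear(curve),
                               error = function(e) NULL)
  out
}

#' @export
print.creep_fit <- function(x, digits = 4, ...) {
  cat("Creep model fit (", x$model_id, "), Gauss-Newton\n", sep = "")
  est <- format(signif(x$params, digits))
  se <- rep("(fixed)", length(x$params))
  se[match(x$free, names(x$params))] <-
    paste0("+/- ", format(signif(x$se, digits)))
  cat(paste0("  ", format(names(x$params), width = 5), " = ", est, "  ", se,
             collapse = "\n"), "\n")
  cat("  R-squared:", format(signif(x$r_squared, 6)),
      " RSE:", format(signif(x$rse, 4)),
      " iterations:", x$n_iter,
      if (x$converged) "(converged)" else "(NOT converged)", "\n")
  invisible(x)
}

#' Closed-form linearized Peleg fit
#'
#' The Peleg model \eqn{\varepsilon(t) = t/(k_1 + k_2 t)} is linear after the
#' transformation \eqn{t/\varepsilon(t) = k_1 + k_2 t}: ordinary least squares
#' of \eqn{t/\varepsilon} on \eqn{t} gives the intercept \eqn{k_1} and slope
#' \eqn{k_2} in closed form, no iteration. The \eqn{t = 0} point is excluded
#' (\eqn{t/\varepsilon} is undefined at the origin).
#'
#' @param curve a \code{\link{creep_curve}} with strictly positive strain at
#'   all \eqn{t > 0}.
#' @return list with \code{k1}, \code{k2}, standard errors \code{se} (named),
#'   linearized-space \code{r_squared} and \code{rse}, and
#'   \code{near_singular} (TRUE when the regression degenerates, e.g. a
#'   constant-strain trace driving the intercept to zero).
#' @export
fit_peleg_linear <- function(curve) {
  stopifnot(inherits(curve, "creep_curve"))
  keep <- curve$time > 0
  t <- curve$time[keep]
  eps <- curve$strain[keep]
  if (any(eps <= 0))
    stop("strain must be positive at all t > 0 for the linearized Peleg fit",
         call. = FALSE)
  if (length(t) < 3)
    stop("need at least 3 points with t > 0", call. = FALSE)
  fit <- stats::lm(I(t / eps) ~ t)
  co <- stats::coef(fit)
  sm <- suppressWarnings(summary(fit))  # "essentially perfect fit" on exact data
  k1 <- unname(co[1]); k2 <- unname(co[2])
  # degenerate when the transformed data lie exactly on a line through the
  # origin (constant strain gives t/eps = t/c): zero intercept with an
  # essentially perfect fit. A noisy intercept estimate near zero is not
  # degeneracy.
  near_singular <- !is.finite(k1) || !is.finite(k2) ||
    (k1 <= max(abs(k1), abs(k2)) * 1e-10 &&
       sm$r.squared > 1 - 1e-12)
  if (near_singular)
    warning("near-singular linearized Peleg regression (intercept ~ 0; ",
            "constant-strain or degenerate trace)", call. = FALSE)
  list(k1 = k1, k2 = k2,
       se = c(k1 = unname(sm$coefficients[1, 2]),
              k2 = unname(sm$coefficients[2, 2])),
       r_squared = unname(sm$r.squared), rse = unname(sm$sigma),
       near_singular = near_singular)
}

#' Deterministic initial parameter values
#'
#' Heuristic, deterministic starting values for \code{\link{creep_fit}}:
#' \itemize{
#'   \item power-law: \eqn{\varepsilon_0} from the first strain sample (or the
#'     smallest positive one), \eqn{k_2} from the terminal strain ratio
#'     (clipped to \eqn{[10^{-3}, 10^3]}), \eqn{n = 0.5}, and \eqn{k_1} from
#'     the mid-grid point, clipped positive;
#'   \item peleg: the closed-form linearized OLS solution;
#'   \item purkayastha: \eqn{k_0} from the first strain, \eqn{k_1} from the
#'     terminal slope, \eqn{(k_2, k_3)} from a two-point solve on the
#'     de-trended tail.
#' }
#'
#' @param spec a \code{\link{creep_model}}.
#' @param curve a \code{\link{creep_curve}}; must be non-degenerate
#'   (increasing overall, positive strain range).
#' @return named numeric vector of starting values.
#' @export
creep_init <- function(spec, curve) {
  if (is.character(spec)) spec <- creep_model(spec)
  stopifnot(inherits(curve, "creep_curve"))
  t <- curve$time; eps <- curve$strain
  n_pt <- length(t)
  rng <- max(eps) - min(eps)
  if (rng <= 0)
    stop("flat curve: strain has no range; supply initial values manually",
         call. = FALSE)
  if (eps[n_pt] <= eps[1])
    stop("strain decreases overall; creep curves increase under constant ",
         "stress", call. = FALSE)
  clip <- function(x, lo, hi) min(max(x, lo), hi)
  switch(spec$model_id,
    peleg = {
      lin <- fit_peleg_linear(curve)
      c(k1 = max(lin$k1, 1e-6), k2 = max(lin$k2, 1e-6))
    },
    powerlaw = {
      pos <- eps[eps > 0]
      e0 <- if (eps[1] > 0) eps[1] else min(pos)
      ratio <- eps[n_pt] / e0 - 1
      k2 <- clip(if (ratio > 0) 1 / ratio else 1e3, 1e-3, 1e3)
      n <- 0.5
      i_mid <- which.min(abs(t - (t[1] + t[n_pt]) / 2))
      u_mid <- t[i_mid]^n
      k1 <- if (eps[i_mid] > e0)
        u_mid * (e0 / (eps[i_mid] - e0) - k2) else NA_real_
      if (!is.finite(k1) || k1 <= 0) k1 <- u_mid
      c(eps0 = e0, k1 = k1, k2 = k2, n = n)
    },
    purkayastha = {
      k0 <- max(eps[1], 1e-6)
      # terminal slope over the last ~10% of the grid
      i0 <- max(1, n_pt - max(2, round(n_pt / 10)))
      k1 <- max((eps[n_pt] - eps[i0]) / (t[n_pt] - t[i0]), 0)
      # de-trended tail g(t) = eps - k0 - k1 t ~ t/(k2 + k3 t):
      # t/g is linear in t; two-point solve at mid and end
      g <- eps - k0 - k1 * t
      ok <- which(t > 0 & g > 0)
      if (length(ok) >= 2) {
        ia <- ok[which.min(abs(t[ok] - t[n_pt] / 4))]
        ib <- ok[length(ok)]
        if (ib == ia) ia <- ok[1]
        za <- t[ia] / g[ia]; zb <- t[ib] / g[ib]
        k3 <- (zb - za) / (t[ib] - t[ia])
        k2 <- za - k3 * t[ia]
      } else {
        k2 <- k3 <- NA_real_
      }
      if (!is.finite(k3) || k3 <= 0) k3 <- 1 / max(rng, 1e-6)
      if (!is.finite(k2) || k2 <= 0) k2 <- t[n_pt] / max(rng, 1e-6) / 10
      c(k0 = k0, k1 = k1, k2 = k2, k3 = k3)
    }
  )
}
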