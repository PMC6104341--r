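#' Residual standard error
#'
#' \eqn{RSE = \sqrt{\sum r_j^2 / (N - p)}} with \eqn{p} the number of free
#' parameters.
#'
#' @param residuals numeric residual vector.
#' @param n_params number of free parameters used by the fit.
#' @return the residual standard error.
#' @export
residual_standard_error <- function(residuals, n_params) {
  n <- length(residuals)
  if (n <= n_params)
    stop("no residual degrees of freedom (N <= p)", call. = FALSE)
  sqrt(sum(residuals^2) / (n - n_params))
}

#' Coefficient of determination
#'
#' \eqn{R^2 = 1 - \sum (obs - fit)^2 / \sum (obs - \bar{obs})^2}, computed
#' about the mean (the centred convention; for non-linear fits this can be
#' negative when the model is worse than the mean).
#'
#' @param observed observed values.
#' @param fitted model-fitted values, same length.
#' @return \eqn{R^2}.
#' @export
r_squared <- function(observed, fitted) {
  stopifnot(length(observed) == length(fitted))
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot <= 0)
    stop("constant observed vector: R-squared undefined", call. = FALSE)
  1 - sum((observed - fitted)^2) / ss_tot
}

#' Duncan's multiple range test
#'
#' Post-hoc comparison of group means after a one-way ANOVA. Means are ranked
#' in descending order; two means spanning \eqn{p} ranked positions differ
#' significantly when their difference exceeds the least significant range
#' \deqn{R_p = q^*(\alpha_p, p, df)\,\sqrt{MSE / n_h},}
#' where \eqn{q^*} is the studentized-range quantile at Duncan's protection
#' level \eqn{\alpha_p = 1 - (1-\alpha)^{p-1}}, \eqn{df = N - g} the error
#' degrees of freedom, \eqn{MSE} the ANOVA error mean square and \eqn{n_h}
#' the harmonic mean group size (the groups here are balanced in the usual
#' design; the harmonic mean extends the test to unbalanced ones). Groups
#' sharing a letter are not significantly different. Critical values come
#' from the studentized-range distribution, not from printed tables, so any
#' degrees of freedom are supported.
#'
#' @param values numeric vector of replicate values.
#' @param groups group labels, same length as \code{values}; at least two
#'   groups of at least two replicates each.
#' @param alpha significance level (default 0.05).
#' @return data.frame with one row per group: \code{group}, \code{mean},
#'   \code{n}, \code{letter}; attributes \code{mse}, \code{df}, \code{alpha}.
#'   Letter 'a' is assigned starting from the largest mean.
#' @export
duncan_mrt <- function(values, groups, alpha = 0.05) {
  groups <- factor(groups)
  stopifnot(length(values) == length(groups), alpha > 0, alpha < 1)
  n_i <- tapply(values, groups, length)
  if (nlevels(groups) < 2)
    stop("need at least 2 groups", call. = FALSE)
  if (any(n_i < 2))
    stop("every group needs at least 2 replicates", call. = FALSE)
  # suppress the "essentially perfect fit" chatter: MSE = 0 is a handled case
  aovt <- suppressWarnings(stats::anova(stats::aov(values ~ groups)))
  mse <- aovt["Residuals", "Mean Sq"]
  df <- aovt["Residuals", "Df"]
  means <- tapply(values, groups, mean)
  g <- length(means)
  n_h <- g / sum(1 / n_i)
  ord <- order(means, decreasing = TRUE)
  m <- means[ord]

  # least significant range for a span of p ranked means
  Rp <- vapply(2:g, function(p) {
    alpha_p <- 1 - (1 - alpha)^(p - 1)
    stats::qtukey(1 - alpha_p, p, df) * sqrt(mse / n_h)
  }, numeric(1))
  Rp <- c(NA_real_, Rp)  # index by span size p

  # nonsig[i, j]: the ranked span i..j is homogeneous (range <= R_p), with
  # Duncan's protection: any pair inside a homogeneous span is homogeneous
  nonsig <- diag(TRUE, g)
  for (i in seq_len(g - 1)) for (j in (i + 1):g)
    nonsig[i, j] <- nonsig[j, i] <- (m[i] - m[j]) <= Rp[j - i + 1]
  for (span in g:2) for (i in seq_len(g - span + 1)) {
    j <- i + span - 1
    if (nonsig[i, j]) nonsig[i:j, i:j] <- TRUE
  }

  # maximal homogeneous bars -> letters, in order of descending means
  bars <- list()
  i <- 1
  while (i <= g) {
    j <- i
    while (j < g && nonsig[i, j + 1]) j <- j + 1
    if (length(bars) == 0 || bars[[length(bars)]][2] < j ||
        bars[[length(bars)]][1] > i)
      bars[[length(bars) + 1]] <- c(i, j)
    i <- i + 1
  }
  # drop bars nested inside an earlier bar (can arise when j did not extend)
  keep <- rep(TRUE, length(bars))
  for (b in seq_along(bars)) for (b2 in seq_along(bars)) {
    if (b != b2 && keep[b2] && bars[[b]][1] >= bars[[b2]][1] &&
        bars[[b]][2] <= bars[[b2]][2]) keep[b] <- FALSE
  }
  bars <- bars[keep]
  lett <- rep("", g)
  for (b in seq_along(bars)) {
    idx <- bars[[b]][1]:bars[[b]][2]
    lett[idx] <- paste0(lett[idx], letters[b])
  }

  out <- data.frame(group = names(m), mean = as.numeric(m),
                    n = as.integer(n_i[ord]), letter = lett,
                    stringsAsFactors = FALSE, row.names = NULL)
  out <- out[match(levels(groups), out$group), ]
  rownames(out) <- NULL
  attr(out, "mse") <- mse
  attr(out, "df") <- df
  attr(out, "alpha") <- alpha
  out
}

#' Aggregate replicate fits into a group summary table
#'
#' Per-group parameter means and standard deviations over replicate fits,
#' with Duncan's-test significance letters computed across groups for each
#' parameter separately (one pooled ANOVA error mean square per parameter).
#' This is the usual replicate-summary table of a creep study: rows are
#' sample groups, columns are model parameters as "mean +/- SD letter",
#' plus mean goodness-of-fit.
#'
#' @param fits list of \code{\link{creep_fit}} objects, all from the same
#'   model.
#' @param groups group label per fit.
#' @param alpha significance level for the letters.
#' @return object of class \code{"creep_group_summary"}: a list with
#'   \code{model_id}, \code{table} (data.frame group x statistic), and the
#'   per-parameter Duncan results in \code{dmrt}.
#' @export
aggregate_replicates <- function(fits, groups, alpha = 0.05) {
  stopifnot(length(fits) == length(groups), length(fits) >= 1)
  ids <- vapply(fits, function(f) f$model_id, character(1))
  if (length(unique(ids)) != 1)
    stop("all fits in a summary must use the same model; got: ",
         paste(unique(ids), collapse = ", "), call. = FALSE)
  groups <- factor(groups)
  pn <- names(fits[[1]]$params)
  P <- t(vapply(fits, function(f) f$params, numeric(length(pn))))
  colnames(P) <- pn
  glev <- levels(groups)
  tab <- data.frame(group = glev,
                    n_replicates = as.integer(table(groups)[glev]),
                    stringsAsFactors = FALSE)
  dmrt <- list()
  for (p in pn) {
    tab[[paste0(p, "_mean")]] <- as.numeric(tapply(P[, p], groups, mean)[glev])
    tab[[paste0(p, "_sd")]] <- as.numeric(tapply(P[, p], groups,
                                                 stats::sd)[glev])
    if (length(glev) >= 2 && all(table(groups) >= 2) &&
        stats::var(P[, p]) > 0) {
      d <- duncan_mrt(P[, p], groups, alpha)
      dmrt[[p]] <- d
      tab[[paste0(p, "_letter")]] <- d$letter[match(glev, d$group)]
    } else {
      tab[[paste0(p, "_letter")]] <- rep("a", length(glev))
    }
  }
  tab$r_squared <- as.numeric(tapply(vapply(fits, `[[`, 1, "r_squared"),
                                     groups, mean)[glev])
  tab$rse <- as.numeric(tapply(vapply(fits, `[[`, 1, "rse"),
                               groups, mean)[glev])
  structure(list(model_id = ids[1], table = tab, dmrt = dmrt, alpha = alpha),
            class = "creep_group_summary")
}

#' @export
print.creep_group_summary <- function(x, digits = 4, ...) {
  cat("Replicate summary, model:", x$model_id, "\n")
  pn <- sub("_mean$", "", grep("_mean$", names(x$table), value = TRUE))
  disp <- data.frame(group = x$table$group, n = x$table$n_replicates)
  for (p in pn)
    disp[[p]] <- paste0(signif(x$table[[paste0(p, "_mean")]], digits), " +/- ",
                        signif(x$table[[paste0(p, "_sd")]], digits), " ",
                        x$table[[paste0(p, "_letter")]])
  disp$R2 <- signif(x$table$r_squared, 6)
  disp$RSE <- signif(x$table$rse, 3)
  print(disp, row.names = FALSE)
  cat("Means sharing a letter (per column) are not significantly different",
      "(Duncan, alpha =", x$alpha, ")\n")
  invisible(x)
}

#' Write a group summary as a delimited table
#'
#' @param summary a \code{\link{aggregate_replicates}} result.
#' @param path output file; tab-separated.
#' @return the path, invisibly.
#' @export
write_group_report <- function(summary, path) {
  stopifnot(inherits(summary, "creep_group_summary"))
  utils::write.table(summary$table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
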