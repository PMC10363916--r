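#' Observation vector of per-trait, per-database effect summaries
#'
#' One observation per trait x database combination: a log odds ratio or
#' an AUC, with its standard error. Observations must be ordered
#' database-major (all traits of database 1, then all traits of database
#' 2, ...), matching the Kronecker product ordering of
#' [kronecker_correlation()].
#'
#' @param b numeric values (log-OR or AUC), length m.
#' @param se nonnegative standard errors, length m.
#' @param trait,database labels of length m.
#' @return Object of class `observation_vector` (a data.frame).
#' @export
observation_vector <- function(b, se, trait, database) {
  m <- length(b)
  if (length(se) != m || length(trait) != m || length(database) != m) {
    stop_config("b, se, trait, database must have equal length")
  }
  if (any(!is.finite(b)) || any(!is.finite(se)) || any(se < 0)) {
    stop_config("b must be finite and se finite nonnegative")
  }
  out <- data.frame(b = b, se = se, trait = as.character(trait),
                    database = as.character(database), stringsAsFactors = FALSE)
  # database-major: database changes slowest
  if (is.unsorted(match(out$database, unique(out$database)))) {
    stop_config("observations must be ordered database-major")
  }
  class(out) <- c("observation_vector", class(out))
  out
}

#' Kronecker-structured correlation across databases and traits
#'
#' Builds the m x m correlation matrix of trait-by-database observations
#' as the Kronecker product of the database correlation matrix and the
#' trait correlation matrix, in database-major order (database block
#' structure, traits within blocks).
#'
#' @param R_db database correlation matrix (d x d).
#' @param R_trait trait correlation matrix (t x t).
#' @return (d*t) x (d*t) correlation matrix.
#' @export
kronecker_correlation <- function(R_db, R_trait) {
  check_correlation_matrix(R_db, "database correlation matrix")
  check_correlation_matrix(R_trait, "trait correlation matrix")
  m <- nrow(R_db) * nrow(R_trait)
  if (m > 20000) stop_config("Kronecker dimension %d too large", m)
  kronecker(R_db, R_trait)
}

#' Overall estimate across traits and databases
#'
#' The unweighted mean of the m observations (the "overall" log-OR or
#' AUC; exponentiate a log-OR mean to report an overall OR).
#'
#' @param obs an [observation_vector()].
#' @return Scalar mean.
#' @export
overall_estimate <- function(obs) {
  if (nrow(obs) == 0L) stop_config("empty observation vector")
  mean(obs$b)
}

#' Correlation-aware variance of the overall estimate
#'
#' \eqn{var(\bar b) = 1' S R S 1 / m^2} with S the diagonal matrix of
#' standard errors and R the observation correlation matrix (typically
#' from [kronecker_correlation()]). A correlation matrix that fails
#' positive semi-definiteness within tolerance is projected to the
#' nearest PSD correlation matrix with a warning.
#'
#' @param obs an [observation_vector()].
#' @param R m x m observation correlation matrix.
#' @return Nonnegative scalar variance, attribute `projected` if the PSD
#'   repair fired.
#' @export
overall_variance <- function(obs, R) {
  m <- nrow(obs)
  if (!is.matrix(R) || nrow(R) != m || ncol(R) != m) {
    stop_config("R must be %d x %d", m, m)
  }
  projected <- FALSE
  ev <- eigen((R + t(R)) / 2, symmetric = TRUE)
  if (min(ev$values) < -1e-8) {
    warning("correlation matrix not PSD; nearest-PSD projection applied")
    V <- ev$vectors %*% diag(pmax(ev$values, 0)) %*% t(ev$vectors)
    D <- 1 / sqrt(diag(V))
    R <- V * tcrossprod(D)
    projected <- TRUE
  }
  v <- as.numeric(t(obs$se) %*% R %*% obs$se) / m^2
  structure(max(v, 0), projected = projected)
}

#' Difference test between two methods' overall estimates
#'
#' \eqn{var(\bar b_1 - \bar b_2) = var(\bar b_1) + var(\bar b_2) -
#' 2 cov(\bar b_1, \bar b_2)} with
#' \eqn{cov \approx r \cdot 1' S_1 R S_2 1 / m^2}, where r is the
#' empirical Pearson correlation between the paired observations. The
#' two-sided p-value uses the normal approximation.
#'
#' @param obs1,obs2 [observation_vector()]s in identical (trait,
#'   database) order, m >= 3.
#' @param R m x m observation correlation matrix.
#' @return List with `diff`, `z`, `p`, `var_diff`, `r_empirical`.
#' @export
difference_test <- function(obs1, obs2, R) {
  m <- nrow(obs1)
  if (nrow(obs2) != m) stop_config("observation vectors differ in length")
  if (m < 3L) stop_config("need m >= 3 for the empirical correlation")
  if (!identical(obs1$trait, obs2$trait) || !identical(obs1$database, obs2$database)) {
    stop_config("observation vectors must share the same (trait, database) index order")
  }
  ok <- complete.cases(obs1$b, obs2$b)
  r_emp <- cor(obs1$b[ok], obs2$b[ok])
  if (!is.finite(r_emp)) r_emp <- 0  # degenerate constant vectors
  v1 <- as.numeric(overall_variance(obs1, R))
  v2 <- as.numeric(overall_variance(obs2, R))
  cov12 <- r_emp * as.numeric(t(obs1$se) %*% R %*% obs2$se) / m^2
  var_diff <- v1 + v2 - 2 * cov12
  d <- overall_estimate(obs1) - overall_estimate(obs2)
  if (d == 0 && var_diff <= 0) {
    # identical inputs: difference exactly zero
    return(list(diff = 0, z = 0, p = 1, var_diff = max(var_diff, 0),
                r_empirical = r_emp))
  }
  if (var_diff <= 0) {
    stop_config(paste0("approximated variance of the difference is nonpositive ",
                       "(v1=%g, v2=%g, cov=%g, r=%g)"), v1, v2, cov12, r_emp)
  }
  z <- d / sqrt(var_diff)
  list(diff = d, z = z, p = 2 * pnorm(-abs(z)), var_diff = var_diff,
       r_empirical = r_emp)
}

#' Aggregate an observation vector into an overall estimate
#'
#' Convenience wrapper combining [overall_estimate()],
#' [kronecker_correlation()] and [overall_variance()], returning a classed
#' result with a confidence interval (on the OR scale when `b` holds
#' log-ORs).
#'
#' @param obs an [observation_vector()].
#' @param R_db,R_trait database and trait correlation matrices; their
#'   Kronecker product must match the observation order.
#' @param scale `"log_or"` (overall OR reported as `exp(b_bar)`) or
#'   `"auc"`.
#' @param conf confidence level (default 0.95).
#' @return Object of class `aggregate_result`.
#' @export
aggregate_observations <- function(obs, R_db, R_trait, scale = c("log_or", "auc"),
                                   conf = 0.95) {
  scale <- match.arg(scale)
  R <- kronecker_correlation(R_db, R_trait)
  b_bar <- overall_estimate(obs)
  v <- overall_variance(obs, R)
  zq <- qnorm(1 - (1 - conf) / 2)
  ci <- b_bar + c(-1, 1) * zq * sqrt(as.numeric(v))
  res <- list(b_bar = b_bar, var_b_bar = as.numeric(v), ci = ci, conf = conf,
              m = nrow(obs), scale = scale,
              overall_or = if (scale == "log_or") exp(b_bar) else NA_real_,
              or_ci = if (scale == "log_or") exp(ci) else c(NA_real_, NA_real_),
              projected = isTRUE(attr(v, "projected")))
  class(res) <- "aggregate_result"
  res
}

#' @export
print.aggregate_result <- function(x, ...) {
  if (x$scale == "log_or") {
    cat(sprintf("overall OR = %.3f (%.0f%% CI %.3f-%.3f), m = %d\n",
                x$overall_or, 100 * x$conf, x$or_ci[1], x$or_ci[2], x$m))
  } else {
    cat(sprintf("overall AUC = %.3f (%.0f%% CI %.3f-%.3f), m = %d\n",
                x$b_bar, 100 * x$conf, x$ci[1], x$ci[2], x$m))
  }
  invisible(x)
}
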