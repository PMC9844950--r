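#' Shrink unit-interval responses away from the boundary
#'
#' The beta distribution has open support, so responses equal to 0 or 1
#' cannot enter a beta regression. The standard compression
#' `(y * (N - 1) + 0.5) / N` maps `[0, 1]` into `(0, 1)`; it is applied to
#' the whole response vector whenever any value lies on the boundary,
#' and the application is logged.
#'
#' @param y Responses in `[0, 1]`.
#' @return Responses strictly inside `(0, 1)`.
#' @export
shrink_unit <- function(y) {
  if (any(y < 0 | y > 1)) stop("responses must lie in [0, 1]")
  if (any(y == 0 | y == 1)) {
    n <- length(y)
    message(sprintf(
      "shrink_unit: %d boundary value(s); compressing all %d responses by (y*(N-1)+0.5)/N",
      sum(y == 0 | y == 1), n
    ))
    y <- (y * (n - 1) + 0.5) / n
  }
  y
}

#' Beta regression of agreement on data-set penetration
#'
#' Fits `|rho_i| ~ Beta(mu_i, phi)` by maximum likelihood, with a logit link
#' for the mean, `logit(mu_i) = beta0 + beta1 * log10(pi_i)`, and a single
#' precision parameter `phi` (mean-precision parameterization: shape
#' parameters `mu*phi` and `(1-mu)*phi`). `pi_i` is the average data-set
#' penetration of country `i` and `|rho_i|` its unsigned correlation with an
#' external mobility index.
#'
#' Reported alongside the coefficients:
#' * `pseudo_R2` — squared correlation between observed and fitted `|rho|`;
#' * `f_statistic`, `f_pvalue` — test of the penetration term against the
#'   intercept-only model, using the squared Wald ratio of the slope
#'   referred to an F(1, n - 3) distribution;
#' * standard errors from the inverse observed information.
#'
#' @param rho_abs Unsigned correlations in `[0, 1]` (boundary values are
#'   compressed via [shrink_unit()]).
#' @param penetration Average penetrations `pi_i > 0`.
#' @return A `beta_reg` object: list with `coefficients` (`(Intercept)`,
#'   `log10(penetration)`), `phi`, `se`, `fitted`, `pseudo_R2`,
#'   `f_statistic`, `f_pvalue`, `logLik`, `logLik_null`, `data`.
#' @export
fit_beta_regression <- function(rho_abs, penetration) {
  stopifnot(length(rho_abs) == length(penetration), all(penetration > 0))
  n <- length(rho_abs)
  if (n < 3) stop("need at least 3 (|rho|, penetration) pairs")
  y <- shrink_unit(rho_abs)
  x <- log10(penetration)

  nll <- function(par, X) {
    eta <- as.numeric(X %*% par[-length(par)])
    mu <- stats::plogis(eta)
    phi <- exp(par[length(par)])
    -sum(stats::dbeta(y, mu * phi, (1 - mu) * phi, log = TRUE))
  }
  fit_one <- function(X, start) {
    opt <- stats::optim(start, nll, X = X, method = "BFGS", hessian = TRUE,
                        control = list(maxit = 500, reltol = 1e-12))
    if (opt$convergence != 0) {
      stop("beta regression did not converge (optim code ",
           opt$convergence, "): ", opt$message)
    }
    opt
  }

  # starting values: linear fit on the logit scale, moment-matched phi
  X <- cbind(1, x)
  b0 <- stats::coef(stats::lm(stats::qlogis(y) ~ x))
  mu0 <- stats::plogis(as.numeric(X %*% b0))
  resid_var <- max(stats::var(y - mu0), 1e-6)
  phi0 <- max(mean(mu0 * (1 - mu0)) / resid_var - 1, 1)
  full <- fit_one(X, c(b0, log(phi0)))

  Xn <- cbind(rep(1, n))
  m0 <- mean(y)
  phi0n <- max(m0 * (1 - m0) / max(stats::var(y), 1e-6) - 1, 1)
  null <- fit_one(Xn, c(stats::qlogis(m0), log(phi0n)))

  vc <- tryCatch(solve(full$hessian), error = function(e) {
    stop("beta regression information matrix is singular: ", conditionMessage(e))
  })
  se <- sqrt(pmax(diag(vc), 0))
  coefs <- full$par[1:2]
  names(coefs) <- c("(Intercept)", "log10(penetration)")
  mu_hat <- stats::plogis(as.numeric(X %*% coefs))

  f_stat <- (coefs[2] / se[2])^2
  f_p <- stats::pf(f_stat, 1, n - 3, lower.tail = FALSE)

  structure(
    list(
      coefficients = coefs,
      phi = exp(full$par[3]),
      se = stats::setNames(se[1:2], names(coefs)),
      fitted = mu_hat,
      pseudo_R2 = stats::cor(y, mu_hat)^2,
      f_statistic = as.numeric(f_stat),
      f_pvalue = as.numeric(f_p),
      logLik = -full$value,
      logLik_null = -null$value,
      data = tibble::tibble(rho_abs = y, penetration = penetration)
    ),
    class = "beta_reg"
  )
}

#' @export
print.beta_reg <- function(x, ...) {
  cat("Beta regression (logit link) of |rho| on log10(penetration)\n")
  cat(sprintf("  intercept: %8.4f (se %.4f)\n", x$coefficients[1], x$se[1]))
  cat(sprintf("  slope:     %8.4f (se %.4f)\n", x$coefficients[2], x$se[2]))
  cat(sprintf("  precision phi: %.2f\n", x$phi))
  cat(sprintf("  pseudo-R2: %.3f   F = %.2f, p = %.4g\n",
              x$pseudo_R2, x$f_statistic, x$f_pvalue))
  invisible(x)
}

#' Predict from a beta regression
#'
#' @param object A `beta_reg`.
#' @param newdata Optional vector of penetrations; defaults to the training
#'   penetrations.
#' @param ... Unused.
#' @return Fitted means on the response scale.
#' @export
predict.beta_reg <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted)
  eta <- object$coefficients[1] + object$coefficients[2] * log10(newdata)
  as.numeric(stats::plogis(eta))
}
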