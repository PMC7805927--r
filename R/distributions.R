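# Maximum-likelihood fitting of candidate distance distributions and
# BIC-based model selection.

#' Rayleigh distribution
#'
#' Density, distribution function and random generation for the Rayleigh
#' distribution with scale `sigma`.
#' @param x,q,n the usual distribution-function arguments.
#' @param sigma scale parameter (> 0).
#' @name rayleigh
#' @export
drayleigh <- function(x, sigma = 1) {
  out <- numeric(length(x))
  ok <- x >= 0
  out[ok] <- x[ok] / sigma^2 * exp(-x[ok]^2 / (2 * sigma^2))
  out
}

#' @rdname rayleigh
#' @export
prayleigh <- function(q, sigma = 1) {
  ifelse(q < 0, 0, 1 - exp(-q^2 / (2 * sigma^2)))
}

#' @rdname rayleigh
#' @export
rrayleigh <- function(n, sigma = 1) {
  sigma * sqrt(-2 * log(stats::runif(n)))
}

#' Generalized extreme value (GEV) distribution
#'
#' Density, distribution function and random generation for the GEV family
#' with shape `shape` (xi), location `loc` (mu) and scale `scale` (sigma).
#' `shape = 0` is the Gumbel limit.
#' @param x,q,n the usual distribution-function arguments.
#' @param shape,loc,scale GEV parameters; `scale > 0`.
#' @name gev
#' @export
dgev <- function(x, shape = 0, loc = 0, scale = 1) {
  z <- (x - loc) / scale
  out <- numeric(length(x))
  if (abs(shape) < 1e-9) {
    t <- exp(-z)
    out <- t * exp(-t) / scale
  } else {
    s <- 1 + shape * z
    ok <- s > 0
    t <- s[ok]^(-1 / shape)
    out[ok] <- t^(shape + 1) * exp(-t) / scale
  }
  out
}

#' @rdname gev
#' @export
pgev <- function(q, shape = 0, loc = 0, scale = 1) {
  z <- (q - loc) / scale
  if (abs(shape) < 1e-9) {
    return(exp(-exp(-z)))
  }
  s <- pmax(1 + shape * z, 0)
  p <- exp(-s^(-1 / shape))
  if (shape > 0) p[s == 0] <- 0 else p[s == 0] <- 1
  p
}

#' @rdname gev
#' @export
rgev <- function(n, shape = 0, loc = 0, scale = 1) {
  u <- stats::runif(n)
  if (abs(shape) < 1e-9) {
    loc - scale * log(-log(u))
  } else {
    loc + scale * ((-log(u))^(-shape) - 1) / shape
  }
}

# half-normal (scale sigma) and log-logistic (shape b, scale a) densities,
# used only as BIC candidates
dhalfnorm <- function(x, sigma = 1) {
  ifelse(x < 0, 0, sqrt(2 / pi) / sigma * exp(-x^2 / (2 * sigma^2)))
}
phalfnorm <- function(q, sigma = 1) {
  ifelse(q < 0, 0, 2 * stats::pnorm(q, 0, sigma) - 1)
}
dllogis <- function(x, shape = 1, scale = 1) {
  ifelse(x <= 0, 0,
         (shape / scale) * (x / scale)^(shape - 1) /
           (1 + (x / scale)^shape)^2)
}
pllogis <- function(q, shape = 1, scale = 1) {
  ifelse(q <= 0, 0, 1 / (1 + (q / scale)^(-shape)))
}

#' Bayesian information criterion
#'
#' `BIC = -2 ln(L) + p ln(nb)` for a model with log-likelihood `ln(L)`,
#' `p` free parameters and `nb` observations.
#'
#' @param loglik natural-log likelihood of the fitted model.
#' @param p number of free parameters.
#' @param nb sample size.
#' @return the BIC value.
#' @export
bic_value <- function(loglik, p, nb) {
  -2 * loglik + p * log(nb)
}

#' Maximum-likelihood fit of a GEV distribution
#'
#' Nelder-Mead optimization of the negative log-likelihood, started from
#' the Gumbel method-of-moments estimates and a small positive shape.
#'
#' @param x sample (numeric, length >= 10).
#' @return list with `shape`, `loc`, `scale`, `loglik`.
#' @export
fit_gev <- function(x) {
  stopifnot(length(x) >= 10)
  s0 <- stats::sd(x) * sqrt(6) / pi
  m0 <- mean(x) - 0.5772157 * s0
  nll <- function(par) {
    sc <- exp(par[3])
    d <- dgev(x, shape = par[1], loc = par[2], scale = sc)
    if (any(d <= 0)) {
      return(1e10)
    }
    -sum(log(d))
  }
  nll0 <- nll(c(0.1, m0, log(s0)))
  best <- stats::optim(c(0.1, m0, log(s0)), nll,
                       control = list(maxit = 1000, reltol = 1e-9))
  if (best$value >= 1e10 || best$value > nll0) {
    # retry from alternative shape starts only when the first fails
    for (xi0 in c(-0.1, 0.5)) {
      fit <- stats::optim(c(xi0, m0, log(s0)), nll,
                          control = list(maxit = 1000, reltol = 1e-9))
      if (fit$value < best$value) best <- fit
    }
  }
  if (!is.finite(best$value) || best$value >= 1e10) {
    stop("GEV fit failed to converge")
  }
  list(shape = best$par[1], loc = best$par[2], scale = exp(best$par[3]),
       loglik = -best$value)
}

# --- candidate-family registry -----------------------------------------
# Each entry fits a family by maximum likelihood and returns parameters,
# the log-likelihood and the free-parameter count. Families that cannot
# support the sample raise an error; fit_and_select() skips them.

fit_via_fitdistrplus <- function(x, distr, start = NULL) {
  f <- if (is.null(start)) {
    fitdistrplus::fitdist(x, distr)
  } else {
    fitdistrplus::fitdist(x, distr, start = start)
  }
  list(params = as.list(f$estimate), loglik = f$loglik,
       p = length(f$estimate))
}

family_registry <- function() {
  list(
    normal = function(x) {
      mu <- mean(x)
      sd0 <- sqrt(mean((x - mu)^2))
      list(params = list(mean = mu, sd = sd0),
           loglik = sum(stats::dnorm(x, mu, sd0, log = TRUE)), p = 2)
    },
    lognormal = function(x) {
      stopifnot(all(x > 0))
      ml <- mean(log(x))
      sl <- sqrt(mean((log(x) - ml)^2))
      list(params = list(meanlog = ml, sdlog = sl),
           loglik = sum(stats::dlnorm(x, ml, sl, log = TRUE)), p = 2)
    },
    exponential = function(x) {
      stopifnot(all(x >= 0))
      r <- 1 / mean(x)
      list(params = list(rate = r),
           loglik = sum(stats::dexp(x, r, log = TRUE)), p = 1)
    },
    gamma = function(x) {
      stopifnot(all(x > 0))
      fit_via_fitdistrplus(x, "gamma")
    },
    weibull = function(x) {
      stopifnot(all(x > 0))
      fit_via_fitdistrplus(x, "weibull")
    },
    rayleigh = function(x) {
      stopifnot(all(x >= 0))
      sg <- sqrt(mean(x^2) / 2)
      list(params = list(sigma = sg),
           loglik = sum(log(drayleigh(x, sg))), p = 1)
    },
    gev = function(x) {
      f <- fit_gev(x)
      list(params = f[c("shape", "loc", "scale")], loglik = f$loglik, p = 3)
    },
    logistic = function(x) fit_via_fitdistrplus(x, "logis"),
    halfnormal = function(x) {
      stopifnot(all(x >= 0))
      sg <- sqrt(mean(x^2))
      list(params = list(sigma = sg),
           loglik = sum(log(dhalfnorm(x, sg))), p = 1)
    },
    loglogistic = function(x) {
      stopifnot(all(x > 0))
      nll <- function(par) {
        d <- dllogis(x, shape = exp(par[1]), scale = exp(par[2]))
        if (any(d <= 0)) {
          return(1e10)
        }
        -sum(log(d))
      }
      fit <- stats::optim(c(log(1.5), log(stats::median(x))), nll,
                          control = list(maxit = 2000, reltol = 1e-10))
      list(params = list(shape = exp(fit$par[1]), scale = exp(fit$par[2])),
           loglik = -fit$value, p = 2)
    }
  )
}

#' Names of the available candidate distribution families
#' @return character vector.
#' @export
candidate_families <- function() {
  names(family_registry())
}

#' Fit one distribution family by maximum likelihood
#'
#' @param x sample.
#' @param family family name (see [candidate_families()]).
#' @return a `fit_candidate`: `family`, `params`, `loglik`, `p`, `nb`,
#'   `bic`.
#' @export
fit_family <- function(x, family) {
  reg <- family_registry()
  if (!family %in% names(reg)) {
    stop("unknown family: ", family)
  }
  f <- reg[[family]](x)
  structure(list(family = family, params = f$params, loglik = f$loglik,
                 p = f$p, nb = length(x),
                 bic = bic_value(f$loglik, f$p, length(x))),
            class = "fit_candidate")
}

#' Fit candidate families and select the best by BIC
#'
#' Each family in `families` is fitted by maximum likelihood; families that
#' cannot fit the sample (e.g. positive-support families on data with
#' zeros) are skipped with a warning. The candidate minimizing
#' `BIC = -2 ln(L) + p ln(nb)` is selected.
#'
#' @param x sample (length >= 10).
#' @param families candidate family names; default all available.
#' @return list with `best` (a `fit_candidate`) and `candidates` (all
#'   successful fits, as a data frame with family, p, loglik, bic).
#' @export
fit_and_select <- function(x, families = candidate_families()) {
  if (length(x) < 10) stop("sample size must be >= 10")
  if (length(families) == 0) stop("candidate list is empty")
  fits <- list()
  for (fam in families) {
    f <- tryCatch(fit_family(x, fam), error = function(e) NULL)
    if (is.null(f) || !is.finite(f$bic)) {
      warning("family '", fam, "' could not be fitted; skipped",
              call. = FALSE)
    } else {
      fits[[fam]] <- f
    }
  }
  if (length(fits) == 0) stop("no candidate family could be fitted")
  bics <- vapply(fits, `[[`, numeric(1), "bic")
  tab <- data.frame(
    family = names(fits),
    p = vapply(fits, `[[`, numeric(1), "p"),
    loglik = vapply(fits, `[[`, numeric(1), "loglik"),
    bic = bics,
    row.names = NULL
  )
  list(best = fits[[which.min(bics)]], candidates = tab[order(tab$bic), ])
}

#' @export
print.fit_candidate <- function(x, ...) {
  cat(sprintf("fit_candidate: %s (p = %d, nb = %d), logLik %.2f, BIC %.2f\n",
              x$family, x$p, x$nb, x$loglik, x$bic))
  cat("  params:", paste(names(x$params),
                         signif(unlist(x$params), 5),
                         sep = " = ", collapse = ", "), "\n")
  invisible(x)
}
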