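#' Reduce site covariates by PCA with varimax rotation
#'
#' Principal components of the (internally standardized) covariate matrix;
#' components with eigenvalue > 1 are retained and varimax-rotated; rotated
#' scores per site are returned for use as occupancy covariates. Constant
#' covariates are dropped with a warning.
#'
#' @param covariates data.frame or matrix, one row per site
#' @return list of class `covariate_reduction`: `loadings` (covariate x
#'   retained PC, rotated), `eigenvalues` (all), `n_retained`, `scores`
#'   (site x retained PC, rotated), `explained` (percent variance per
#'   retained PC and cumulative)
#' @export
reduce_covariates <- function(covariates) {
  X <- as.matrix(covariates)
  if (ncol(X) < 2 || nrow(X) < 3) stop("need >= 2 covariates and >= 3 sites")
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    warning("dropping constant covariates: ",
            paste(colnames(X)[sds == 0], collapse = ", "))
    X <- X[, sds > 0, drop = FALSE]
  }
  Z <- scale(X)
  pc <- stats::prcomp(Z, center = FALSE, scale. = FALSE)
  eig <- pc$sdev^2
  keep <- which(eig > 1)
  if (!length(keep)) keep <- 1L
  load_raw <- pc$rotation[, keep, drop = FALSE] %*%
    diag(pc$sdev[keep], length(keep))        # correlation-scaled loadings
  if (length(keep) > 1) {
    vm <- stats::varimax(load_raw)
    loadings <- unclass(vm$loadings)
    rotmat <- vm$rotmat
  } else {
    loadings <- load_raw
    rotmat <- diag(1)
  }
  scores <- scale(pc$x[, keep, drop = FALSE]) %*% rotmat
  colnames(scores) <- colnames(loadings) <- sprintf("PC%d", seq_along(keep))
  expl <- 100 * colSums(loadings^2) / ncol(X)
  structure(list(loadings = loadings, eigenvalues = eig,
                 n_retained = length(keep), scores = scores,
                 explained = expl, cumulative = cumsum(expl)),
            class = "covariate_reduction")
}

#' Fit a single-season occupancy model with imperfect detection
#'
#' Maximum likelihood for the zero-inflated detection model: for a site
#' with detection history y, `P(y) = psi * prod(p_j^y_j (1-p_j)^(1-y_j)) +
#' (1 - psi) * I(all y = 0)`, with logit links on occupancy `psi` and
#' per-survey detection `p`. Three detection structures: `constant` (one
#' intercept), `survey_specific` (one intercept per survey index) and
#' `abundance_index` (logit p linear in a site-level abundance index).
#' Optimized by multi-start quasi-Newton on the logit scale; standard
#' errors from the inverse observed information.
#'
#' @param hist a `detection_history` (from [gen_detection_histories()] or
#'   [read_detection_table()])
#' @param psi_formula RHS formula for occupancy covariates, evaluated in
#'   `hist$covariates` (default `~ 1`)
#' @param detection_model one of `"constant"`, `"survey_specific"`,
#'   `"abundance_index"`
#' @param abundance name of the abundance-index column in `hist$covariates`
#'   (required for `detection_model = "abundance_index"`)
#' @param n_starts optimizer restarts
#' @param seed integer seed for the restart jitter
#' @param start optional warm-start coefficient vector
#' @return object of class `occu_fit`: coefficients, `vcov`, `logLik`,
#'   `aic`, per-site `psi_hat` and `p_hat`, `model` label, `converged`
#' @export
fit_occupancy <- function(hist, psi_formula = ~ 1,
                          detection_model = c("constant", "survey_specific",
                                              "abundance_index"),
                          abundance = NULL, n_starts = 3L, seed = 1L,
                          start = NULL) {
  detection_model <- match.arg(detection_model)
  surveyed <- !vapply(hist$y, function(v) length(v) == 0L, TRUE)
  y <- hist$y[surveyed]
  covs <- if (!is.null(hist$covariates))
    hist$covariates[surveyed, , drop = FALSE]
  else data.frame(row.names = seq_len(sum(surveyed)))
  X <- stats::model.matrix(psi_formula, data = covs)
  G <- length(y)
  kmax <- max(vapply(y, length, 0L))
  npsi <- ncol(X)
  ndet <- switch(detection_model, constant = 1L, survey_specific = kmax,
                 abundance_index = 2L)
  ab <- NULL
  if (detection_model == "abundance_index") {
    if (is.null(abundance) || !abundance %in% names(covs))
      stop("abundance-index column not found in covariates")
    ab <- covs[[abundance]]
  }
  ## per-site sufficient statistics (vectorized likelihood)
  d_i <- vapply(y, function(v) sum(v, na.rm = TRUE), 0)        # detections
  m_i <- vapply(y, function(v) sum(!is.na(v)), 0)              # surveys
  none <- d_i == 0
  Ymat <- NAmat <- NULL
  if (detection_model == "survey_specific") {
    Ymat <- matrix(NA_real_, G, kmax)
    for (i in seq_len(G)) Ymat[i, seq_along(y[[i]])] <- y[[i]]
    NAmat <- is.na(Ymat)
  }
  nloglik <- function(par) {
    beta <- par[seq_len(npsi)]; theta <- par[npsi + seq_len(ndet)]
    psi <- stats::plogis(drop(X %*% beta))
    logcond <- switch(detection_model,
      constant = {
        p <- stats::plogis(theta[1])
        d_i * log(max(p, 1e-300)) + (m_i - d_i) * log(max(1 - p, 1e-300))
      },
      abundance_index = {
        p <- stats::plogis(theta[1] + theta[2] * ab)
        d_i * log(pmax(p, 1e-300)) + (m_i - d_i) * log(pmax(1 - p, 1e-300))
      },
      survey_specific = {
        p <- stats::plogis(theta)
        lp <- matrix(log(pmax(p, 1e-300)), G, kmax, byrow = TRUE)
        lq <- matrix(log(pmax(1 - p, 1e-300)), G, kmax, byrow = TRUE)
        contrib <- Ymat * lp + (1 - Ymat) * lq
        contrib[NAmat] <- 0
        rowSums(contrib)
      })
    li <- psi * exp(logcond) + (1 - psi) * none
    -sum(log(pmax(li, 1e-300)))
  }
  set.seed(seed)
  npar <- npsi + ndet
  best <- NULL
  for (s in seq_len(n_starts)) {
    st <- if (s == 1) { if (is.null(start)) rep(0, npar) else start }
          else stats::rnorm(npar, 0, 1)
    op <- try(stats::optim(st, nloglik, method = "BFGS", hessian = FALSE,
                           control = list(maxit = 500, reltol = 1e-10)),
              silent = TRUE)
    if (inherits(op, "try-error")) next
    if (is.null(best) || op$value < best$value - 1e-8) best <- op
  }
  if (is.null(best)) stop("occupancy optimizer failed at every start")
  H <- stats::optimHess(best$par, nloglik)
  vc <- try(solve(H), silent = TRUE)
  if (inherits(vc, "try-error")) vc <- matrix(NA_real_, npar, npar)
  beta <- best$par[seq_len(npsi)]; theta <- best$par[npsi + seq_len(ndet)]
  psi_hat <- stats::plogis(drop(X %*% beta))
  p_list <- lapply(seq_len(G), function(i) {
    k <- length(y[[i]])
    switch(detection_model,
           constant = rep(stats::plogis(theta[1]), k),
           survey_specific = stats::plogis(theta[seq_len(k)]),
           abundance_index = rep(stats::plogis(theta[1] + theta[2] * ab[i]), k))
  })
  p_hat <- vapply(p_list, mean, 0)
  boundary <- any(psi_hat > 1 - 1e-6) || any(psi_hat < 1e-6)
  if (boundary) warning("occupancy estimate at boundary")
  cn <- c(paste0("psi_", colnames(X)),
          switch(detection_model,
                 constant = "p_(Intercept)",
                 survey_specific = sprintf("p_survey%d", seq_len(kmax)),
                 abundance_index = c("p_(Intercept)", paste0("p_", abundance))))
  names(best$par) <- cn
  dimnames(vc) <- list(cn, cn)
  structure(list(coefficients = best$par, vcov = vc,
                 logLik = -best$value, aic = 2 * best$value + 2 * npar,
                 n_params = npar, psi_hat = psi_hat, p_hat = p_hat,
                 p_list = p_list, covariates = covs,
                 model = paste0("psi(", deparse(psi_formula[[2]]), "),p(",
                                detection_model, ")"),
                 detection_model = detection_model, abundance = abundance,
                 psi_formula = psi_formula, npsi = npsi,
                 X = X, y = y, ab = ab,
                 converged = best$convergence == 0 && !boundary,
                 grid_id = hist$grid_id[surveyed]),
            class = "occu_fit")
}

#' @method print occu_fit
#' @export
print.occu_fit <- function(x, ...) {
  cat("Single-season occupancy model:", x$model, "\n")
  cat(sprintf("  sites: %d  logLik: %.2f  AIC: %.2f  converged: %s\n",
              length(x$y), x$logLik, x$aic, x$converged))
  cat(sprintf("  mean psi-hat: %.3f  mean p-hat: %.3f\n",
              mean(x$psi_hat), mean(x$p_hat)))
  invisible(x)
}

#' Summarize an occupancy fit
#'
#' @param object an `occu_fit`
#' @param c_hat overdispersion factor; standard errors are inflated by
#'   `sqrt(c_hat)` and the exponentiated coefficients reported
#' @param ... unused
#' @method summary occu_fit
#' @export
summary.occu_fit <- function(object, c_hat = 1, ...) {
  se <- sqrt(pmax(diag(object$vcov), 0)) * sqrt(c_hat)
  tab <- data.frame(estimate = object$coefficients, se = se,
                    exponent = exp(object$coefficients))
  out <- list(model = object$model, coefficients = tab, aic = object$aic,
              logLik = object$logLik, c_hat = c_hat,
              inflation = sqrt(c_hat))
  class(out) <- "summary.occu_fit"
  out
}

#' @method print summary.occu_fit
#' @export
print.summary.occu_fit <- function(x, ...) {
  cat("Occupancy model:", x$model, "\n")
  cat(sprintf("logLik %.2f  AIC %.2f  (SEs inflated by sqrt(c-hat) = %.3f)\n",
              x$logLik, x$aic, x$inflation))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' @export
coef.occu_fit <- function(object, ...) object$coefficients

#' @export
logLik.occu_fit <- function(object, ...) {
  structure(object$logLik, df = object$n_params, class = "logLik")
}

#' @export
vcov.occu_fit <- function(object, ...) object$vcov

#' Predict per-site occupancy probability
#' @param object an `occu_fit`
#' @param newdata optional data.frame of covariates
#' @param ... unused
#' @export
predict.occu_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$psi_hat)
  X <- stats::model.matrix(object$psi_formula, data = newdata)
  stats::plogis(drop(X %*% object$coefficients[seq_len(object$npsi)]))
}

#' @export
fitted.occu_fit <- function(object, ...) object$psi_hat

#' Simulate detection histories from a fitted occupancy model
#' @param object an `occu_fit`
#' @param nsim number of replicate data sets
#' @param seed integer seed
#' @param ... unused
#' @return list of length `nsim`; each element is a list of 0/1 vectors
#'   matching the fitted survey design
#' @export
simulate.occu_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  ks <- vapply(object$y, length, 0L)
  lapply(seq_len(nsim), function(s) {
    z <- stats::rbinom(length(ks), 1, object$psi_hat)
    lapply(seq_along(ks), function(i)
      stats::rbinom(ks[i], 1, object$p_list[[i]] * z[i]))
  })
}

#' AIC model selection and model-averaged occupancy
#'
#' Ranks candidate fits by AIC, computes Akaike weights, and averages
#' per-site occupancy over all models within `delta_aic_cut` of the best
#' (weights renormalized over that set).
#'
#' @param fits list of `occu_fit` objects on the same sites
#' @param delta_aic_cut models with delta AIC below this enter the average
#' @return list: `table` (model, aic, delta_aic, weight, model_likelihood,
#'   n_params, minus2loglik), `psi_averaged` per site
#' @export
model_select_average <- function(fits, delta_aic_cut = 4) {
  if (!length(fits)) stop("no fits supplied")
  aic <- vapply(fits, `[[`, 0, "aic")
  delta <- aic - min(aic)
  w <- exp(-delta / 2); w <- w / sum(w)
  tab <- data.frame(model = vapply(fits, `[[`, "", "model"),
                    aic = aic, delta_aic = delta, weight = w,
                    model_likelihood = exp(-delta / 2),
                    n_params = vapply(fits, `[[`, 0, "n_params"),
                    minus2loglik = -2 * vapply(fits, `[[`, 0, "logLik"))
  tab <- tab[order(tab$aic), ]
  inavg <- which(delta < delta_aic_cut)
  wavg <- w[inavg] / sum(w[inavg])
  psi <- Reduce(`+`, Map(function(f, wt) wt * f$psi_hat,
                         fits[inavg], wavg))
  list(table = tab, psi_averaged = psi)
}

#' Parametric-bootstrap goodness of fit and overdispersion
#'
#' Sites are binned by survey count (histories of unequal length are not
#' comparable); within each cohort a chi-squared statistic compares
#' observed detection-history frequencies with their expected frequencies
#' under the fitted model (unobserved histories pooled into a remainder
#' class). Bootstrap data sets are simulated from the fitted `(psi, p)`;
#' `c_hat` is the ratio of the observed statistic to the bootstrap mean and
#' the standard-error inflation factor is `sqrt(c_hat)`.
#'
#' @param fit an `occu_fit`
#' @param n_boot bootstrap replicates (>= 100 recommended)
#' @param seed integer seed
#' @return list of class `occu_gof`: `chi2_obs`, `chi2_boot`, `c_hat`,
#'   `inflation`, `p_value`
#' @export
gof_bootstrap <- function(fit, n_boot = 1000L, seed = 1L) {
  if (n_boot < 100) warning("n_boot < 100 gives an unstable c-hat")
  set.seed(seed)
  obs <- occu_gof_chi2(fit$y, fit)
  sims <- simulate(fit, nsim = n_boot)
  ## each bootstrap data set is refit (warm-started at the parent fit) so
  ## observed and bootstrap statistics both enjoy the same overfitting
  boot <- vapply(sims, function(yb) {
    hb <- list(grid_id = fit$grid_id, y = yb, covariates = fit$covariates)
    fb <- suppressWarnings(fit_occupancy(hb, fit$psi_formula,
                                         fit$detection_model,
                                         abundance = fit$abundance,
                                         n_starts = 1,
                                         start = unname(fit$coefficients)))
    occu_gof_chi2(fb$y, fb)
  }, 0)
  c_hat <- obs / mean(boot)
  structure(list(chi2_obs = obs, chi2_boot = boot, c_hat = c_hat,
                 inflation = sqrt(c_hat),
                 p_value = mean(boot >= obs)),
            class = "occu_gof")
}

## chi-squared on detection-count frequencies within survey-count cohorts:
## observed counts of d = 0..k detections vs their expected frequencies
## under the fitted (psi, p); per-site P(D = d | occupied) by the
## Poisson-binomial recursion so survey-specific detection is exact
occu_gof_chi2 <- function(ylist, fit) {
  ks <- vapply(ylist, length, 0L)
  stat <- 0
  for (k in unique(ks)) {
    idx <- which(ks == k)
    d_obs <- vapply(ylist[idx], function(v) sum(v, na.rm = TRUE), 0)
    obs <- tabulate(d_obs + 1, k + 1)
    expd <- numeric(k + 1)
    for (i in idx) {
      p <- fit$p_list[[i]]
      pb <- c(1, numeric(k))                 # P(D = d | occupied), DP
      for (j in seq_len(k))
        pb <- c(pb[1] * (1 - p[j]),
                pb[-1] * (1 - p[j]) + pb[-(k + 1)] * p[j])
      pd <- fit$psi_hat[i] * pb
      pd[1] <- pd[1] + (1 - fit$psi_hat[i])
      expd <- expd + pd
    }
    ## pool adjacent detection-count classes until each pooled class has
    ## expected count >= 0.5 (keeps the statistic bounded)
    po <- pe <- numeric(0)
    acc_o <- acc_e <- 0
    for (d in seq_len(k + 1)) {
      acc_o <- acc_o + obs[d]; acc_e <- acc_e + expd[d]
      if (acc_e >= 0.5) {
        po <- c(po, acc_o); pe <- c(pe, acc_e)
        acc_o <- acc_e <- 0
      }
    }
    if (acc_e > 0 && length(pe)) {           # fold the tail into the last class
      po[length(po)] <- po[length(po)] + acc_o
      pe[length(pe)] <- pe[length(pe)] + acc_e
    }
    stat <- stat + sum((po - pe)^2 / pe)
  }
  stat
}

#' Standard-error inflation factor from an overdispersion estimate
#' @param c_hat overdispersion (observed/expected fit statistic)
#' @return `sqrt(c_hat)`
#' @export
se_inflation <- function(c_hat) {
  stopifnot(c_hat > 0)
  sqrt(c_hat)
}

#' Naive versus model-inferred occupancy and occupied-habitat area
#'
#' Naive grid occupancy is the fraction of surveyed grids with at least one
#' detection; model occupancy is the mean of the per-grid occupancy
#' probabilities. Occupied habitat weights each grid's habitat area by its
#' occupancy probability (naive analogue: habitat of detection grids).
#' Increments are reported in percentage points.
#'
#' @param psi_hat per-grid occupancy probabilities
#' @param habitat_area per-grid habitat area (same length; any unit)
#' @param detected logical per grid: at least one detection
#' @return list: `naive_occupancy`, `model_occupancy` (percent),
#'   `increment_points`, `naive_habitat`, `model_habitat`,
#'   `habitat_increment_pct`
#' @export
occupancy_area_summary <- function(psi_hat, habitat_area, detected) {
  stopifnot(length(psi_hat) == length(habitat_area),
            length(psi_hat) == length(detected), all(habitat_area >= 0))
  naive <- 100 * mean(detected)
  model <- 100 * mean(psi_hat)
  nh <- sum(habitat_area[detected])
  mh <- sum(psi_hat * habitat_area)
  list(naive_occupancy = naive, model_occupancy = model,
       increment_points = model - naive,
       naive_habitat = nh, model_habitat = mh,
       habitat_increment_pct = if (nh > 0) 100 * (mh - nh) / nh else NA_real_)
}
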