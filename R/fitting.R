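#' Global multi-experiment least-squares fitting
#'
#' Several experiments are fitted simultaneously: parameters declared shared
#' are constrained equal across experiments by construction (one parameter
#' vector drives every model function). Rate constants span decades, so the
#' optimizer works in log10 space within box bounds; multiple starts are
#' drawn from a seeded Latin hypercube. Weighted residuals default to
#' inverse noise standard deviation per channel.
#'
#' @name fitting
NULL

#' Declare one experiment of a fit problem
#'
#' @param model function taking a named parameter vector (natural scale) and
#'   returning predicted values aligned with `observed`
#' @param observed numeric vector of observations
#' @param weights scalar or vector of weights (typically 1/sigma); must be
#'   positive
#' @param label optional label used in diagnostics
#' @return a `fit_experiment`
#' @export
fit_experiment <- function(model, observed, weights = 1, label = "") {
  stopifnot(is.function(model), is.numeric(observed))
  if (any(weights <= 0)) pl_error("weights must be > 0", "validation_error")
  structure(list(model = model, observed = observed, weights = weights,
                 label = label), class = "fit_experiment")
}

#' Global fit over a set of experiments
#'
#' Minimizes the channel-weighted sum of squared residuals over all
#' experiments with the Levenberg-Marquardt algorithm on log10-transformed
#' parameters. Identifiability is screened at the start point by
#' finite-difference sensitivity rank; rank deficiency raises a warning
#' naming the null directions. Approximate standard errors come from the
#' local quadratic approximation at the optimum.
#'
#' @param experiments list of [fit_experiment()] objects
#' @param start named vector of starting values (natural scale, > 0)
#' @param lower,upper named bounds (natural scale); default start/100 and
#'   start*100
#' @param n_starts number of optimizer starts (1 = from `start` only;
#'   additional starts are Latin-hypercube samples of the log-bound box)
#' @param seed integer seed for the start design
#' @param maxiter Levenberg-Marquardt iteration cap per start
#' @return a `fit_result`: `par` (best fit), `se` (approximate standard
#'   errors), `objective`, `reduced_chisq`, `residuals` per experiment,
#'   `convergence`, `n_obs`, `starts` (objective per start)
#' @export
global_fit <- function(experiments, start, lower = start / 100,
                       upper = start * 100, n_starts = 1, seed = 1,
                       maxiter = 100) {
  stopifnot(length(experiments) >= 1, all(start > 0), all(lower > 0),
            all(lower <= start), all(start <= upper))
  pnames <- names(start)
  if (is.null(pnames)) pl_error("start values must be named", "validation_error")
  lower <- lower[pnames]; upper <- upper[pnames]

  obs_all <- unlist(lapply(experiments, function(e) e$observed))
  w_all <- unlist(lapply(experiments, function(e) {
    if (length(e$weights) == 1L) rep(e$weights, length(e$observed)) else e$weights
  }))

  resid_fun <- function(logp) {
    p <- stats::setNames(10^logp, pnames)
    pred <- tryCatch(
      unlist(lapply(experiments, function(e) e$model(p))),
      error = function(err) NULL
    )
    if (is.null(pred) || length(pred) != length(obs_all) || any(!is.finite(pred))) {
      return(rep(1e6, length(obs_all)))
    }
    w_all * (pred - obs_all)
  }

  ## identifiability screen: finite-difference sensitivity rank at the start
  log_start <- log10(start)
  r0 <- resid_fun(log_start)
  J <- matrix(0, nrow = length(r0), ncol = length(pnames))
  h <- 1e-4
  for (j in seq_along(pnames)) {
    lp <- log_start; lp[j] <- lp[j] + h
    J[, j] <- (resid_fun(lp) - r0) / h
  }
  sv <- svd(J)
  rank_tol <- max(sv$d) * 1e-8
  if (any(sv$d < rank_tol)) {
    null_dirs <- apply(sv$v[, sv$d < rank_tol, drop = FALSE], 2, function(v) {
      paste(pnames[abs(v) > 0.3], collapse = "+")
    })
    warning(sprintf("parameter set looks non-identifiable at the start point; null directions: %s",
                    paste(null_dirs, collapse = "; ")), call. = FALSE)
  }

  ## start designs: supplied start plus seeded Latin-hypercube points
  starts <- matrix(log_start, nrow = 1)
  if (n_starts > 1) {
    set.seed(seed)
    u <- lhs::randomLHS(n_starts - 1L, length(pnames))
    lo <- log10(lower); hi <- log10(upper)
    extra <- sweep(sweep(u, 2, hi - lo, `*`), 2, lo, `+`)
    starts <- rbind(starts, extra)
  }

  best <- NULL
  start_obj <- numeric(nrow(starts))
  for (s in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = starts[s, ], fn = resid_fun,
                         lower = log10(lower), upper = log10(upper),
                         control = minpack.lm::nls.lm.control(maxiter = maxiter)),
      error = function(err) NULL
    )
    if (is.null(fit)) { start_obj[s] <- NA_real_; next }
    start_obj[s] <- fit$deviance
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best)) pl_error("optimizer failed on every start", "fit_error")

  par_hat <- stats::setNames(10^best$par, pnames)
  n_obs <- length(obs_all)
  dof <- max(1L, n_obs - length(pnames))
  sigma2 <- best$deviance / dof

  ## standard errors via the Jacobian at the optimum (log10 scale -> natural)
  se <- rep(NA_real_, length(pnames))
  Jh <- matrix(0, nrow = n_obs, ncol = length(pnames))
  rh <- resid_fun(best$par)
  for (j in seq_along(pnames)) {
    lp <- best$par; lp[j] <- lp[j] + h
    Jh[, j] <- (resid_fun(lp) - rh) / h
  }
  jtj <- crossprod(Jh)
  cv <- tryCatch(solve(jtj) * sigma2, error = function(err) NULL)
  if (!is.null(cv)) {
    se_log <- sqrt(pmax(diag(cv), 0))
    se <- par_hat * log(10) * se_log  # delta method back to natural scale
  }
  names(se) <- pnames

  ## residual traces per experiment at the optimum
  pred_all <- unlist(lapply(experiments, function(e) e$model(par_hat)))
  lens <- vapply(experiments, function(e) length(e$observed), 0L)
  idx_end <- cumsum(lens); idx_start <- c(1L, utils::head(idx_end, -1L) + 1L)
  residuals <- lapply(seq_along(experiments), function(i) {
    experiments[[i]]$observed - pred_all[idx_start[i]:idx_end[i]]
  })
  names(residuals) <- vapply(experiments, function(e) e$label, "")

  structure(list(par = par_hat, se = se, objective = best$deviance,
                 reduced_chisq = sigma2, residuals = residuals,
                 convergence = list(info = best$info, message = best$message,
                                    niter = best$niter),
                 n_obs = n_obs, starts = start_obj),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("<fit_result>\n")
  tab <- data.frame(estimate = signif(x$par, 4), std_error = signif(x$se, 3))
  print(tab)
  cat(sprintf("objective %.4g over %d observations (reduced chi-square %.3g)\n",
              x$objective, x$n_obs, x$reduced_chisq))
  invisible(x)
}

#' Noise level from a pre-trigger baseline
#'
#' Default fit weighting is inverse noise standard deviation per channel,
#' with the noise estimated from the portion of a trace recorded before the
#' flash (or light-on) trigger.
#'
#' @param values trace values
#' @param baseline_idx indices of the pre-trigger samples
#' @return estimated standard deviation
#' @export
baseline_sigma <- function(values, baseline_idx) {
  stopifnot(length(baseline_idx) >= 3)
  stats::sd(values[baseline_idx])
}
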