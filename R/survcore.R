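#' Kaplan-Meier product-limit fit
#'
#' Censored subjects leave the risk set after their time; tied events drop
#' simultaneously.
#'
#' @param times non-negative follow-up times (months).
#' @param events 0/1 event indicators.
#' @return object of class `km_curve`: list with `time` (distinct event
#'   times), `n_risk`, `n_event`, `surv` (S at each event time), `n`,
#'   `max_time` (max observed time, any status).
#' @export
km_fit <- function(times, events) {
  if (length(times) == 0) stop("empty input")
  stopifnot(length(times) == length(events), all(times >= 0),
            all(events %in% c(0, 1)))
  o <- order(times)
  times <- times[o]; events <- events[o]
  et <- unique(times[events == 1])
  n <- length(times)
  n_risk <- vapply(et, function(t) sum(times >= t), numeric(1))
  n_event <- vapply(et, function(t) sum(times == t & events == 1), numeric(1))
  surv <- cumprod(1 - n_event / n_risk)
  structure(list(time = et, n_risk = n_risk, n_event = n_event, surv = surv,
                 n = n, max_time = max(times)),
            class = "km_curve")
}

#' Survival probability of a Kaplan-Meier curve at given times
#'
#' @param curve a [km_fit()] result.
#' @param t times.
#' @return S(t), right-continuous step function with S(0) = 1.
#' @export
km_surv_at <- function(curve, t) {
  vapply(t, function(tt) {
    k <- sum(curve$time <= tt)
    if (k == 0) 1 else curve$surv[k]
  }, numeric(1))
}

#' Restricted mean survival time (area under the KM step function)
#'
#' Integrates S(t) from 0 to `horizon`. The default horizon is the curve's
#' maximum observed time; beyond the last step S is carried forward flat.
#'
#' @param curve a [km_fit()] result.
#' @param horizon months (> 0).
#' @return restricted mean survival time in months.
#' @export
mean_survival_time <- function(curve, horizon = NULL) {
  horizon <- horizon %||% curve$max_time
  if (horizon <= 0) stop("horizon must be > 0")
  knots <- c(0, curve$time[curve$time < horizon], horizon)
  s <- c(1, curve$surv[curve$time < horizon])
  sum(s * diff(knots))
}

#' Two-group log-rank test
#'
#' Hypergeometric expectation and variance at each distinct event time,
#' chi-square statistic on 1 df. With no events in either group the statistic
#' is 0 and p = 1 (degenerate).
#'
#' @param times_a,events_a group A follow-up.
#' @param times_b,events_b group B follow-up.
#' @return list with `chisq`, `p`, `observed` and `expected` (group A).
#' @export
logrank <- function(times_a, events_a, times_b, events_b) {
  if (length(times_a) == 0 || length(times_b) == 0)
    stop("both groups must be non-empty")
  times <- c(times_a, times_b)
  events <- c(events_a, events_b)
  grp_a <- rep(c(TRUE, FALSE), c(length(times_a), length(times_b)))
  et <- sort(unique(times[events == 1]))
  if (length(et) == 0)
    return(list(chisq = 0, p = 1, observed = 0, expected = 0))
  obs <- 0; expd <- 0; v <- 0
  for (t in et) {
    at_risk <- times >= t
    n_j <- sum(at_risk)
    n1_j <- sum(at_risk & grp_a)
    d_j <- sum(times == t & events == 1)
    d1_j <- sum(times == t & events == 1 & grp_a)
    obs <- obs + d1_j
    expd <- expd + d_j * n1_j / n_j
    if (n_j > 1)
      v <- v + d_j * (n1_j / n_j) * (1 - n1_j / n_j) * (n_j - d_j) / (n_j - 1)
  }
  if (v <= 0) return(list(chisq = 0, p = 1, observed = obs, expected = expd))
  chisq <- (obs - expd)^2 / v
  list(chisq = chisq, p = stats::pchisq(chisq, df = 1, lower.tail = FALSE),
       observed = obs, expected = expd)
}

#' Harrell concordance index
#'
#' Fraction of usable pairs (the subject with the shorter time had an event
#' and times differ) in which the higher risk score belongs to the
#' shorter-lived subject; risk ties count 1/2.
#'
#' @param risk numeric risk scores (higher = worse).
#' @param times follow-up times.
#' @param events 0/1 indicators.
#' @return c-index in \[0, 1\], NA if no usable pairs.
#' @export
concordance_index <- function(risk, times, events) {
  stopifnot(length(risk) == length(times), length(times) == length(events))
  ev <- which(events == 1)
  conc <- 0; ties <- 0; usable <- 0
  for (i in ev) {
    later <- times > times[i]
    usable <- usable + sum(later)
    conc <- conc + sum(risk[i] > risk[later])
    ties <- ties + sum(risk[i] == risk[later])
  }
  if (usable == 0) return(NA_real_)
  (conc + 0.5 * ties) / usable
}

# Negative log partial likelihood machinery shared by cox_fit.
# Returns loglik, gradient and information at beta for sorted data.
cox_pl <- function(beta, x, times, events, ties) {
  n <- nrow(x)
  eta <- drop(x %*% beta)
  eta <- eta - max(eta)            # guard overflow; PL is shift-invariant
  w <- exp(eta)
  p <- ncol(x)
  ll <- 0
  grad <- numeric(p)
  info <- matrix(0, p, p)
  # data sorted by time ascending; risk set sums by reverse cumulation
  s0 <- rev(cumsum(rev(w)))
  s1 <- apply(x * w, 2, function(col) rev(cumsum(rev(col))))
  s1 <- matrix(s1, nrow = n)
  # s2 per risk set accumulated on the fly for each event time
  et <- unique(times[events == 1])
  for (t in et) {
    first <- match(TRUE, times >= t)          # risk set = first:n
    tied <- which(times == t & events == 1)
    d <- length(tied)
    xd <- x[tied, , drop = FALSE]
    wd <- w[tied]
    sum_xd <- colSums(xd)
    S0 <- s0[first]
    S1 <- s1[first, ]
    idx_risk <- first:n
    xw <- x[idx_risk, , drop = FALSE] * w[idx_risk]
    S2 <- crossprod(x[idx_risk, , drop = FALSE], xw)
    if (ties == "breslow") {
      ll <- ll + sum(eta[tied]) - d * log(S0)
      grad <- grad + sum_xd - d * S1 / S0
      info <- info + d * (S2 / S0 - tcrossprod(S1 / S0))
    } else {  # efron
      S0d <- sum(wd)
      S1d <- colSums(xd * wd)
      xwd <- xd * wd
      S2d <- crossprod(xd, xwd)
      for (k in seq_len(d)) {
        f <- (k - 1) / d
        S0k <- S0 - f * S0d
        S1k <- S1 - f * S1d
        S2k <- S2 - f * S2d
        ll <- ll - log(S0k)
        grad <- grad - S1k / S0k
        info <- info + (S2k / S0k - tcrossprod(S1k / S0k))
      }
      ll <- ll + sum(eta[tied])
      grad <- grad + sum_xd
    }
  }
  list(loglik = ll, gradient = grad, information = info)
}

#' Cox proportional hazards fit by Newton-Raphson
#'
#' Maximizes the log partial likelihood with the Efron tie correction
#' (default) or Breslow; step-halving guards overshooting. Reports Wald
#' p-values per coefficient and the Harrell concordance of the fitted linear
#' predictor.
#'
#' @param covariates numeric matrix or data.frame, n x p.
#' @param times,events follow-up and 0/1 indicators.
#' @param ties "efron" or "breslow".
#' @param max_iter Newton iterations (default 100).
#' @param tol convergence tolerance on the max coefficient change.
#' @return object of class `cox_result`: coefficients table (beta, hr, se,
#'   z, p), `loglik`, `concordance`, `converged`, `flags`.
#' @export
cox_fit <- function(covariates, times, events, ties = c("efron", "breslow"),
                    max_iter = 100, tol = 1e-9) {
  ties <- match.arg(ties)
  x <- as.matrix(covariates)
  storage.mode(x) <- "double"
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  stopifnot(nrow(x) == length(times), length(times) == length(events))
  if (!all(is.finite(x))) stop("covariates must be finite")
  if (sum(events) < 1) stop("at least one event is required")
  const <- apply(x, 2, function(col) length(unique(col)) == 1L)
  if (any(const))
    stop("constant covariate(s): ", paste(colnames(x)[const], collapse = ", "))
  o <- order(times)
  x_s <- x[o, , drop = FALSE]; t_s <- times[o]; e_s <- events[o]
  p <- ncol(x)
  beta <- numeric(p)
  flags <- character(0)
  converged <- FALSE
  fit <- cox_pl(beta, x_s, t_s, e_s, ties)
  for (it in seq_len(max_iter)) {
    step <- tryCatch(solve(fit$information, fit$gradient),
                     error = function(e) NULL)
    if (is.null(step)) { flags <- c(flags, "singular_information"); break }
    new_beta <- beta + step
    new_fit <- cox_pl(new_beta, x_s, t_s, e_s, ties)
    halvings <- 0
    while ((!is.finite(new_fit$loglik) || new_fit$loglik < fit$loglik) &&
           halvings < 20) {
      step <- step / 2
      new_beta <- beta + step
      new_fit <- cox_pl(new_beta, x_s, t_s, e_s, ties)
      halvings <- halvings + 1
    }
    delta <- max(abs(new_beta - beta))
    beta <- new_beta; fit <- new_fit
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged) flags <- c(flags, "not_converged")
  if (any(abs(beta) > 15)) flags <- c(flags, "monotone_likelihood")
  se <- tryCatch(sqrt(diag(solve(fit$information))),
                 error = function(e) rep(NA_real_, p))
  z <- beta / se
  coef_table <- data.frame(term = colnames(x), beta = beta, hr = exp(beta),
                           se = se, z = z,
                           p = 2 * stats::pnorm(-abs(z)),
                           row.names = NULL, stringsAsFactors = FALSE)
  lp <- drop(x %*% beta)
  structure(list(coefficients = coef_table, loglik = fit$loglik,
                 gradient = fit$gradient,
                 concordance = concordance_index(lp, times, events),
                 converged = converged, flags = flags, ties = ties),
            class = "cox_result")
}
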