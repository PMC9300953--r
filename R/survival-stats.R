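# Survival machinery implemented in the package: product-limit estimation,
# the two-group log-rank test, the deterministic median split used for every
# 50:50 comparison, and univariate Cox partial-likelihood fitting with Efron
# tie handling. survival::survfit/survdiff/coxph serve as independent
# oracles in the test suite only.

check_surv_input <- function(times, events) {
  if (length(times) == 0) stop_param("empty survival input")
  if (length(times) != length(events)) stop_param("times and events differ in length")
  if (anyNA(times) || anyNA(events)) stop_param("missing survival values")
  if (any(times < 0)) stop_param("survival times must be non-negative")
  if (!all(events %in% c(0, 1))) stop_param("events must be 0/1")
}

#' Kaplan-Meier product-limit estimate
#'
#' Computes `S(t) = prod(1 - d_i / n_i)` over the distinct event times.
#' The curve starts at `S(0) = 1` and drops only at event times; censored
#' observations leave the risk set without a drop.
#'
#' @param times Non-negative follow-up times.
#' @param events 0/1 event indicators (1 = event observed).
#' @return A tibble of class `sighub_km` with one row per distinct event
#'   time: `time`, `n_risk`, `n_event`, `survival`. The number at risk at
#'   time zero is stored in the `n_start` attribute. All-censored input
#'   yields zero rows (the curve is identically 1).
#' @export
km_estimate <- function(times, events) {
  check_surv_input(times, events)
  o <- order(times)
  t_s <- times[o]; e_s <- events[o]
  ev_times <- unique(t_s[e_s == 1])
  n <- length(t_s)
  rows <- purrr::map(ev_times, function(tt) {
    tibble(time = tt,
           n_risk = sum(t_s >= tt),
           n_event = sum(t_s == tt & e_s == 1))
  })
  out <- if (length(rows)) bind_rows(rows) else
    tibble(time = numeric(0), n_risk = integer(0), n_event = integer(0))
  out$survival <- cumprod(1 - out$n_event / out$n_risk)
  attr(out, "n_start") <- n
  class(out) <- c("sighub_km", class(out))
  out
}

#' Evaluate a Kaplan-Meier curve at given times
#'
#' Step-function evaluation: `S(t)` equals 1 before the first event time and
#' the last computed survival probability at or after the final drop.
#'
#' @param km A `sighub_km` curve.
#' @param t Times at which to evaluate.
#' @return Numeric vector of survival probabilities.
#' @export
km_survival_at <- function(km, t) {
  vapply(t, function(tt) {
    i <- which(km$time <= tt)
    if (length(i) == 0) 1 else km$survival[max(i)]
  }, numeric(1))
}

#' @export
autoplot.sighub_km <- function(object, ...) {
  n0 <- attr(object, "n_start")
  df <- tibble(time = c(0, object$time), survival = c(1, object$survival))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$survival)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Time (months)", y = "Survival probability",
                  subtitle = sprintf("n = %d at risk at t = 0", n0)) +
    ggplot2::theme_minimal()
}

#' Two-group log-rank test
#'
#' Observed-minus-expected event counts with the hypergeometric variance at
#' each distinct pooled event time; the statistic `(O - E)^2 / V` is
#' referred to a chi-square distribution with 1 df (two-sided).
#'
#' @param times_a,events_a Follow-up and 0/1 events for group A.
#' @param times_b,events_b Follow-up and 0/1 events for group B.
#' @return A `sighub_test` additionally carrying `observed_a`, `expected_a`
#'   and `variance` (O, E, V for group A).
#' @export
logrank_test <- function(times_a, events_a, times_b, events_b) {
  check_surv_input(times_a, events_a)
  check_surv_input(times_b, events_b)
  if (sum(events_a) + sum(events_b) == 0) {
    stop_degenerate("no events in either group")
  }
  times <- c(times_a, times_b)
  events <- c(events_a, events_b)
  grp_a <- c(rep(TRUE, length(times_a)), rep(FALSE, length(times_b)))
  ev_times <- sort(unique(times[events == 1]))
  O <- E <- V <- 0
  for (tt in ev_times) {
    at_risk <- times >= tt
    nj <- sum(at_risk)
    n1j <- sum(at_risk & grp_a)
    dead <- times == tt & events == 1
    dj <- sum(dead)
    d1j <- sum(dead & grp_a)
    O <- O + d1j
    E <- E + dj * n1j / nj
    if (nj > 1) {
      V <- V + dj * (n1j / nj) * (1 - n1j / nj) * (nj - dj) / (nj - 1)
    }
  }
  if (V == 0) {
    # identical groups with every subject tied: no information, p = 1
    return(new_test_result(0, 1, 1, "Log-rank test",
                           observed_a = O, expected_a = E, variance = V))
  }
  stat <- (O - E)^2 / V
  p <- pchisq(stat, df = 1, lower.tail = FALSE)
  new_test_result(stat, 1, p, "Log-rank test",
                  observed_a = O, expected_a = E, variance = V)
}

#' Deterministic 50:50 (or percentile) split
#'
#' Samples strictly above the cutpoint go to `high`, strictly below to
#' `low`; values equal to the cutpoint are assigned to `low` first (in input
#' order) until `low` reaches `ceiling(n * p)`, the remainder to `high`.
#' This makes the two halves as balanced as ties allow and is stable under
#' reordering-free reruns.
#'
#' @param values Numeric vector, `n >= 2`.
#' @param percentile Split point as a percentage (default 50, the median).
#' @return Factor with levels `low`, `high`, aligned with `values`.
#' @export
median_split <- function(values, percentile = 50) {
  if (length(values) < 2) stop_param("need at least 2 values to split")
  if (anyNA(values)) stop_param("missing values are not allowed")
  if (length(unique(values)) < 2) {
    stop_degenerate("all values identical; split undefined")
  }
  p <- percentile / 100
  if (p <= 0 || p >= 1) stop_param("percentile must be in (0, 100)")
  cut <- unname(quantile(values, p, type = 7))
  lab <- rep(NA_character_, length(values))
  lab[values > cut] <- "high"
  lab[values < cut] <- "low"
  target_low <- ceiling(length(values) * p)
  ties <- which(values == cut)
  for (i in ties) {
    lab[i] <- if (sum(lab == "low", na.rm = TRUE) < target_low) "low" else "high"
  }
  factor(lab, levels = c("low", "high"))
}

# Efron partial-likelihood pieces for a single covariate at coefficient
# beta. Returns loglik, score U, information I. Data must be pre-sorted by
# time; `first`/`count` index tied-event blocks.
cox_eval <- function(beta, x, times, events) {
  n <- length(x)
  eta <- beta * x
  theta <- exp(eta)
  # risk-set sums via reverse cumulative sums over times sorted increasing
  r0 <- rev(cumsum(rev(theta)))
  r1 <- rev(cumsum(rev(theta * x)))
  r2 <- rev(cumsum(rev(theta * x^2)))
  ll <- 0; U <- 0; I <- 0
  i <- 1L
  while (i <= n) {
    j <- i
    while (j < n && times[j + 1L] == times[i]) j <- j + 1L
    d_idx <- i:j
    d_idx <- d_idx[events[d_idx] == 1]
    d <- length(d_idx)
    if (d > 0) {
      s0 <- sum(theta[d_idx]); s1 <- sum(theta[d_idx] * x[d_idx])
      s2 <- sum(theta[d_idx] * x[d_idx]^2)
      ll <- ll + sum(eta[d_idx])
      U <- U + sum(x[d_idx])
      for (l in seq_len(d) - 1L) {
        f <- l / d
        phi0 <- r0[i] - f * s0
        phi1 <- r1[i] - f * s1
        phi2 <- r2[i] - f * s2
        ll <- ll - log(phi0)
        U <- U - phi1 / phi0
        I <- I + phi2 / phi0 - (phi1 / phi0)^2
      }
    }
    i <- j + 1L
  }
  list(loglik = ll, score = U, info = I)
}

#' Univariate Cox proportional-hazards fit
#'
#' Maximizes the partial likelihood for a single covariate by
#' Newton-Raphson with step-halving, using the Efron approximation for tied
#' event times. Non-convergence is reported through `converged = FALSE`,
#' never as an error.
#'
#' @param times,events Follow-up times and 0/1 event indicators.
#' @param covariate Numeric covariate with nonzero variance.
#' @param max_iter Maximum Newton iterations (default 30).
#' @param tol Convergence tolerance on the coefficient step (default 1e-9).
#' @param min_events Minimum number of events required (default 5).
#' @return A `sighub_cox` object: `beta`, `se`, `hr`, `ci95`, `p_value`
#'   (Wald, two-sided), `n`, `n_events`, `loglik`, `score_chisq_0` (score
#'   test at beta = 0), `converged`, `iterations`.
#' @export
cox_univariate <- function(times, events, covariate,
                           max_iter = 30, tol = 1e-9, min_events = 5) {
  check_surv_input(times, events)
  if (length(covariate) != length(times)) stop_param("covariate length mismatch")
  if (anyNA(covariate)) stop_param("missing covariate values")
  if (var(covariate) == 0) stop_degenerate("constant covariate")
  if (sum(events) < min_events) {
    stop_degenerate(sprintf("fewer than %d events", min_events))
  }
  o <- order(times)
  t_s <- times[o]; e_s <- events[o]
  x_c <- covariate[o] - mean(covariate)
  x_scale <- sd(x_c)
  x_s <- x_c / x_scale

  ev0 <- cox_eval(0, x_s, t_s, e_s)
  score_chisq_0 <- ev0$score^2 / ev0$info
  beta <- 0
  ll <- ev0$loglik
  ev <- ev0
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    step <- ev$score / ev$info
    new_beta <- beta + step
    new_ev <- cox_eval(new_beta, x_s, t_s, e_s)
    halvings <- 0L
    while (new_ev$loglik < ll && halvings < 20L) {
      step <- step / 2
      new_beta <- beta + step
      new_ev <- cox_eval(new_beta, x_s, t_s, e_s)
      halvings <- halvings + 1L
    }
    done <- abs(step) < tol || abs(new_ev$loglik - ll) < tol
    beta <- new_beta; ll <- new_ev$loglik; ev <- new_ev
    if (done) { converged <- TRUE; break }
  }
  beta_raw <- beta / x_scale
  se_raw <- 1 / sqrt(ev$info) / x_scale
  z <- qnorm(0.975)
  structure(
    list(beta = beta_raw, se = se_raw, hr = exp(beta_raw),
         ci95 = c(lo = exp(beta_raw - z * se_raw),
                  hi = exp(beta_raw + z * se_raw)),
         p_value = 2 * pt(-abs(beta_raw / se_raw), df = Inf),
         n = length(t_s), n_events = sum(e_s), loglik = ll,
         score_chisq_0 = score_chisq_0,
         converged = converged, iterations = iter),
    class = "sighub_cox"
  )
}

#' @export
print.sighub_cox <- function(x, ...) {
  cat("Univariate Cox proportional-hazards fit\n")
  cat(sprintf("  n = %d, events = %d\n", x$n, x$n_events))
  cat(sprintf("  beta = %.4f (se %.4f), HR = %.3f [%.3f, %.3f], p = %s\n",
              x$beta, x$se, x$hr, x$ci95[["lo"]], x$ci95[["hi"]],
              format.pval(x$p_value, digits = 4)))
  if (!x$converged) cat("  WARNING: Newton-Raphson did not converge\n")
  invisible(x)
}

#' @export
tidy.sighub_cox <- function(x, ...) {
  tibble(term = "covariate", estimate = x$beta, std.error = x$se,
         hazard.ratio = x$hr, conf.low = x$ci95[["lo"]],
         conf.high = x$ci95[["hi"]], p.value = x$p_value)
}

#' @export
glance.sighub_cox <- function(x, ...) {
  tibble(n = x$n, n.events = x$n_events, logLik = x$loglik,
         score.chisq = x$score_chisq_0, converged = x$converged,
         iterations = x$iterations)
}
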