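## Evidence-synthesis utilities used to build the model's survival inputs:
## pseudo individual patient data (IPD) reconstruction from a digitized
## Kaplan-Meier curve with its numbers-at-risk table, Weibull fitting with a
## parameter covariance, the spliced-curve derivation of the turnaround-time
## (TAT) hazard ratio, and log-linear HR rescaling between TAT differences.

#' Construct a digitized Kaplan-Meier curve
#'
#' @param time Digitized times in years, ascending, starting at 0.
#' @param survival Survival probabilities, non-increasing from at most 1.
#' @param risk_time Times of the numbers-at-risk table (first must be 0).
#' @param risk_n Numbers at risk, non-increasing positive integers.
#' @return An object of class `digitized_km`.
#' @export
digitized_km <- function(time, survival, risk_time, risk_n) {
  if (length(time) != length(survival))
    stop_config("digitized_km: time and survival differ in length")
  if (is.unsorted(time) || any(time < 0))
    stop_config("digitized_km: times must be ascending and non-negative")
  if (survival[1] > 1 + 1e-9 || any(diff(survival) > 1e-9))
    stop_config("digitized_km: survival must be non-increasing from at most 1")
  if (length(risk_time) != length(risk_n) || length(risk_n) < 1)
    stop_config("digitized_km: risk table requires at least one row")
  if (any(diff(risk_n) > 0))
    stop_config("digitized_km: numbers at risk must be non-increasing")
  structure(list(time = time, survival = pmin(survival, 1),
                 risk_time = risk_time, risk_n = risk_n),
            class = "digitized_km")
}

#' Write / read a digitized curve as delimited text
#'
#' Two tab-separated blocks: the digitized coordinates and the
#' numbers-at-risk table, separated by a `# numbers at risk` marker.
#'
#' @param curve A [digitized_km()].
#' @param path File path.
#' @return `path` invisibly ([write_km_curve()]); a `digitized_km`
#'   ([read_km_curve()]).
#' @export
write_km_curve <- function(curve, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# digitized KM curve: time\tsurvival", con)
  writeLines(sprintf("%.10g\t%.10g", curve$time, curve$survival), con)
  writeLines("# numbers at risk: time\tn", con)
  writeLines(sprintf("%.10g\t%d", curve$risk_time, as.integer(curve$risk_n)), con)
  invisible(path)
}

#' @rdname write_km_curve
#' @export
read_km_curve <- function(path) {
  lines <- readLines(path)
  marker <- grep("^# numbers at risk", lines)
  if (length(marker) != 1) stop_config("read_km_curve: missing numbers-at-risk block")
  parse_block <- function(x) {
    x <- x[!grepl("^#", x) & nzchar(x)]
    do.call(rbind, lapply(strsplit(x, "\t"), as.numeric))
  }
  km <- parse_block(lines[seq_len(marker - 1)])
  rt <- parse_block(lines[marker:length(lines)])
  digitized_km(km[, 1], km[, 2], rt[, 1], rt[, 2])
}

#' Reconstruct pseudo individual patient data from a digitized KM curve
#'
#' Interval-wise reconstruction: within each interval of the numbers-at-risk
#' table, censoring times are spread uniformly and their count adjusted until
#' the implied number at risk at the start of the next interval matches the
#' published number; event counts at each digitized time are chosen so the
#' reconstructed Kaplan-Meier estimator tracks the digitized survival. After
#' the last risk-table interval, events follow the digitized drops and all
#' remaining subjects are censored at the last digitized time.
#'
#' @param curve A [digitized_km()].
#' @return A data frame of class `pseudo_ipd` with columns `time` (years) and
#'   `event` (1 event, 0 censored).
#' @export
reconstruct_pseudo_ipd <- function(curve) {
  tt <- curve$time
  ss <- curve$survival
  if (tt[1] > 0) {  # anchor at (0, 1)
    tt <- c(0, tt)
    ss <- c(1, ss)
  }
  np <- length(tt)
  rt <- curve$risk_time
  rn <- curve$risk_n
  nint <- length(rt)
  # index of first digitized point at or after each risk time
  lower <- vapply(rt, function(x) which(tt >= x - 1e-12)[1], integer(1))
  if (anyNA(lower)) stop_config("risk table extends beyond the digitized curve")

  ev_times <- numeric(0); cn_times <- numeric(0)
  n_at_risk <- rn[1]
  km_prev <- 1      # reconstructed KM value at the previous digitized point
  i_cur <- 1

  for (j in seq_len(nint)) {
    i_end <- if (j < nint) lower[j + 1] - 1 else np
    i_start <- i_cur + (j == 1)  # skip the (0,1) anchor point
    idx <- if (i_start > i_end) integer(0) else seq.int(i_start, i_end)
    t_lo <- rt[j]
    t_hi <- if (j < nint) rt[j + 1] else tt[np]
    target_next <- if (j < nint) rn[j + 1] else NA

    ## Allocate `nc` censoring times evenly over the interval; censors falling
    ## before a digitized time leave the risk set before its events.
    solve_interval <- function(nc) {
      ct <- if (nc > 0) t_lo + seq_len(nc) * (t_hi - t_lo) / (nc + 1) else numeric(0)
      n <- n_at_risk
      km <- km_prev
      d_out <- numeric(length(idx))
      prev_t <- t_lo
      for (q in seq_along(idx)) {
        i <- idx[q]
        n <- n - sum(ct > prev_t & ct < tt[i])
        d_q <- if (km > 0 && n > 0) round(n * (1 - ss[i] / km)) else 0
        d_q <- max(0, min(d_q, n))
        if (d_q > 0) km <- km * (1 - d_q / n)
        n <- n - d_q
        d_out[q] <- d_q
        prev_t <- tt[i]
      }
      n <- n - sum(ct >= prev_t)
      list(n_end = n, d = d_out, ct = ct, km = km)
    }

    if (j < nint) {
      ## iterate the censor count until the implied number at risk at the
      ## start of the next interval matches the published number
      nc <- max(0, n_at_risk - target_next)
      res <- solve_interval(nc)
      for (iter in 1:100) {
        gap <- res$n_end - target_next
        if (gap == 0) break
        nc_new <- max(0, min(n_at_risk, nc + gap))
        if (nc_new == nc) break
        nc <- nc_new
        res <- solve_interval(nc)
      }
    } else {
      res <- solve_interval(0)
    }

    for (q in seq_along(idx)) {
      i <- idx[q]
      if (res$d[q] > 0) {
        ## the observed drop at t_i collects events from (t_{i-1}, t_i];
        ## place them at the interval midpoint to avoid a half-step late bias
        mid <- if (i > 1) (tt[i - 1] + tt[i]) / 2 else tt[i]
        ev_times <- c(ev_times, rep(mid, res$d[q]))
      }
    }
    if (length(res$ct)) cn_times <- c(cn_times, res$ct)
    n_at_risk <- res$n_end   # carry forward: subject count stays conserved
    km_prev <- res$km
    i_cur <- i_end + 1
  }

  # subjects still at risk after the last digitized time are censored there
  if (n_at_risk > 0) cn_times <- c(cn_times, rep(tt[np], n_at_risk))

  out <- data.frame(time = c(ev_times, cn_times),
                    event = c(rep(1L, length(ev_times)), rep(0L, length(cn_times))))
  out <- out[order(out$time, -out$event), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("pseudo_ipd", "data.frame")
  out
}

#' Fit a Weibull survival model to (pseudo) IPD
#'
#' Maximum-likelihood Weibull fit with standard errors and parameter
#' correlation from the observed information, reported in the model's survival
#' parameter convention (`log_scale` is the log of the rate-like scale,
#' `shape` is the log shape).
#'
#' @param ipd Data frame with columns `time` and `event`.
#' @return A list of class `weibull_fit`: `log_scale`, `log_scale_se`,
#'   `shape`, `shape_se`, `correlation`, `n`, `n_events`, `loglik`.
#' @export
fit_weibull <- function(ipd) {
  n_events <- sum(ipd$event == 1)
  if (n_events < 2)
    stop_config("fit_weibull: at least 2 events required (got %d); model not identifiable",
                n_events)
  fit <- flexsurv::flexsurvreg(survival::Surv(time, event) ~ 1, data = ipd,
                               dist = "weibull")
  # flexsurv weibull: S(t) = exp(-(t / b)^a); estimates on log scale in res.t.
  # Our convention: log_scale = log(1/b) = -log(b); shape = log(a).
  est <- fit$res.t[, "est"]
  se <- fit$res.t[, "se"]
  v <- fit$cov  # covariance of (log shape, log scale)
  rho <- v["shape", "scale"] / sqrt(v["shape", "shape"] * v["scale", "scale"])
  structure(list(
    log_scale = unname(-est["scale"]),
    log_scale_se = unname(se["scale"]),
    shape = unname(est["shape"]),
    shape_se = unname(se["shape"]),
    correlation = unname(-rho),  # sign flips with log_scale = -log(b)
    n = nrow(ipd), n_events = n_events, loglik = fit$loglik
  ), class = "weibull_fit")
}

weibull_rate_shape <- function(fit) {
  if (inherits(fit, c("weibull_fit", "weibull_curve")) || is.list(fit))
    c(lambda = exp(fit$log_scale), k = exp(fit$shape))
  else stop_config("expected a weibull_fit-like object")
}

#' Turnaround-time hazard ratio from spliced survival curves
#'
#' Derives the HR associated with faster treatment initiation: patients are
#' assumed to experience best-supportive-care (BSC) mortality during the
#' diagnostic turnaround time and therapy mortality thereafter (therapy clock
#' starting at initiation). Two spliced curves are built - one per turnaround
#' time - pseudo patient-level data are generated from each by inverse-CDF
#' sampling, and a proportional-hazards model with a group indicator estimates
#' the HR of the shorter versus longer turnaround time.
#'
#' @param bsc_fit,therapy_fit `weibull_fit`-like objects (elements `log_scale`
#'   and `shape`) for BSC and on-therapy survival.
#' @param tat_short_weeks,tat_long_weeks Turnaround times in weeks,
#'   `tat_short_weeks <= tat_long_weeks`.
#' @param n Subjects sampled per arm.
#' @return The estimated hazard ratio (short versus long; < 1 when faster
#'   initiation is beneficial). Exactly 1 when the turnaround times are equal.
#' @export
tat_splice_hr <- function(bsc_fit, therapy_fit, tat_short_weeks = 1.5,
                          tat_long_weeks = 4.5, n = 10000) {
  if (tat_short_weeks > tat_long_weeks)
    stop_config("tat_splice_hr: tat_short_weeks must be <= tat_long_weeks")
  if (tat_short_weeks == tat_long_weeks) return(1)
  b <- weibull_rate_shape(bsc_fit)
  th <- weibull_rate_shape(therapy_fit)
  sample_spliced <- function(tau, u) {
    s_tau <- exp(-(b["lambda"] * tau)^b["k"])
    t_bsc <- (-log(u))^(1 / b["k"]) / b["lambda"]
    t_ther <- tau + (-log(u / s_tau))^(1 / th["k"]) / th["lambda"]
    ifelse(u >= s_tau, t_bsc, t_ther)
  }
  u1 <- stats::runif(n)
  u2 <- stats::runif(n)
  tau_s <- tat_short_weeks / 52
  tau_l <- tat_long_weeks / 52
  d <- data.frame(
    time = c(sample_spliced(tau_s, u1), sample_spliced(tau_l, u2)),
    event = 1L,
    short = rep(c(1L, 0L), each = n)
  )
  fit <- survival::coxph(survival::Surv(time, event) ~ short, data = d)
  unname(exp(stats::coef(fit)))
}

#' Rescale a hazard ratio to a different turnaround-time difference
#'
#' Assumes a log-linear relationship between the log HR and the time-to-
#' treatment difference: `exp(log(hr) * weeks_to / weeks_from)`.
#'
#' @param hr Hazard ratio (> 0) associated with a `weeks_from`-week difference.
#' @param weeks_from,weeks_to Positive turnaround-time differences in weeks.
#' @return The rescaled hazard ratio.
#' @export
#' @examples
#' rescale_hr_loglinear(0.72, 3, 1)  # ~0.90
rescale_hr_loglinear <- function(hr, weeks_from, weeks_to) {
  if (hr <= 0 || weeks_from <= 0 || weeks_to <= 0)
    stop_config("rescale_hr_loglinear: all inputs must be positive")
  exp(log(hr) * weeks_to / weeks_from)
}
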