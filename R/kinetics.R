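#' Construct a fluorescence exchange-kinetics trace
#'
#' A mant-GDP exchange time course: fluorescence recorded during a flat
#' pre-reaction baseline (typically ~300 s), followed by the decay after
#' the exchange reaction is started by reagent addition. The reaction
#' start time is explicit metadata — it is known from the experiment,
#' and guessing it from the data risks silent misalignment.
#'
#' @param time_s strictly increasing timestamps, seconds.
#' @param signal fluorescence, arbitrary units.
#' @param t_reaction_start_s time of reagent addition (within the range).
#' @param condition `"intrinsic"`, `"gef"` or `"edta"`.
#' @param gtpase,gef free-text labels.
#' @param gef_conc_uM GEF concentration, micromolar.
#' @param normalized internal flag set by [normalize_trace()].
#' @return object of class `kinetic_trace`.
#' @export
kinetic_trace <- function(time_s, signal, t_reaction_start_s,
                          condition = c("intrinsic", "gef", "edta"),
                          gtpase = "", gef = "", gef_conc_uM = NA_real_,
                          normalized = FALSE) {
  condition <- match.arg(condition)
  stopifnot(length(time_s) == length(signal), length(time_s) >= 2)
  if (any(diff(time_s) <= 0)) stop("timestamps must be strictly increasing")
  if (t_reaction_start_s <= min(time_s) || t_reaction_start_s > max(time_s)) {
    stop("t_reaction_start_s must lie within the recorded time range, with a baseline before it")
  }
  structure(list(time_s = as.numeric(time_s), signal = as.numeric(signal),
                 t_reaction_start_s = t_reaction_start_s,
                 condition = condition, gtpase = gtpase, gef = gef,
                 gef_conc_uM = gef_conc_uM, normalized = normalized),
            class = "kinetic_trace")
}

#' @export
print.kinetic_trace <- function(x, ...) {
  cat(sprintf("<kinetic_trace> %s%s: %d samples over %.0f s, reaction at %.0f s%s\n",
              x$condition,
              if (nzchar(x$gtpase)) paste0(" (", x$gtpase, ")") else "",
              length(x$time_s), diff(range(x$time_s)), x$t_reaction_start_s,
              if (x$normalized) ", normalized" else ""))
  invisible(x)
}

#' Read a trace from CSV plus a metadata sidecar
#'
#' The CSV must have columns `time_s` and `signal`; metadata
#' (`t_reaction_start_s`, `condition`, labels) comes from a YAML or JSON
#' sidecar, or can be passed directly.
#'
#' @param path CSV file.
#' @param metadata path to a YAML/JSON sidecar, or a named list.
#' @return a `kinetic_trace`.
#' @export
read_trace_csv <- function(path, metadata) {
  tab <- utils::read.csv(path)
  if (!all(c("time_s", "signal") %in% names(tab))) {
    stop("trace CSV needs columns time_s and signal")
  }
  md <- if (is.character(metadata)) {
    if (grepl("\\.json$", metadata)) jsonlite::read_json(metadata, simplifyVector = TRUE)
    else yaml::read_yaml(metadata)
  } else metadata
  kinetic_trace(tab$time_s, tab$signal,
                t_reaction_start_s = md$t_reaction_start_s,
                condition = md$condition %||% "intrinsic",
                gtpase = md$gtpase %||% "", gef = md$gef %||% "",
                gef_conc_uM = md$gef_conc_uM %||% NA_real_)
}

#' Write a trace to CSV plus a YAML metadata sidecar
#' @param x a `kinetic_trace`.
#' @param path CSV output path; metadata goes to `<path>.yaml`.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(x, path) {
  utils::write.csv(data.frame(time_s = x$time_s, signal = x$signal),
                   path, row.names = FALSE)
  yaml::write_yaml(list(t_reaction_start_s = x$t_reaction_start_s,
                        condition = x$condition, gtpase = x$gtpase,
                        gef = x$gef, gef_conc_uM = x$gef_conc_uM),
                   paste0(path, ".yaml"))
  invisible(path)
}

#' Normalize a trace by its pre-reaction baseline
#'
#' Divides every signal value by the mean signal inside the baseline
#' window (the `baseline_window_s` seconds preceding the reaction
#' start, 300 s by default), so the normalized baseline averages 1.
#'
#' @param x a `kinetic_trace`.
#' @param baseline_window_s window length before the reaction start, s.
#' @return the normalized `kinetic_trace`.
#' @export
normalize_trace <- function(x, baseline_window_s = 300) {
  stopifnot(inherits(x, "kinetic_trace"))
  in_window <- x$time_s >= (x$t_reaction_start_s - baseline_window_s) &
    x$time_s < x$t_reaction_start_s
  if (sum(in_window) < 3) {
    stop("baseline window holds fewer than 3 samples before the reaction start")
  }
  base <- mean(x$signal[in_window])
  if (base <= 0) stop("baseline mean is zero or negative; cannot normalize")
  out <- x
  out$signal <- x$signal / base
  out$normalized <- TRUE
  out
}

#' Fit the decay phase of a normalized trace to a mono-exponential
#'
#' Nonlinear least squares of
#' `f(t') = (a0 - a_plateau) * exp(-k_obs * t') + a_plateau`
#' on the decay phase only (`t >= t_reaction_start_s`, shifted so the
#' reaction starts at t' = 0). Initialization uses variable projection:
#' for fixed `k_obs` the model is linear in `a0` and `a_plateau`, so the
#' profiled sum of squares is minimized over a log-spaced rate grid and
#' refined before the full nonlinear fit. A trace without a detectable decay (the
#' signature of a GEF-inactive arm, or an unstarted reaction) is not an
#' error: it returns `k_obs = 0` with `converged = FALSE` and
#' `no_decay = TRUE`.
#'
#' @param x a normalized `kinetic_trace` (see [normalize_trace()]).
#' @param skip_s seconds to mask after the reaction start (mixing
#'   artifact; default 0).
#' @return object of class `exchange_fit` with `a0`, `a_plateau`,
#'   `k_obs` (per second), `se` (named standard errors), `sse`,
#'   `converged`, `no_decay`, and the fitted data.
#' @export
fit_monoexponential <- function(x, skip_s = 0) {
  stopifnot(inherits(x, "kinetic_trace"))
  sel <- x$time_s >= (x$t_reaction_start_s + skip_s)
  tp <- x$time_s[sel] - x$t_reaction_start_s
  y <- x$signal[sel]
  if (length(y) < 10) stop("need at least 10 samples in the decay phase")

  n_tail <- max(3L, ceiling(0.1 * length(y)))
  tail_y <- y[(length(y) - n_tail + 1):length(y)]
  head_y <- y[seq_len(min(10L, length(y)))]
  noise <- stats::sd(tail_y)
  no_decay <- (mean(head_y) - mean(tail_y)) <= max(3 * noise, 1e-12)
  blank <- function(flag) {
    structure(list(a0 = mean(y), a_plateau = mean(y), k_obs = 0,
                   se = c(a0 = NA_real_, a_plateau = NA_real_, k_obs = NA_real_),
                   sse = sum((y - mean(y))^2), converged = FALSE,
                   no_decay = flag, n = length(y),
                   time_s = tp, signal = y, fitted = rep(mean(y), length(y))),
              class = "exchange_fit")
  }
  if (no_decay) return(blank(TRUE))

  # initialization by variable projection: for fixed k the model is linear
  # in (a0, a_plateau), so profile the SSE over a log-spaced k grid and
  # refine; robust from slow, plateau-free decays up to near-instant ones
  lin_sse <- function(k) {
    f <- stats::lm.fit(cbind(1, exp(-k * tp)), y)
    sum(f$residuals^2)
  }
  grid <- 10^seq(-6, 0.5, length.out = 40)
  k0 <- grid[which.min(vapply(grid, lin_sse, numeric(1)))]
  opt <- stats::optimize(function(lk) lin_sse(exp(lk)),
                         interval = log(k0) + c(-2, 2))
  k0 <- exp(opt$minimum)
  lin <- stats::lm.fit(cbind(1, exp(-k0 * tp)), y)
  ap0 <- unname(lin$coefficients[1])
  a00 <- ap0 + unname(lin$coefficients[2])
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ (a0 - ap) * exp(-k * tp) + ap,
                      start = list(a0 = a00, ap = ap0, k = k0),
                      lower = c(-Inf, -Inf, 0),
                      control = minpack.lm::nls.lm.control(
                        maxiter = 500, ftol = 1e-10)),
    error = function(e) NULL)
  if (is.null(fit)) return(blank(FALSE))
  cf <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, 3))
  structure(list(a0 = unname(cf["a0"]), a_plateau = unname(cf["ap"]),
                 k_obs = unname(cf["k"]),
                 se = c(a0 = unname(se[1]), a_plateau = unname(se[2]),
                        k_obs = unname(se[3])),
                 sse = sum(stats::residuals(fit)^2),
                 converged = fit$convInfo$isConv %||% TRUE,
                 no_decay = FALSE, n = length(y),
                 time_s = tp, signal = y,
                 fitted = stats::fitted(fit)),
            class = "exchange_fit")
}

#' @export
print.exchange_fit <- function(x, ...) {
  if (x$no_decay) {
    cat("<exchange_fit> no detectable decay: k_obs = 0 (flagged, not fitted)\n")
  } else {
    cat(sprintf("<exchange_fit> k_obs = %.4g /s (se %.2g), a0 = %.4g, plateau = %.4g%s\n",
                x$k_obs, x$se["k_obs"], x$a0, x$a_plateau,
                if (!x$converged) " [NOT CONVERGED]" else ""))
  }
  invisible(x)
}

#' @export
coef.exchange_fit <- function(object, ...) {
  c(a0 = object$a0, a_plateau = object$a_plateau, k_obs = object$k_obs)
}

#' @export
predict.exchange_fit <- function(object, newdata = NULL, ...) {
  tp <- if (is.null(newdata)) object$time_s else newdata
  (object$a0 - object$a_plateau) * exp(-object$k_obs * tp) + object$a_plateau
}

#' @export
residuals.exchange_fit <- function(object, ...) {
  object$signal - object$fitted
}

#' Classify GEF activation against intrinsic exchange
#'
#' Compares observed exchange rates between a GEF arm and an intrinsic
#' (GTPase alone) arm: `fold = mean k_obs(GEF) / mean k_obs(intrinsic)`.
#' The 95% confidence interval of the fold comes from a nonparametric
#' bootstrap over replicate fits when each arm has at least 3
#' replicates, otherwise from delta-method propagation of the fit
#' standard errors. Decision rule: `"active"` when fold >= threshold and
#' the CI excludes 1; `"inactive"` when the CI upper bound is below the
#' threshold; otherwise `"indeterminate"`. An intrinsic arm with no
#' detectable decay gives `"indeterminate"` (the fold is undefined).
#'
#' @param gef_fits,intrinsic_fits lists of `exchange_fit`s (replicates).
#' @param fold_threshold minimum fold counted as activation (default 2).
#' @param conf confidence level.
#' @param n_boot bootstrap resamples.
#' @param seed optional integer seed for the bootstrap.
#' @return object of class `activation_call`: `fold`, `ci`, `call`,
#'   `k_gef`, `k_intrinsic`.
#' @export
classify_activation <- function(gef_fits, intrinsic_fits,
                                fold_threshold = 2, conf = 0.95,
                                n_boot = 2000, seed = NULL) {
  if (inherits(gef_fits, "exchange_fit")) gef_fits <- list(gef_fits)
  if (inherits(intrinsic_fits, "exchange_fit")) intrinsic_fits <- list(intrinsic_fits)
  if (!length(gef_fits) || !length(intrinsic_fits)) stop("empty arm")
  kg <- vapply(gef_fits, `[[`, 0, "k_obs")
  ki <- vapply(intrinsic_fits, `[[`, 0, "k_obs")
  result <- function(fold, ci, call) {
    structure(list(fold = fold, ci = ci, call = call,
                   k_gef = kg, k_intrinsic = ki,
                   fold_threshold = fold_threshold),
              class = "activation_call")
  }
  if (mean(ki) <= 0) {
    return(result(NA_real_, c(NA_real_, NA_real_), "indeterminate"))
  }
  fold <- mean(kg) / mean(ki)
  alpha <- 1 - conf
  if (length(kg) >= 3 && length(ki) >= 3) {
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
      set.seed(seed)
    }
    boots <- replicate(n_boot, {
      bg <- mean(sample(kg, replace = TRUE))
      bi <- mean(sample(ki, replace = TRUE))
      if (bi <= 0) NA_real_ else bg / bi
    })
    ci <- unname(stats::quantile(boots, c(alpha / 2, 1 - alpha / 2), na.rm = TRUE))
  } else {
    se_mean <- function(fits, k) {
      if (length(k) > 1) stats::sd(k) / sqrt(length(k))
      else {
        s <- fits[[1]]$se["k_obs"]
        if (is.na(s)) 0 else unname(s)
      }
    }
    sg <- se_mean(gef_fits, kg)
    si <- se_mean(intrinsic_fits, ki)
    se_fold <- fold * sqrt((sg / mean(kg))^2 + (si / mean(ki))^2)
    z <- stats::qnorm(1 - alpha / 2)
    ci <- c(max(fold - z * se_fold, 0), fold + z * se_fold)
  }
  call <- if (fold >= fold_threshold && (ci[1] > 1 || ci[2] < 1)) {
    "active"
  } else if (ci[2] < fold_threshold) {
    "inactive"
  } else {
    "indeterminate"
  }
  result(fold, ci, call)
}

#' @export
print.activation_call <- function(x, ...) {
  cat(sprintf("<activation_call> fold = %.3g [%.3g, %.3g] vs threshold %g -> %s\n",
              x$fold, x$ci[1], x$ci[2], x$fold_threshold, toupper(x$call)))
  invisible(x)
}
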