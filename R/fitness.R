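#' Competitive success of a mutant in pairwise competition
#'
#' Defined as the mutant frequency after the competition divided by its
#' realized initial frequency; `S = 1` is neutrality, `S > 1` a relative
#' benefit. Scale-free: multiplying both spore tallies behind `f_final` by a
#' constant leaves `S` unchanged.
#'
#' @param f_final Mutant frequency after competition, in `[0, 1]`.
#' @param f_initial Realized initial mutant frequency, in `(0, 1]`.
#' @return `S = f_final / f_initial`. Vectorised.
#' @examples
#' competitive_success(0.2, 0.1)  # 2
#' @export
competitive_success <- function(f_final, f_initial) {
  if (any(f_initial <= 0)) {
    stop("competitive success is undefined at zero initial frequency",
         call. = FALSE)
  }
  if (any(f_final < 0 | f_final > 1) || any(f_initial > 1)) {
    stop("frequencies must lie in [0, 1]", call. = FALSE)
  }
  f_final / f_initial
}

#' Fit frequency dependence of competitive success
#'
#' Regresses a transform of competitive success `S` on the realized initial
#' frequency and locates the equilibrium frequency, i.e. the frequency at
#' which the fitted curve predicts `S = 1` (neutrality). The default
#' transform fits `log(S)` linearly in `f_initial`, under which the
#' equilibrium is the zero crossing of the fitted line; a quadratic-in-f
#' option is available since the true functional form of the trend is not
#' identified by the assay. Confidence bounds come from a nonparametric
#' bootstrap over competition records.
#'
#' The equilibrium is reported as the smallest root of `S = 1` inside the
#' observed initial-frequency range; when the fitted curve does not cross 1
#' in range (all-advantage, all-disadvantage, or a flat fit), it is `NA`
#' with a reason.
#'
#' @param records Tibble with columns `f_initial`, `f_final` (one row per
#'   competition replicate); at least 3 distinct initial frequencies.
#' @param transform `"log"` (default) or `"quadratic"` (quadratic in
#'   `f_initial` on the log-S scale).
#' @param n_boot Bootstrap resamples for the equilibrium confidence interval
#'   (default 1000; 0 disables).
#' @param conf Confidence level, default 0.95.
#' @return Object of class `"freq_dep_fit"`: a list with `model` (the `lm`
#'   fit), `transform`, `coefficients`, `equilibrium`,
#'   `equilibrium_reason`, `equilibrium_ci`, `f_range`, `n`, `boot`
#'   (bootstrap equilibria).
#' @export
fit_frequency_dependence <- function(records,
                                     transform = c("log", "quadratic"),
                                     n_boot = 1000, conf = 0.95) {
  transform <- match.arg(transform)
  stopifnot(is.data.frame(records),
            all(c("f_initial", "f_final") %in% names(records)))
  records <- records[records$f_initial > 0, , drop = FALSE]
  records$S <- competitive_success(records$f_final, records$f_initial)
  usable <- records$S > 0            # log scale cannot carry extinct mutants
  if (sum(!usable) > 0) {
    warning(sum(!usable), " record(s) with S = 0 dropped from the log-scale ",
            "fit", call. = FALSE)
    records <- records[usable, , drop = FALSE]
  }
  if (length(unique(records$f_initial)) < 3) {
    stop("need at least 3 distinct initial frequencies", call. = FALSE)
  }
  f_range <- range(records$f_initial)

  fit_one <- function(d) {
    if (transform == "log") {
      stats::lm(log(S) ~ f_initial, data = d)
    } else {
      stats::lm(log(S) ~ f_initial + I(f_initial^2), data = d)
    }
  }
  # smallest root of predicted log(S) = 0 within the observed range
  root_of <- function(cf) {
    if (transform == "log") {
      b <- cf[["f_initial"]]
      if (abs(b) < 1e-10) return(NA_real_)
      r <- -cf[["(Intercept)"]] / b
      if (r >= f_range[1] && r <= f_range[2]) r else NA_real_
    } else {
      a <- cf[["I(f_initial^2)"]]; b <- cf[["f_initial"]]
      c0 <- cf[["(Intercept)"]]
      if (abs(a) < 1e-10) {
        if (abs(b) < 1e-10) return(NA_real_)
        r <- -c0 / b
        return(if (r >= f_range[1] && r <= f_range[2]) r else NA_real_)
      }
      disc <- b^2 - 4 * a * c0
      if (disc < 0) return(NA_real_)
      roots <- sort(c((-b - sqrt(disc)) / (2 * a),
                      (-b + sqrt(disc)) / (2 * a)))
      roots <- roots[roots >= f_range[1] & roots <= f_range[2]]
      if (length(roots) == 0) NA_real_ else roots[1]
    }
  }

  model <- fit_one(records)
  cf <- stats::coef(model)
  eq <- root_of(cf)
  reason <- if (!is.na(eq)) {
    "crossing_in_range"
  } else if (transform == "log" && abs(cf[["f_initial"]]) < 1e-10) {
    "flat_fit"
  } else if (all(stats::predict(model) > 0)) {
    "advantage_everywhere"
  } else if (all(stats::predict(model) < 0)) {
    "disadvantage_everywhere"
  } else {
    "no_crossing_in_range"
  }

  boot_eq <- numeric(0)
  ci <- c(NA_real_, NA_real_)
  if (n_boot > 0) {
    boot_eq <- vapply(seq_len(n_boot), function(i) {
      idx <- sample.int(nrow(records), replace = TRUE)
      d <- records[idx, , drop = FALSE]
      if (length(unique(d$f_initial)) < 3) return(NA_real_)
      root_of(stats::coef(fit_one(d)))
    }, numeric(1))
    ok <- !is.na(boot_eq)
    if (sum(ok) >= 20) {
      alpha <- (1 - conf) / 2
      ci <- unname(stats::quantile(boot_eq[ok], c(alpha, 1 - alpha)))
    }
  }

  structure(list(model = model, transform = transform,
                 coefficients = cf, equilibrium = eq,
                 equilibrium_reason = reason, equilibrium_ci = ci,
                 f_range = f_range, n = nrow(records), boot = boot_eq),
            class = "freq_dep_fit")
}

#' @export
print.freq_dep_fit <- function(x, ...) {
  cat("Frequency dependence of competitive success (", x$transform,
      " transform, n = ", x$n, ")\n", sep = "")
  cat("  coefficients:",
      paste(names(x$coefficients), signif(x$coefficients, 4),
            sep = " = ", collapse = ", "), "\n")
  if (is.na(x$equilibrium)) {
    cat("  equilibrium: absent (", x$equilibrium_reason, ")\n", sep = "")
  } else {
    cat("  equilibrium frequency (S = 1): ", signif(x$equilibrium, 4),
        sep = "")
    if (!anyNA(x$equilibrium_ci)) {
      cat("  [", signif(x$equilibrium_ci[1], 4), ", ",
          signif(x$equilibrium_ci[2], 4), "]", sep = "")
    }
    cat("\n")
  }
  invisible(x)
}

#' One-sample t-test of a ratio against a null value
#'
#' Thin wrapper over [stats::t.test()] for the pipeline's ratio tests (e.g.
#' end/start frequency ratios of a genotype across replicate heterokaryons,
#' tested against 1 = no change). Provided as glue, not novel computation.
#'
#' @param ratios Numeric vector, length >= 2.
#' @param null_value Null ratio (default 1).
#' @param alternative `"two_sided"`, `"less"`, or `"greater"`.
#' @return Tibble with `t`, `df`, `p`, `mean`.
#' @examples
#' ratio_ttest(c(0.8, 0.7, 0.9, 0.6), alternative = "less")
#' @export
ratio_ttest <- function(ratios, null_value = 1,
                        alternative = c("two_sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  if (length(ratios) < 2) stop("need at least 2 ratios", call. = FALSE)
  if (stats::sd(ratios) == 0) {
    stop("all ratios identical: zero variance, t statistic undefined",
         call. = FALSE)
  }
  tt <- stats::t.test(ratios, mu = null_value,
                      alternative = sub("two_sided", "two.sided", alternative))
  tibble::tibble(t = unname(tt$statistic), df = unname(tt$parameter),
                 p = tt$p.value, mean = unname(tt$estimate))
}

#' Scatter of competitive success against initial frequency with the fitted
#' trend
#'
#' @param fit A `"freq_dep_fit"` object.
#' @param records The records used for the fit.
#' @return A ggplot object (requires ggplot2).
#' @export
plot_frequency_dependence <- function(fit, records) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting", call. = FALSE)
  }
  records$S <- competitive_success(records$f_final, records$f_initial)
  grid <- tibble::tibble(
    f_initial = seq(fit$f_range[1], fit$f_range[2], length.out = 100)
  )
  grid$S <- exp(stats::predict(fit$model, newdata = grid))
  ggplot2::ggplot(records, ggplot2::aes(x = .data$f_initial, y = .data$S)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_line(data = grid, colour = "steelblue") +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "initial mutant frequency",
                  y = "competitive success S (log scale)")
}
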