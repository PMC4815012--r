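#' Gaussian-in-log-concentration concentration-response model
#'
#' The peaked ("Gaussian logarithmic") 4-parameter model
#' \deqn{y(x) = c + (d - c)\,\exp\!\left(-\tfrac12\left(\frac{\ln x - \ln e}{b}\right)^2\right)}
#' with baseline `c` (fixed at 1 after fold-induction normalisation), peak
#' response `d` (fold) reached at concentration `e` (uM), and log-width `b`.
#' Unlike a sigmoidal Hill curve it is non-monotonic: the response rises to a
#' maximum at `x = e` and falls again at higher concentrations, the shape
#' typical of reporters whose induction window is bounded above by overt
#' toxicity.
#'
#' @param b Log-width (non-zero; stored as its absolute value).
#' @param d Peak response in fold induction.
#' @param e Peak concentration in uM (> 0).
#' @param c Lower asymptote; defaults to 1 (normalised folds).
#' @return An object of class `gaussian_cr_model`.
#' @export
gaussian_cr_model <- function(b, d, e, c = 1) {
  if (b == 0) stop("b must be non-zero", call. = FALSE)
  if (e <= 0) stop("e must be positive", call. = FALSE)
  structure(list(b = abs(b), c = c, d = d, e = e), class = "gaussian_cr_model")
}

#' @export
print.gaussian_cr_model <- function(x, ...) {
  cat(sprintf("<gaussian_cr_model> b=%.4g c=%.4g d=%.4g e=%.4g uM", x$b, x$c,
              x$d, x$e))
  if (!is.null(x$sse)) cat(sprintf("  (SSE %.4g, converged: %s)", x$sse,
                                   x$converged))
  cat("\n")
  invisible(x)
}

#' Linear concentration-response model
#'
#' Ordinary least-squares line `fold = a0 + a1 * x`, with `x` either the
#' nominal concentration (default, control included at 0) or log10
#' concentration (control excluded, since log 0 is undefined).
#'
#' @param a0,a1 Intercept and slope.
#' @param covariate `"concentration"` or `"log10_concentration"`.
#' @return An object of class `linear_cr_model`.
#' @export
linear_cr_model <- function(a0, a1, covariate = "concentration") {
  structure(list(a0 = a0, a1 = a1, covariate = covariate),
            class = "linear_cr_model")
}

#' Evaluate a concentration-response model
#'
#' @param model A `gaussian_cr_model` or `linear_cr_model`.
#' @param x Concentrations in uM (>= 0). For the Gaussian model `x = 0`
#'   returns the baseline `c`.
#' @return Predicted fold inductions.
#' @export
predict_cr <- function(model, x) {
  UseMethod("predict_cr")
}

#' @export
predict_cr.gaussian_cr_model <- function(model, x) {
  y <- rep(model$c, length(x))
  pos <- x > 0
  y[pos] <- model$c + (model$d - model$c) *
    exp(-0.5 * ((log(x[pos]) - log(model$e)) / model$b)^2)
  y
}

#' @export
predict_cr.linear_cr_model <- function(model, x) {
  xx <- if (model$covariate == "log10_concentration") log10(x) else x
  model$a0 + model$a1 * xx
}

#' Normalise intensity records to fold induction over the solvent control
#'
#' Each embryo's mean ROI intensity is divided by the mean of the control
#' (concentration 0) embryos' means, so the control mean fold is exactly 1.
#'
#' @param records Data.frame with at least `concentration_uM` and `mean`
#'   (e.g. from [quantify_batch()]); `embryo_id` is carried through.
#' @param value_col Column holding the per-embryo intensity (default
#'   `"mean"`).
#' @return The records with a `fold_induction` column appended, of class
#'   `dose_response_dataset`.
#' @export
normalise_records <- function(records, value_col = "mean") {
  if (!value_col %in% names(records))
    stop("records lack a '", value_col, "' column", call. = FALSE)
  ctrl <- records[[value_col]][records$concentration_uM == 0]
  if (length(ctrl) == 0) stop("empty control group (concentration 0)", call. = FALSE)
  m <- mean(ctrl)
  if (m == 0) stop("zero control mean; cannot normalise", call. = FALSE)
  records$fold_induction <- records[[value_col]] / m
  class(records) <- c("dose_response_dataset", class(records))
  records
}

# one-way ANOVA via lm/anova with explicit handling of degenerate inputs
one_way_anova <- function(values, groups) {
  groups <- factor(groups)
  k <- nlevels(groups)
  if (k < 2) stop("ANOVA needs >= 2 groups", call. = FALSE)
  n <- table(groups)
  if (any(n < 2)) stop("every group needs n >= 2", call. = FALSE)
  N <- length(values)
  fit <- stats::lm(values ~ groups)
  tab <- stats::anova(fit)
  F <- tab$`F value`[1]
  p <- tab$`Pr(>F)`[1]
  if (!is.finite(F)) {
    ssb <- tab$`Sum Sq`[1]; ssw <- tab$`Sum Sq`[2]
    if (ssw <= 0 && ssb <= 1e-12 * max(1, sum(values^2))) {
      F <- 0; p <- 1                      # all values identical
    } else if (ssw <= 0) {
      F <- Inf; p <- 0                    # perfect separation
    }
  }
  list(F = F, df_between = k - 1L, df_within = N - k, p = p)
}

#' ANOVA gate for a dose series
#'
#' One-way ANOVA of fold induction across concentrations (solvent control
#' included). A chemical passes the gate, and proceeds to
#' concentration-response modelling, only when `p < alpha` (default 0.001);
#' otherwise it is classified as having no significant effect.
#'
#' @param dataset A `dose_response_dataset` (from [normalise_records()]) or
#'   any data.frame with `concentration_uM` and `fold_induction`.
#' @param alpha Significance threshold (default 0.001).
#' @return A list: `F`, `df_between`, `df_within`, `p`, `alpha`, `pass`.
#' @export
anova_gate <- function(dataset, alpha = 0.001) {
  res <- one_way_anova(dataset$fold_induction,
                       factor(dataset$concentration_uM))
  res$alpha <- alpha
  res$pass <- is.finite(res$p) && res$p < alpha
  res
}

#' Fit the Gaussian-in-log-concentration model
#'
#' Nonlinear least squares of fold induction on log concentration with the
#' baseline fixed at `c = 1`. The control observations (concentration 0)
#' define the normalisation but are excluded from the fit (log 0 is
#' undefined). Initialisation is multi-start over a deterministic grid:
#' every tested concentration as a candidate peak `e`, log-width candidates
#' spanning the dose range, and the maximum per-dose mean as the peak `d`.
#' The best-SSE converged start wins.
#'
#' @param dataset A `dose_response_dataset`.
#' @param c Fixed lower asymptote (default 1).
#' @return A `gaussian_cr_model` with extra fields `sse`, `converged`,
#'   `n_obs`, `no_induction` (peak estimate at or below baseline).
#' @export
fit_gaussian_cr <- function(dataset, c = 1) {
  x <- dataset$concentration_uM
  y <- dataset$fold_induction
  keep <- x > 0
  x <- x[keep]; y <- y[keep]
  if (length(unique(x)) < 3)
    stop("need >= 3 distinct nonzero concentrations for the Gaussian fit",
         call. = FALSE)
  lx <- log(x)
  if (diff(range(y)) < 1e-12) {
    # exactly flat response: any width/peak fits perfectly, so the peak
    # height is the common value and b/e are undefined
    out <- structure(list(b = NA_real_, c = c, d = mean(y), e = NA_real_,
                          sse = sum((y - mean(y))^2), converged = TRUE,
                          n_obs = length(y),
                          no_induction = mean(y) <= c + 1e-8),
                     class = "gaussian_cr_model")
    return(out)
  }
  dose_means <- tapply(y, x, mean)
  d0 <- max(max(dose_means), c + 0.05)
  span <- max(diff(range(lx)), 0.5)
  b_starts <- span * c(0.1, 0.25, 0.5)
  e_starts <- sort(unique(x))
  best <- NULL
  cc <- c
  for (e0 in e_starts) for (b0 in b_starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ cc + (d - cc) * exp(-0.5 * ((lx - le) / b)^2),
        start = list(b = b0, d = d0, le = log(e0)),
        lower = c(b = 1e-4, d = cc, le = min(lx) - 2 * span),
        upper = c(b = 10 * span, d = Inf, le = max(lx) + 2 * span),
        control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15,
                                             ptol = 1e-15)),
      error = function(e) NULL)
    if (is.null(fit)) next
    sse <- sum(stats::residuals(fit)^2)
    if (is.null(best) || sse < best$sse - 1e-12 * (1 + best$sse))
      best <- list(sse = sse, par = stats::coef(fit))
  }
  if (is.null(best)) {
    out <- structure(list(b = NA_real_, c = cc, d = NA_real_, e = NA_real_,
                          sse = NA_real_, converged = FALSE,
                          n_obs = length(y), no_induction = NA),
                     class = "gaussian_cr_model")
    return(out)
  }
  p <- best$par
  out <- gaussian_cr_model(b = p[["b"]], d = p[["d"]], e = exp(p[["le"]]),
                           c = cc)
  out$sse <- best$sse
  out$converged <- TRUE
  out$n_obs <- length(y)
  out$no_induction <- out$d <= cc + 1e-8
  out
}

#' Fit the linear concentration-response model
#'
#' OLS of fold induction on concentration. With the default covariate the
#' solvent control enters at concentration 0; with the log10 covariate the
#' control is excluded.
#'
#' @param dataset A `dose_response_dataset`.
#' @param covariate `"concentration"` (default) or `"log10_concentration"`.
#' @return A `linear_cr_model` with extra fields `sse` and `n_obs`.
#' @export
fit_linear_cr <- function(dataset,
                          covariate = c("concentration", "log10_concentration")) {
  covariate <- match.arg(covariate)
  x <- dataset$concentration_uM
  y <- dataset$fold_induction
  if (covariate == "log10_concentration") {
    keep <- x > 0
    x <- log10(x[keep]); y <- y[keep]
  }
  if (length(unique(x)) < 2) stop("need >= 2 distinct covariate values",
                                  call. = FALSE)
  fit <- stats::lm(y ~ x)
  cf <- stats::coef(fit)
  out <- linear_cr_model(a0 = unname(cf[1]), a1 = unname(cf[2]),
                         covariate = covariate)
  out$sse <- sum(stats::residuals(fit)^2)
  out$n_obs <- length(y)
  out
}

#' Effective concentration for a target fold induction (EC1.5)
#'
#' Inverts a fitted concentration-response curve at the effect level
#' (default 1.5-fold). The Gaussian model crosses the level twice; the
#' ascending-limb (lower-concentration) root
#' \deqn{\ln x = \ln e - |b|\sqrt{2\ln\frac{d-c}{y^*-c}}}
#' is returned, since only it is meaningful as an effective concentration.
#' It requires the fitted peak `d` to exceed the effect level. For the
#' linear model, `x = (y* - a0)/a1`, valid only for a positive slope and a
#' concentration within `[0, max_dose * 10]` when `max_dose` is supplied.
#'
#' @param model A fitted `gaussian_cr_model` or `linear_cr_model`.
#' @param effect Target fold induction (default 1.5).
#' @param max_dose Highest tested concentration, used to bound linear-model
#'   extrapolation (optional).
#' @return A list of class `ec_result`: `ec15_uM`, `effect_level`,
#'   `model_kind`, `valid`, `reason`.
#' @export
ec15 <- function(model, effect = 1.5, max_dose = NULL) {
  UseMethod("ec15")
}

ec_result <- function(ec, effect, kind, valid, reason = NA_character_) {
  structure(list(ec15_uM = ec, effect_level = effect, model_kind = kind,
                 valid = valid, reason = reason),
            class = "ec_result")
}

#' @export
ec15.gaussian_cr_model <- function(model, effect = 1.5, max_dose = NULL) {
  if (!isTRUE(model$converged %||% TRUE) || !is.finite(model$d))
    return(ec_result(NA_real_, effect, "gaussian", FALSE, "model not fitted"))
  if (effect <= model$c)
    return(ec_result(NA_real_, effect, "gaussian", FALSE,
                     "effect level at or below baseline"))
  if (model$d < effect)
    return(ec_result(NA_real_, effect, "gaussian", FALSE,
                     "peak below effect level"))
  z <- sqrt(2 * log((model$d - model$c) / (effect - model$c)))
  ec <- exp(log(model$e) - abs(model$b) * z)
  ec_result(ec, effect, "gaussian", TRUE)
}

#' @export
ec15.linear_cr_model <- function(model, effect = 1.5, max_dose = NULL) {
  if (model$a1 <= 0)
    return(ec_result(NA_real_, effect, "linear", FALSE, "non-positive slope"))
  x <- (effect - model$a0) / model$a1
  if (model$covariate == "log10_concentration") x <- 10^x
  if (x < 0)
    return(ec_result(NA_real_, effect, "linear", FALSE,
                     "negative concentration"))
  if (!is.null(max_dose) && x > 10 * max_dose)
    return(ec_result(NA_real_, effect, "linear", FALSE,
                     "extrapolates beyond 10x the tested range"))
  ec_result(x, effect, "linear", TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Analyze one chemical's dose series end to end
#'
#' Pipeline: fold-induction normalisation, ANOVA gate at `alpha`, Gaussian
#' concentration-response fit (with the linear model as fallback), and EC1.5
#' inversion. The verdict is one of `"no_effect"` (gate failed),
#' `"gaussian"` or `"linear"` (model fitted, finite EC), or
#' `"induction_without_EC"` (significant effect but no valid EC estimate).
#'
#' @param records Intensity records (one row per embryo) with columns
#'   `concentration_uM` and `mean`; if a `chemical` column holds several
#'   chemicals, pass `chemical` to pick one.
#' @param chemical Optional chemical name to subset on.
#' @param config A [run_config()]; `alpha`, `effect_level` and
#'   `fallback` are used here.
#' @param out_json Optional path for the machine-readable report.
#' @return A list of class `chemical_report`: `chemical`, `anova`, `model`,
#'   `ec`, `verdict`, `dataset`.
#' @export
analyze_chemical <- function(records, chemical = NULL, config = run_config(),
                             out_json = NULL) {
  if (!is.null(chemical)) records <- records[records$chemical == chemical, ]
  if (is.null(chemical))
    chemical <- if ("chemical" %in% names(records))
      paste(unique(records$chemical), collapse = "+") else "unknown"
  if (nrow(records) == 0) stop("no records for chemical ", chemical, call. = FALSE)
  if (length(unique(records$concentration_uM)) < 2)
    stop("analysis needs >= 2 groups (control plus >= 1 dose)", call. = FALSE)
  dataset <- normalise_records(records)
  gate <- anova_gate(dataset, alpha = config$alpha)
  max_dose <- max(dataset$concentration_uM)
  model <- NULL; ec <- NULL
  if (!gate$pass) {
    verdict <- "no_effect"
  } else {
    use_linear <- identical(config$fallback, "force_linear")
    if (!use_linear) {
      model <- tryCatch(fit_gaussian_cr(dataset), error = function(e) NULL)
      gauss_ok <- !is.null(model) && isTRUE(model$converged) &&
        !isTRUE(model$no_induction)
      if (gauss_ok) {
        ec <- ec15(model, effect = config$effect_level)
      }
      use_linear <- !gauss_ok ||
        (identical(config$fallback, "linear") && !isTRUE(ec$valid))
    }
    if (use_linear) {
      model <- fit_linear_cr(dataset)
      ec <- ec15(model, effect = config$effect_level, max_dose = max_dose)
    }
    verdict <- if (isTRUE(ec$valid)) ec$model_kind else "induction_without_EC"
  }
  report <- structure(list(chemical = chemical, anova = gate,
                           model = model, ec = ec, verdict = verdict,
                           dataset = dataset),
                      class = "chemical_report")
  if (!is.null(out_json)) write_chemical_report(report, out_json)
  report
}

#' @export
print.chemical_report <- function(x, ...) {
  cat(sprintf("<chemical_report> %s\n", x$chemical))
  cat(sprintf("  ANOVA: F(%d, %d) = %.4g, p = %.4g [%s at alpha = %g]\n",
              x$anova$df_between, x$anova$df_within, x$anova$F, x$anova$p,
              if (x$anova$pass) "pass" else "fail", x$anova$alpha))
  if (!is.null(x$model)) print(x$model)
  if (!is.null(x$ec) && isTRUE(x$ec$valid))
    cat(sprintf("  EC%.3g = %.4g uM (%s model)\n", x$ec$effect_level,
                x$ec$ec15_uM, x$ec$model_kind))
  cat(sprintf("  verdict: %s\n", x$verdict))
  invisible(x)
}

#' Write a chemical report as JSON
#'
#' @param report A `chemical_report` from [analyze_chemical()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_chemical_report <- function(report, path) {
  model_json <- if (is.null(report$model)) NULL
  else if (inherits(report$model, "gaussian_cr_model"))
    list(kind = "gaussian", b = report$model$b, c = report$model$c,
         d = report$model$d, e = report$model$e, sse = report$model$sse,
         converged = report$model$converged)
  else list(kind = "linear", a0 = report$model$a0, a1 = report$model$a1,
            covariate = report$model$covariate, sse = report$model$sse)
  jsonlite::write_json(list(
    chemical = report$chemical,
    anova = report$anova[c("F", "df_between", "df_within", "p", "alpha", "pass")],
    model = model_json,
    ec15_uM = if (isTRUE(report$ec$valid)) report$ec$ec15_uM else NA,
    verdict = report$verdict
  ), path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
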