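#' Evaluate the Richards generalized logistic curve
#'
#' \deqn{y(x) = A + C \left(1 + T e^{-B (x - M)}\right)^{-1/T}}
#' where `A` is the lower asymptote, `B` the growth rate (1/day), `C` the
#' asymptotic rise above `A` (cells), `M` the time of maximum growth (day)
#' and `T` a dimensionless shape parameter placing the inflection point.
#' `T = 1` recovers the ordinary logistic. The exponent is evaluated in log
#' space so large `|B (x - M)|` does not overflow.
#'
#' @param params Named numeric vector or list with elements `A`, `B`, `C`,
#'   `M`, `T`; `B`, `C`, `T` must be positive.
#' @param x Time(s) in days.
#' @return Numeric vector of curve values (cells), same length as `x`.
#' @examples
#' richards_eval(c(A = 0, B = 1, C = 1000, M = 8, T = 1), 8) # 500
#' @export
richards_eval <- function(params, x) {
  p <- validate_richards(params)
  # log(1 + T*exp(u)) computed stably: for large u it is u + log(T) + log1p(exp(-u)/T)
  u <- -p[["B"]] * (x - p[["M"]])
  logT <- log(p[["T"]])
  big <- u + logT > 35
  log_inner <- numeric(length(u))
  log_inner[big] <- u[big] + logT + log1p(exp(-(u[big] + logT)))
  log_inner[!big] <- log1p(p[["T"]] * exp(u[!big]))
  p[["A"]] + p[["C"]] * exp(-log_inner / p[["T"]])
}

validate_richards <- function(params) {
  p <- unlist(params)[c("A", "B", "C", "M", "T")]
  if (anyNA(p)) stop("params must contain named elements A, B, C, M, T")
  if (p[["B"]] <= 0 || p[["C"]] <= 0 || p[["T"]] <= 0) {
    stop("Richards parameters B, C and T must be positive")
  }
  p
}

#' Fit a Richards curve to a growth curve by nonlinear least squares
#'
#' Fits the five parameters of [richards_eval()] to `(day, cell_count)`
#' pairs with bounded Levenberg-Marquardt least squares. Positivity of `B`,
#' `C` and `T` is enforced through box constraints. Default starting values
#' use standard sigmoid heuristics: `A` = minimum count, `C` = range,
#' `M` = time of steepest numerical gradient, `B` = 4 * max slope / `C`,
#' `T` = 1; the fit is deterministic given data and start.
#'
#' @param curve A [growth_curve()] (or data frame with columns `day`,
#'   `cell_count`).
#' @param init Optional named vector of starting values `A, B, C, M, T`.
#' @param maxiter Iteration budget for the optimizer.
#' @return An object of class `richards_fit`: list with `params` (named
#'   vector), `residual` (sum of squared deviations), `fitted`, `converged`.
#' @examples
#' truth <- c(A = 1, B = 0.9, C = 4000, M = 8, T = 1.2)
#' gc <- growth_curve(seq(2, 15, by = 1 / 8), richards_eval(truth, seq(2, 15, by = 1 / 8)))
#' fit_richards(gc)$params
#' @export
fit_richards <- function(curve, init = NULL, maxiter = 200L) {
  stopifnot(is.data.frame(curve), all(c("day", "cell_count") %in% names(curve)))
  day <- curve$day
  y <- curve$cell_count
  if (length(day) < 6) stop("need at least 6 points to fit 5 parameters")
  if (diff(range(y)) <= .Machine$double.eps * max(abs(y), 1)) {
    stop("degenerate fit: curve is constant (no growth to fit)")
  }
  rng <- max(y) - min(y)
  if (is.null(init)) {
    # slopes of the median-smoothed curve keep noise spikes out of the init
    ys <- if (length(y) >= 7) stats::runmed(y, 5) else y
    slopes <- diff(ys) / diff(day)
    i_max <- which.max(slopes)
    init <- c(
      A = min(y),
      B = min(max(4 * slopes[i_max] / rng, 0.05), 5),
      C = rng,
      M = min(max(mean(day[i_max + 0:1]), min(day)), max(day)),
      T = 1
    )
  }
  init <- init[c("A", "B", "C", "M", "T")]
  lower <- c(A = -Inf, B = 1e-6, C = 1e-6, M = -Inf, T = 1e-3)
  upper <- c(A = Inf, B = Inf, C = Inf, M = Inf, T = 1e3)
  do_fit <- function(start) {
    minpack.lm::nlsLM(
      cell_count ~ A + C * (1 + T * exp(-B * (day - M)))^(-1 / T),
      data = data.frame(day = day, cell_count = y),
      start = as.list(start), lower = lower, upper = upper,
      control = minpack.lm::nls.lm.control(maxiter = maxiter)
    )
  }
  fit <- tryCatch(do_fit(init), error = function(e) e)
  if (inherits(fit, "error")) {
    # fall back to a neutral logistic start before giving up
    fallback <- c(A = min(y), B = 1, C = rng, M = stats::median(day), T = 1)
    fit <- do_fit(fallback)
  }
  params <- stats::coef(fit)[c("A", "B", "C", "M", "T")]
  fitted <- richards_eval(params, day)
  structure(
    list(
      params = params,
      residual = sum((y - fitted)^2),
      fitted = fitted,
      converged = fit$convInfo$isConv
    ),
    class = "richards_fit"
  )
}

#' @export
print.richards_fit <- function(x, ...) {
  cat("Richards curve fit\n")
  print(round(x$params, 4))
  cat(sprintf("residual sum of squares: %.4g\n", x$residual))
  invisible(x)
}
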