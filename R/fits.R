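## Saturating-exponential fit shared by the assembly-signal and
## nucleation-rate pipelines: y = A_max * (1 - exp(-k * t)).

#' Fit a saturating exponential
#'
#' Least-squares fit of `y = a_max * (1 - exp(-k * t))`, the model used for
#' normalized assembly signals and for per-frame peak counts; `k` is the
#' global assembly (or apparent nucleation) rate and `ln(2)/k` the assembly
#' half-life.
#'
#' @param t times, seconds (non-negative).
#' @param y observed values; same length as `t`, at least 4 points.
#' @return an object of class `exp_fit` with elements `a_max`, `k`
#'   (1/s), `half_life_s`, `residual_sse`, `converged`, `ci95` (asymptotic
#'   95% intervals for `a_max` and `k` from the Jacobian), and the data.
#'   When the optimizer fails, or the data are all zero, `converged` is
#'   `FALSE` and `k = 0` is returned as a sentinel.
#' @examples
#' t <- 0:40
#' f <- fit_saturating_exponential(t, 3 * (1 - exp(-0.1 * t)))
#' coef(f)
#' @export
fit_saturating_exponential <- function(t, y) {
  if (length(t) != length(y)) stop_param("'t' and 'y' lengths differ")
  if (length(t) < 4L) stop_param("need at least 4 points")
  if (any(!is.finite(t)) || any(!is.finite(y)) || any(t < 0))
    stop_param("'t' must be finite and >= 0, 'y' finite")

  failed <- function() {
    structure(list(a_max = 0, k = 0, half_life_s = Inf,
                   residual_sse = sum(y^2), converged = FALSE,
                   ci95 = matrix(NA_real_, 2, 2,
                                 dimnames = list(c("a_max", "k"),
                                                 c("lower", "upper"))),
                   data = data.frame(t = t, y = y)),
              class = "exp_fit")
  }
  if (all(y == 0) || stats::sd(y) == 0) return(failed())

  a0 <- max(y)
  if (a0 <= 0) return(failed())
  # time at which the signal first reaches 1 - 1/e of the plateau
  i63 <- which(y >= 0.632 * a0)
  k0 <- if (length(i63) && t[min(i63)] > 0) 1 / t[min(i63)]
        else 1 / max(stats::median(t), .Machine$double.eps)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ a * (1 - exp(-k * t)),
                      data = data.frame(t = t, y = y),
                      start = list(a = a0, k = k0),
                      lower = c(0, 0),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(failed())
  cf <- stats::coef(fit)
  if (!all(is.finite(cf)) || cf[["k"]] <= 0) return(failed())
  se <- tryCatch(sqrt(diag(stats::vcov(fit))), error = function(e)
    c(a = NA_real_, k = NA_real_))
  ci <- cbind(lower = cf - 1.96 * se, upper = cf + 1.96 * se)
  dimnames(ci) <- list(c("a_max", "k"), c("lower", "upper"))
  structure(list(a_max = unname(cf[["a"]]), k = unname(cf[["k"]]),
                 half_life_s = log(2) / cf[["k"]],
                 residual_sse = sum(stats::resid(fit)^2),
                 converged = TRUE, ci95 = ci,
                 data = data.frame(t = t, y = y)),
            class = "exp_fit")
}

#' @export
print.exp_fit <- function(x, ...) {
  cat("Saturating exponential fit: y = a_max * (1 - exp(-k t))\n")
  cat(sprintf("  a_max = %.4g   k = %.4g 1/s   half-life = %.4g s\n",
              x$a_max, x$k, x$half_life_s))
  cat(sprintf("  SSE = %.4g   converged: %s\n", x$residual_sse, x$converged))
  invisible(x)
}

#' @export
coef.exp_fit <- function(object, ...) c(a_max = object$a_max, k = object$k)

#' @export
predict.exp_fit <- function(object, t = object$data$t, ...)
  object$a_max * (1 - exp(-object$k * t))

#' @export
residuals.exp_fit <- function(object, ...)
  object$data$y - predict(object)

#' @export
plot.exp_fit <- function(x, ...) {
  graphics::plot(x$data$t, x$data$y, xlab = "time (s)", ylab = "signal", ...)
  tt <- seq(min(x$data$t), max(x$data$t), length.out = 200)
  graphics::lines(tt, predict(x, tt), col = 2, lwd = 2)
  invisible(x)
}
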