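# Convex tonic/phasic decomposition of EDA.
#
# Model: y = M q + B l + C d + residual, where
#   M q  - phasic component: the response of a Bateman second-order system
#          (time constants tau0 > tau1) to a nonnegative sudomotor driver q,
#          discretised as convolution with the peak-normalised sampled kernel;
#   B l  - smooth tonic curve on a cubic B-spline basis (knots every
#          delta_knot seconds), ridge-penalised;
#   C d  - offset + linear drift.
# Objective: 1/2 ||y - Mq - Bl - Cd||^2 + alpha * 1'q + gamma/2 ||l||^2,
# subject to q >= 0. The l1 term is linear under the nonnegativity
# constraint, so the problem is a convex QP. The tonic/drift coefficients are
# eliminated in closed form, leaving a nonnegative QP in q solved exactly by
# the dual active-set method (quadprog).

# Build (and cache) the fixed operators for a given (n, rate, parameters).
cvxeda_operators <- function(n, rate, tau0, tau1, delta_knot) {
  key <- paste(n, rate, tau0, tau1, delta_knot, sep = "|")
  cached <- .cvxeda_cache[[key]]
  if (!is.null(cached)) return(cached)
  dt <- 1 / rate
  t <- (seq_len(n) - 1) * dt
  h <- scr_kernel(t, tau0, tau1, normalize = TRUE)
  M <- matrix(0, n, n)
  for (j in seq_len(n)) M[j:n, j] <- h[1:(n - j + 1)]
  # cubic B-spline tonic basis, knots every delta_knot s, extended ends
  knots <- seq(0, t[n], by = delta_knot)
  if (length(knots) < 2) knots <- c(0, t[n])
  aug <- c(rep(knots[1], 3), knots, rep(knots[length(knots)], 3))
  B <- splines::splineDesign(aug, t, ord = 4, outer.ok = TRUE)
  C <- cbind(1, t / t[n])
  ops <- list(M = M, B = B, C = C, t = t)
  .cvxeda_cache[[key]] <- ops
  ops
}
.cvxeda_cache <- new.env(parent = emptyenv())

#' Convex tonic/phasic decomposition of a 2 Hz EDA series
#'
#' Decomposes a (possibly signed, high-passed) EDA series into a phasic
#' component driven by a sparse nonnegative sudomotor driver through a
#' Bateman second-order system, a smooth spline tonic component with offset
#' and linear drift, and a residual. The three parts add back to the input
#' exactly.
#'
#' @param series Tibble with columns `time_s`, `eda`, uniform rate, >= 30
#'   samples.
#' @param tau0,tau1 Bateman time constants in seconds (`tau0 > tau1 > 0`;
#'   defaults 2.0 and 0.7).
#' @param delta_knot Tonic spline knot spacing in seconds (default 10).
#' @param alpha Sparsity weight on the driver (default 8e-4).
#' @param gamma Ridge weight on the tonic spline coefficients (default 1e-2).
#' @return An object of class `eda_decomposition`: list with `time_s`,
#'   `phasic`, `tonic`, `driver`, `residual`, `rate` and the parameters.
#' @export
#' @examples
#' t <- seq(0, 120, by = 0.5)
#' y <- 2 + scr_kernel(t - 60, normalize = TRUE)
#' d <- cvxeda_decompose(tibble::tibble(time_s = t, eda = y))
#' max(abs(d$phasic + d$tonic + d$residual - y))  # ~ 0
cvxeda_decompose <- function(series, tau0 = 2.0, tau1 = 0.7, delta_knot = 10,
                             alpha = 8e-4, gamma = 1e-2) {
  n <- nrow(series)
  if (n < 30L) stop("need at least 30 samples for the decomposition", call. = FALSE)
  if (!(tau0 > tau1 && tau1 > 0)) {
    stop("Bateman time constants require tau0 > tau1 > 0", call. = FALSE)
  }
  stopifnot(alpha > 0, gamma > 0)
  rate <- series_rate(series$time_s)
  y <- series$eda
  ops <- cvxeda_operators(n, rate, tau0, tau1, delta_knot)
  M <- ops$M
  G <- cbind(ops$B, ops$C)
  nl <- ncol(ops$B)
  Gam <- diag(c(rep(gamma, nl), rep(0, ncol(ops$C))), ncol(G))

  # eliminate (l, d): for residual r, min_b 1/2||r - G b||^2 + 1/2 b'Gam b
  # has value 1/2 r' S r with S = I - G (G'G + Gam)^-1 G'
  GtG <- crossprod(G) + Gam
  GtG_inv_Gt <- solve(GtG, t(G))
  SM <- M - G %*% (GtG_inv_Gt %*% M)      # S %*% M
  Sy <- y - G %*% (GtG_inv_Gt %*% y)      # S %*% y

  H <- crossprod(M, SM)
  H <- (H + t(H)) / 2 + diag(1e-8 * max(diag(H)), n)
  f <- as.numeric(crossprod(M, Sy)) - alpha

  sol <- tryCatch(
    quadprog::solve.QP(Dmat = H, dvec = f, Amat = diag(n), bvec = rep(0, n)),
    error = function(e) stop("QP solver failed: ", conditionMessage(e), call. = FALSE)
  )
  q <- pmax(sol$solution, 0)
  q[q < 1e-10] <- 0

  beta <- as.numeric(GtG_inv_Gt %*% (y - M %*% q))
  phasic <- as.numeric(M %*% q)
  tonic <- as.numeric(G %*% beta)
  structure(list(time_s = series$time_s, phasic = phasic, tonic = tonic,
                 driver = q, residual = y - phasic - tonic, rate = rate,
                 tau0 = tau0, tau1 = tau1, delta_knot = delta_knot,
                 alpha = alpha, gamma = gamma),
            class = "eda_decomposition")
}

#' @export
print.eda_decomposition <- function(x, ...) {
  cat("EDA decomposition:", length(x$phasic), "samples at", x$rate, "Hz\n")
  cat(sprintf("  phasic sd %.4g uS, tonic range [%.4g, %.4g] uS, residual sd %.4g uS\n",
              sd(x$phasic), min(x$tonic), max(x$tonic), sd(x$residual)))
  invisible(x)
}

#' Tidy an EDA decomposition
#'
#' @param x An `eda_decomposition` from [cvxeda_decompose()].
#' @param ... Unused.
#' @return Tibble with columns `time_s`, `phasic`, `tonic`, `driver`,
#'   `residual`.
#' @export
tidy.eda_decomposition <- function(x, ...) {
  tibble(time_s = x$time_s, phasic = x$phasic, tonic = x$tonic,
         driver = x$driver, residual = x$residual)
}

#' @describeIn tidy.eda_decomposition Plot phasic/tonic/driver traces.
#' @param object An `eda_decomposition`.
#' @export
autoplot.eda_decomposition <- function(object, ...) {
  df <- tidy(object) %>%
    tidyr::pivot_longer(c("phasic", "tonic", "driver"),
                        names_to = "part", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(.data$time_s, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$part), scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = "uS", title = "Convex EDA decomposition")
}
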