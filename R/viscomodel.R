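#' Effective elasticity, effective mass and rigidity factor of the clot
#'
#' Converts a clot shift series into the time-resolved viscoelastic model
#' quantities. With `dG_z`, `dF_z` the bandwidth/frequency shifts at the
#' sample-loading snapshot (viscous plasma only) and `dG(t)`, `dF(t)` the
#' running shifts, the model computes per time point
#'
#' * `c(t) = dG_z / dG(t)` — plasma viscosity correction coefficient,
#' * `mu_t(t) = a * (dG(t)^2 - c(t)^2 * dG_z^2)` — normalised effective
#'   elasticity,
#' * `M_t(t) = b * (dF(t) - c(t) * dF_z)` — normalised effective mass density,
#' * `RF(t) = mu_t / M_t` — the rigidity factor,
#'
#' with scaling constants `a` (Hz^-2) and `b` (Hz^-1). At the z-snapshot
#' `c = 1` and both `mu_t` and `M_t` are exactly zero, so `RF` is undefined
#' there; any point whose net frequency shift `|dF - c*dF_z|` is below
#' `rf_floor` is likewise flagged undefined rather than reported as a huge
#' ratio.
#'
#' @param series A `shift_series` (see [baseline_reference()]); its `dG_hz`
#'   must be positive everywhere and `dG_z > 0`.
#' @param a Elasticity scaling constant, Hz^-2 (default 2.5e-7).
#' @param b Mass scaling constant, Hz^-1 (default 1e-3).
#' @param rf_floor Net frequency shift (Hz) below which RF is flagged
#'   undefined (default 1 Hz).
#'
#' @return A `visco_series` tibble with columns `time_s`, `c`, `mu_t`, `M_t`,
#'   `RF`, `rf_defined`; constants kept as attributes.
#' @examples
#' s <- baseline_reference(tibble::tibble(
#'   time_s = c(0, 300), dF_hz = c(700, 1800), dG_hz = c(1000, 2236.068)))
#' rigidity_series(s)
#' @export
rigidity_series <- function(series, a = 2.5e-7, b = 1e-3, rf_floor = 1) {
  if (!inherits(series, "shift_series"))
    abort("`series` must be a shift_series (see baseline_reference()).")
  stopifnot_scalar_number(a, "a", positive = TRUE)
  stopifnot_scalar_number(b, "b", positive = TRUE)
  stopifnot_scalar_number(rf_floor, "rf_floor")
  dG_z <- attr(series, "dG_z")
  dF_z <- attr(series, "dF_z")
  z <- attr(series, "z_index")
  if (dG_z <= 0)
    abort("dG_z must be > 0: liquid loading must broaden the resonance.")
  if (any(series$dG_hz <= 0))
    abort("dG(t) must be > 0 at every time point.")

  cc <- dG_z / series$dG_hz
  mu_t <- a * (series$dG_hz^2 - cc^2 * dG_z^2)
  M_t <- b * (series$dF_hz - cc * dF_z)
  defined <- abs(M_t) >= b * rf_floor
  RF <- ifelse(defined, mu_t / M_t, NA_real_)

  structure(
    tibble(time_s = series$time_s, c = cc, mu_t = mu_t, M_t = M_t,
           RF = RF, rf_defined = defined),
    a = a, b = b, rf_floor = rf_floor, z_index = z,
    class = c("visco_series", class(tibble())))
}

#' Summarise a rigidity series over a plateau window
#'
#' Reduces a `visco_series` to single per-sample values the way a clot is
#' reported: `mu_t` and `M_t` as means over the end-of-trace plateau window,
#' and `RF` as the mean of the defined `RF(t)` points in that window.
#'
#' @param vs A `visco_series` from [rigidity_series()].
#' @param window Numeric length-2 time range (s) over which to average; the
#'   default is the last 20 % of the trace.
#'
#' @return One-row tibble: `mu_t`, `M_t`, `RF`, `n_points`, `n_rf_defined`,
#'   `window_start_s`, `window_end_s`.
#' @export
rigidity_summary <- function(vs, window = NULL) {
  if (!inherits(vs, "visco_series"))
    abort("`vs` must be a visco_series (see rigidity_series()).")
  if (is.null(window)) {
    t0 <- min(vs$time_s); t1 <- max(vs$time_s)
    window <- c(t1 - 0.2 * (t1 - t0), t1)
  }
  if (length(window) != 2L || !is.numeric(window) || window[2] < window[1])
    abort("`window` must be an increasing numeric time range c(start, end).")
  inw <- vs$time_s >= window[1] & vs$time_s <= window[2]
  if (!any(inw)) abort("empty window: no time points inside `window`.")
  def <- inw & vs$rf_defined
  if (sum(def) < 3L)
    abort("window must contain at least 3 defined RF points.")
  tibble(mu_t = mean(vs$mu_t[inw]),
         M_t = mean(vs$M_t[inw]),
         RF = mean(vs$RF[def]),
         n_points = sum(inw),
         n_rf_defined = sum(def),
         window_start_s = window[1],
         window_end_s = window[2])
}

#' @export
print.visco_series <- function(x, ...) {
  cat(sprintf("<visco_series> a = %.3g Hz^-2, b = %.3g Hz^-1, %d/%d RF points defined\n",
              attr(x, "a"), attr(x, "b"), sum(x$rf_defined), nrow(x)))
  NextMethod()
}

#' Plot a rigidity series
#'
#' Effective elasticity, effective mass density and rigidity factor against
#' time; undefined RF points are omitted.
#'
#' @param object A `visco_series`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.visco_series <- function(object, ...) {
  long <- tidyr::pivot_longer(
    as_tibble(object)[, c("time_s", "mu_t", "M_t", "RF")],
    -"time_s", names_to = "quantity", values_to = "value")
  long$quantity <- factor(long$quantity, c("mu_t", "M_t", "RF"),
                          c("effective elasticity μ_t (a.u.)",
                            "effective mass density M_t (a.u.)",
                            "rigidity factor RF (a.u.)"))
  ggplot2::ggplot(stats::na.omit(long),
                  ggplot2::aes(.data$time_s, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~quantity, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time since activation (s)", y = NULL)
}
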