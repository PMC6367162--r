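#' Plot a fitted hurdle model
#'
#' For the binomial stage, the observed success/failure indicators and the
#' fitted probability of reproductive success against precipitation; for
#' the yield stage, success-year log yields and the fitted log-linear
#' relation against log-precipitation. Faceted by species.
#'
#' @param object a `hurdle_fit`.
#' @param stage `"binomial"` or `"yield"`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.hurdle_fit <- function(object, stage = c("binomial", "yield"), ...) {
  stage <- match.arg(stage)
  data <- object$data
  co <- tidy(if (stage == "binomial") object$binomial else object$yield) |>
    dplyr::select("species_code", "term", "estimate") |>
    tidyr::pivot_wider(names_from = "term", values_from = "estimate")
  grid <- co |>
    dplyr::cross_join(tibble::tibble(
      log_precip = seq(min(data$log_precip), max(data$log_precip),
                       length.out = 100)
    )) |>
    dplyr::mutate(fitted = .data$intercept + .data$slope * .data$log_precip)
  if (stage == "binomial") {
    grid$fitted <- inv_logit(grid$fitted)
    ggplot2::ggplot(data, ggplot2::aes(x = .data$log_precip)) +
      ggplot2::geom_point(ggplot2::aes(y = as.numeric(.data$success)),
                          shape = 1, alpha = 0.6) +
      ggplot2::geom_line(data = grid, ggplot2::aes(y = .data$fitted),
                         colour = "steelblue") +
      ggplot2::facet_wrap(~species_code) +
      ggplot2::labs(x = "log(precipitation + 1)",
                    y = "probability of reproductive success") +
      ggplot2::theme_minimal()
  } else {
    pts <- data |>
      dplyr::filter(.data$success) |>
      dplyr::mutate(log_K = log(.data$K))
    ggplot2::ggplot(pts, ggplot2::aes(x = .data$log_precip, y = .data$log_K)) +
      ggplot2::geom_point(shape = 1, alpha = 0.6) +
      ggplot2::geom_line(data = grid, ggplot2::aes(y = .data$fitted),
                         colour = "steelblue") +
      ggplot2::facet_wrap(~species_code) +
      ggplot2::labs(x = "log(precipitation + 1)",
                    y = "log(low-density yield)") +
      ggplot2::theme_minimal()
  }
}

#' Plot the selection gradient evaluations of an ESS solve
#'
#' The gradient `h(g)` at every candidate germination fraction visited by
#' the pre-scan and bisection, with the solved ESS marked. A decreasing
#' curve crossing zero at `g_ess` is the expected picture for an interior
#' ESS.
#'
#' @param object an `ess_result`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.ess_result <- function(object, ...) {
  path <- dplyr::arrange(object$h_path, .data$g)
  pl <- ggplot2::ggplot(path, ggplot2::aes(x = .data$g, y = .data$h)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_line(colour = "grey70") +
    ggplot2::geom_point(ggplot2::aes(shape = .data$persistent)) +
    ggplot2::labs(x = "resident germination fraction g",
                  y = "selection gradient h(g)") +
    ggplot2::theme_minimal()
  if (!is.na(object$g_ess)) {
    pl <- pl + ggplot2::geom_vline(xintercept = object$g_ess,
                                   colour = "steelblue", linetype = 3)
  }
  pl
}

#' Plot standardized trait-regression coefficients
#'
#' Dot-and-whisker plot (estimate +/- 2 standard errors) of the
#' standardized coefficients, intercept excluded.
#'
#' @param object a `trait_regression`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.trait_regression <- function(object, ...) {
  co <- tidy(object) |>
    dplyr::filter(.data$term != "(Intercept)")
  ggplot2::ggplot(co, ggplot2::aes(x = .data$estimate, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(
      xmin = .data$estimate - 2 * .data$std.error,
      xmax = .data$estimate + 2 * .data$std.error
    )) +
    ggplot2::labs(x = "standardized coefficient", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot an invasion (uninvadability) profile
#'
#' Mutant invasion growth rates from [verify_ess()] against the mutant
#' germination fraction, with a 3-standard-error ribbon and the resident
#' marked. For a true ESS the curve is concave, touches zero at the
#' resident, and is negative elsewhere.
#'
#' @param profile the tibble returned by [verify_ess()].
#' @return a ggplot.
#' @export
plot_invasion_profile <- function(profile) {
  g0 <- attr(profile, "resident_g")
  pl <- ggplot2::ggplot(profile, ggplot2::aes(x = .data$mutant_g, y = .data$r)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$r - 3 * .data$se,
                                      ymax = .data$r + 3 * .data$se),
                         fill = "steelblue", alpha = 0.2) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "mutant germination fraction",
                  y = "invasion growth rate r(g_ess, mutant)") +
    ggplot2::theme_minimal()
  if (!is.null(g0)) {
    pl <- pl + ggplot2::geom_vline(xintercept = g0, colour = "steelblue",
                                   linetype = 3)
  }
  pl
}
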