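#' Plot a dilution curve over its critical points
#'
#' @param points Critical-point data frame (`ldm_max`, `nc`).
#' @param curve A [dilution_curve()].
#' @return A ggplot object.
#' @export
plot_dilution_curve <- function(points, curve) {
  pm <- points_matrix(points)
  grid <- data.frame(ldm = seq(min(pm$ldm), max(pm$ldm), length.out = 200))
  grid$nc <- curve$a * grid$ldm^(-curve$b)
  ggplot2::ggplot(pm, ggplot2::aes(x = .data$ldm, y = .data$nc)) +
    ggplot2::geom_line(data = grid, colour = "firebrick") +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "Leaf dry matter (t/ha)", y = "Critical N concentration (%)",
      title = sprintf("Nc%% = %.3g LDM^-%.3g  (R2 = %.2f)",
                      curve$a, curve$b, curve$r2)
    ) +
    ggplot2::theme_minimal()
}

#' 1:1 plot of a validation report
#'
#' Observed versus curve-predicted critical N with the identity line; the
#' closer the points sit to the 1:1 line, the better the curve transfers.
#'
#' @param report A `validation_report` from [validate_curve()].
#' @return A ggplot object.
#' @export
plot_validation <- function(report) {
  stopifnot(inherits(report, "validation_report"))
  ggplot2::ggplot(report$pairs,
                  ggplot2::aes(x = .data$observed, y = .data$predicted)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::geom_point() +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "Observed critical N (%)", y = "Predicted critical N (%)",
      title = sprintf("RMSE = %.2f, n-RMSE = %.1f%% (%s)",
                      report$rmse, report$n_rmse, report$stability)
    ) +
    ggplot2::theme_minimal()
}

#' Plot the quadratic relative-yield response to NNI
#'
#' @param response A `yield_response` from [fit_yield_response()]; if it
#'   carries a `data` element (as pipeline fits do) the treatment points
#'   are overlaid.
#' @return A ggplot object.
#' @export
plot_yield_response <- function(response) {
  stopifnot(inherits(response, "yield_response"))
  dat <- response$data
  rng <- if (!is.null(dat)) range(dat$nni) else
    response$nni_opt + c(-0.5, 0.5)
  grid <- data.frame(nni = seq(rng[1], rng[2], length.out = 200))
  grid$ry <- response$c0 + response$c1 * grid$nni + response$c2 * grid$nni^2
  p <- ggplot2::ggplot(grid, ggplot2::aes(x = .data$nni, y = .data$ry)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::labs(x = "Nitrogen nutrition index",
                  y = "Relative yield",
                  title = sprintf("Optimum NNI = %.2f, max RY = %.2f",
                                  response$nni_opt, response$ry_max)) +
    ggplot2::theme_minimal()
  if (!is.null(dat)) {
    p <- p + ggplot2::geom_point(
      data = dat, ggplot2::aes(x = .data$nni, y = .data$ry))
  }
  p
}
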