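#' Nitrogen nutrition index
#'
#' NNI is the ratio of measured plant N concentration (`na`) to the
#' critical concentration at the same biomass (`nc`). NNI = 1 is optimal
#' nutrition, below 1 deficient, above 1 surplus. Because exact equality
#' is measure-zero on real data, status uses a band around 1 (default
#' 0.95–1.05); `band = c(1, 1)` recovers the strict three-way rule.
#'
#' @param na Measured PNC, % (> 0, vectorized).
#' @param nc Critical PNC, % (> 0, vectorized).
#' @param band Two-sided optimal band on NNI.
#' @return A tibble with `na`, `nc`, `nni`, `status`.
#' @examples
#' compute_nni(c(1.5, 1.2, 0.6), c(1.5, 0.8, 1.2))
#' @export
compute_nni <- function(na, nc, band = c(0.95, 1.05)) {
  if (any(!is.finite(na) | na <= 0) || any(!is.finite(nc) | nc <= 0)) {
    stop("`na` and `nc` must be positive and finite", call. = FALSE)
  }
  stopifnot(length(band) == 2, band[1] <= band[2])
  nni <- na / nc
  status <- dplyr::case_when(
    nni < band[1] ~ "deficient",
    nni > band[2] ~ "surplus",
    TRUE ~ "optimal"
  )
  tibble::tibble(na = na, nc = nc, nni = nni, status = status)
}

#' Root mean square error
#'
#' @param observed,predicted Numeric vectors of equal nonzero length.
#' @return `sqrt(mean((predicted - observed)^2))`, in the units of the
#'   observations.
#' @export
rmse <- function(observed, predicted) {
  if (length(observed) != length(predicted)) {
    stop("observed and predicted differ in length", call. = FALSE)
  }
  if (length(observed) == 0) stop("empty input", call. = FALSE)
  sqrt(mean((predicted - observed)^2))
}

#' Normalized RMSE, percent of the observed mean
#'
#' `n-RMSE = 100 * RMSE / mean(observed)`; the scale-free error used to
#' grade model stability (see [stability_class()]).
#'
#' @inheritParams rmse
#' @return n-RMSE in percent.
#' @export
n_rmse <- function(observed, predicted) {
  obar <- mean(observed)
  if (!is.finite(obar) || obar <= 0) {
    stop("mean of observed values must be positive", call. = FALSE)
  }
  100 * rmse(observed, predicted) / obar
}

#' Jamieson stability class of an n-RMSE value
#'
#' Model stability grading by normalized RMSE: below 10% excellent,
#' 10–20% good, 20–30% moderate, 30% and above poor. The published
#' inequalities leave the boundaries open on both sides; the half-open
#' intervals `[0,10) [10,20) [20,30) [30,Inf)` make the classes exhaustive
#' and mutually exclusive.
#'
#' @param x n-RMSE value(s), percent, >= 0.
#' @return Character vector in
#'   `c("excellent", "good", "moderate", "poor")`.
#' @examples
#' stability_class(c(9.99, 10.78, 29.99, 30))
#' @export
stability_class <- function(x) {
  if (any(!is.finite(x) | x < 0)) stop("n-RMSE must be >= 0", call. = FALSE)
  as.character(cut(x, c(0, 10, 20, 30, Inf), right = FALSE,
                   labels = c("excellent", "good", "moderate", "poor")))
}

#' Relative yield within a season-year group
#'
#' Each treatment's yield divided by the highest yield of the group, so
#' the best treatment maps to 1.
#'
#' @param yields Positive yields (t/ha) of the treatments of one
#'   season-year.
#' @return Relative yields in `(0, 1]`, same order.
#' @export
relative_yield <- function(yields) {
  if (length(yields) == 0) stop("empty yield group", call. = FALSE)
  if (any(!is.finite(yields) | yields <= 0)) {
    stop("yields must be positive and finite", call. = FALSE)
  }
  yields / max(yields)
}

#' Quadratic response of relative yield to NNI
#'
#' Fits `RY = c0 + c1 * NNI + c2 * NNI^2` by OLS and reports the vertex:
#' the NNI at which relative yield peaks (`nni_opt = -c1 / (2 c2)`) and
#' the peak itself (`ry_max`). A fit that opens upward (`c2 >= 0`) is
#' flagged — its vertex is a minimum, not an optimum — and reported with a
#' warning.
#'
#' @param nni NNI values (>= 4, not all equal).
#' @param ry Relative yields, same length.
#' @return A `yield_response`: `c0`, `c1`, `c2`, `r2`, `nni_opt`,
#'   `ry_max`, `convex` flag, `n`.
#' @examples
#' nni <- seq(0.5, 1.5, by = 0.1)
#' fit_yield_response(nni, 1 - (nni - 1)^2) # vertex (1, 1)
#' @export
fit_yield_response <- function(nni, ry) {
  if (length(nni) != length(ry)) stop("nni and ry differ in length",
                                      call. = FALSE)
  if (length(nni) < 4) stop("need >= 4 (nni, ry) pairs", call. = FALSE)
  if (var(nni) == 0) stop("rank-deficient design: all nni equal",
                          call. = FALSE)
  fit <- lm(ry ~ nni + I(nni^2))
  co <- unname(coef(fit))
  if (any(is.na(co))) stop("rank-deficient quadratic design", call. = FALSE)
  c0 <- co[1]; c1 <- co[2]; c2 <- co[3]
  nni_opt <- -c1 / (2 * c2)
  ry_max <- c0 + c1 * nni_opt + c2 * nni_opt^2
  pred <- c0 + c1 * nni + c2 * nni^2
  r2 <- 1 - sum((ry - pred)^2) / sum((ry - mean(ry))^2)
  convex <- c2 >= 0
  if (convex) {
    warning("quadratic opens upward (c2 >= 0): the vertex is a minimum, ",
            "not a yield optimum", call. = FALSE)
  }
  structure(
    list(c0 = c0, c1 = c1, c2 = c2, r2 = r2,
         nni_opt = nni_opt, ry_max = ry_max, convex = convex,
         n = length(nni)),
    class = "yield_response"
  )
}

#' @export
print.yield_response <- function(x, ...) {
  cat("Quadratic relative-yield response to NNI:\n")
  cat(sprintf("  RY = %.4g + %.4g NNI %+.4g NNI^2   (R2 = %.3f, n = %d)\n",
              x$c0, x$c1, x$c2, x$r2, x$n))
  if (x$convex) {
    cat(sprintf("  WARNING: opens upward; vertex (%.4g, %.4g) is a minimum\n",
                x$nni_opt, x$ry_max))
  } else {
    cat(sprintf("  optimum: NNI = %.4g, maximal RY = %.4g\n",
                x$nni_opt, x$ry_max))
  }
  invisible(x)
}

#' Validate a dilution curve against hold-out critical points
#'
#' Predicts the critical N concentration of each hold-out point from its
#' maximum LDM via the curve, compares with the observed critical value,
#' and reports RMSE, n-RMSE and the Jamieson stability class, plus the
#' paired values for 1:1 plotting.
#'
#' @param curve A [dilution_curve()].
#' @param holdout_points Critical points (>= 2 rows with `ldm_max`, `nc`)
#'   not used in fitting.
#' @return A `validation_report`: `rmse` (% N), `n_rmse` (%), `stability`,
#'   `n`, and `pairs` (tibble `ldm_max`, `observed`, `predicted`).
#' @export
validate_curve <- function(curve, holdout_points) {
  stopifnot(inherits(curve, "dilution_curve"))
  pm <- points_matrix(holdout_points)
  if (nrow(pm) < 2) stop("need >= 2 hold-out points", call. = FALSE)
  predicted <- curve$a * pm$ldm^(-curve$b)
  r <- rmse(pm$nc, predicted)
  nr <- n_rmse(pm$nc, predicted)
  structure(
    list(rmse = r, n_rmse = nr, stability = stability_class(nr),
         n = nrow(pm),
         pairs = tibble::tibble(ldm_max = pm$ldm, observed = pm$nc,
                                predicted = predicted)),
    class = "validation_report"
  )
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("Curve validation on %d hold-out points:\n", x$n))
  cat(sprintf("  RMSE   = %.4g %%N\n", x$rmse))
  cat(sprintf("  n-RMSE = %.4g %%  ->  stability: %s\n", x$n_rmse,
              x$stability))
  invisible(x)
}

#' NNI of every observation under a dilution curve
#'
#' Computes the nitrogen nutrition index of each observation: the measured
#' PNC divided by the curve's critical N at the observation's own LDM
#' (default), or — when a critical-point table is supplied via `points` —
#' at the sampling date's maximum LDM (`ldm_basis = "plateau"`), the
#' date-level alternative.
#'
#' @param table A validated observation table.
#' @param curve A [dilution_curve()].
#' @param band Optimal-NNI band, see [compute_nni()].
#' @param ldm_basis `"own"` (default) or `"plateau"`.
#' @param points Critical points with the per-date `ldm_max`; required for
#'   `ldm_basis = "plateau"`.
#' @return The table with added columns `nc`, `nni`, `status`.
#' @export
nni_table <- function(table, curve, band = c(0.95, 1.05),
                      ldm_basis = c("own", "plateau"), points = NULL) {
  ldm_basis <- match.arg(ldm_basis)
  table <- validate_observations(table)
  if (ldm_basis == "own") {
    basis <- table$ldm
  } else {
    if (is.null(points)) {
      stop('`points` is required for ldm_basis = "plateau"', call. = FALSE)
    }
    key <- c("variety", "season", "year", "stage")
    joined <- dplyr::left_join(table, points[, c(key, "ldm_max")], by = key)
    if (any(is.na(joined$ldm_max))) {
      stop("some observations have no critical point for their date",
           call. = FALSE)
    }
    basis <- joined$ldm_max
  }
  nc <- suppressWarnings(evaluate_nc(curve, basis))
  rec <- compute_nni(table$pnc, nc, band = band)
  table$nc <- rec$nc
  table$nni <- rec$nni
  table$status <- rec$status
  table
}
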