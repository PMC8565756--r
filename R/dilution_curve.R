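#' Construct a critical N dilution curve object
#'
#' A dilution curve is the power law `Nc% = a * LDM^-b`: `a` is the
#' critical N concentration at LDM = 1 t/ha and `b` the dilution exponent
#' (how fast the critical concentration falls as the canopy grows). Use
#' this constructor for published curves; [fit_curve()] builds one from
#' extracted critical points.
#'
#' @param a Critical N % at LDM = 1 t/ha; > 0.
#' @param b Dilution exponent.
#' @param r2 Coefficient of determination on the original Nc scale, if
#'   known.
#' @param n_points Number of critical points behind the fit.
#' @param fit_method `"loglog_ols"`, `"nonlinear_ls"` or `"fixed"` for a
#'   published curve.
#' @param group Free-form label (season/variety/year).
#' @param ldm_range LDM range (t/ha) the curve was fitted on; evaluation
#'   outside it warns.
#' @return A `dilution_curve` object.
#' @examples
#' early <- dilution_curve(2.66, 0.79, group = "early rice (published)")
#' evaluate_nc(early, 1)
#' @export
dilution_curve <- function(a, b, r2 = NA_real_, n_points = NA_integer_,
                           fit_method = "fixed", group = NULL,
                           ldm_range = NULL) {
  if (!(is.numeric(a) && length(a) == 1 && a > 0)) {
    stop("`a` must be a single positive number", call. = FALSE)
  }
  if (!(is.numeric(b) && length(b) == 1 && is.finite(b))) {
    stop("`b` must be a single finite number", call. = FALSE)
  }
  structure(
    list(a = a, b = b, r2 = r2, n_points = n_points,
         fit_method = fit_method, group = group, ldm_range = ldm_range),
    class = "dilution_curve"
  )
}

#' @export
print.dilution_curve <- function(x, ...) {
  cat(sprintf("Critical N dilution curve%s:\n",
              if (is.null(x$group)) "" else paste0(" [", x$group, "]")))
  cat(sprintf("  Nc%% = %.4g * LDM^-%.4g", x$a, x$b))
  if (!is.na(x$r2)) cat(sprintf("   (R2 = %.3f on the Nc scale", x$r2))
  if (!is.na(x$n_points)) cat(sprintf(", n = %d points", x$n_points))
  if (!is.na(x$r2)) cat(")")
  cat("\n  fit:", x$fit_method, "\n")
  invisible(x)
}

points_matrix <- function(points) {
  if (is.data.frame(points)) {
    ldm_col <- intersect(c("ldm_max", "ldm"), names(points))[1]
    if (is.na(ldm_col) || !"nc" %in% names(points)) {
      stop("`points` needs columns `ldm_max` (or `ldm`) and `nc`",
           call. = FALSE)
    }
    data.frame(ldm = points[[ldm_col]], nc = points$nc)
  } else {
    stop("`points` must be a data frame of critical points", call. = FALSE)
  }
}

#' Fit the critical N dilution power law to critical points
#'
#' Fits `Nc% = a * LDM^-b` to extracted critical points. The default,
#' `loglog_ols`, is ordinary least squares on the linearized form
#' `ln Nc = ln a - b ln LDM` (the scale the between-group comparison uses);
#' `nonlinear_ls` refines that solution by least squares on the original
#' Nc scale. Either way `r2` is reported on the original scale
#' (`1 - SSres/SStot`) so methods are comparable.
#'
#' @param points Data frame with columns `ldm_max` (or `ldm`) and `nc`;
#'   >= 3 rows, all positive.
#' @param method `"loglog_ols"` (default) or `"nonlinear_ls"`.
#' @param group Optional label stored on the curve.
#' @return A [dilution_curve()].
#' @examples
#' pts <- data.frame(ldm_max = c(0.5, 1, 2, 3), nc = 3 * c(0.5, 1, 2, 3)^-0.5)
#' fit_curve(pts) # recovers a = 3, b = 0.5, r2 = 1
#' @export
fit_curve <- function(points, method = c("loglog_ols", "nonlinear_ls"),
                      group = NULL) {
  method <- match.arg(method)
  pm <- points_matrix(points)
  if (nrow(pm) < 3) {
    stop("insufficient data: need >= 3 critical points, got ", nrow(pm),
         call. = FALSE)
  }
  if (any(!is.finite(pm$ldm) | !is.finite(pm$nc) | pm$ldm <= 0 |
            pm$nc <= 0)) {
    stop("critical points must have positive finite ldm and nc",
         call. = FALSE)
  }
  co <- coef(lm(log(nc) ~ log(ldm), data = pm))
  a <- exp(unname(co[1])); b <- -unname(co[2])
  if (method == "nonlinear_ls") {
    nl <- minpack.lm::nlsLM(nc ~ a * ldm^(-b), data = pm,
                            start = list(a = a, b = b))
    a <- unname(coef(nl)["a"]); b <- unname(coef(nl)["b"])
  }
  pred <- a * pm$ldm^(-b)
  r2 <- 1 - sum((pm$nc - pred)^2) / sum((pm$nc - mean(pm$nc))^2)
  dilution_curve(a, b, r2 = r2, n_points = nrow(pm), fit_method = method,
                 group = group, ldm_range = range(pm$ldm))
}

#' Evaluate a dilution curve: critical N at a given leaf dry matter
#'
#' @param curve A [dilution_curve()].
#' @param ldm Leaf dry matter, t/ha; > 0 (vectorized).
#' @return Critical N concentration(s), % of dry weight.
#' @export
evaluate_nc <- function(curve, ldm) {
  stopifnot(inherits(curve, "dilution_curve"))
  if (any(!is.finite(ldm) | ldm <= 0)) {
    stop("`ldm` must be positive and finite", call. = FALSE)
  }
  if (!is.null(curve$ldm_range) &&
      any(ldm < curve$ldm_range[1] | ldm > curve$ldm_range[2])) {
    warning("evaluating the curve outside the fitted LDM range [",
            signif(curve$ldm_range[1], 4), ", ",
            signif(curve$ldm_range[2], 4), "] t/ha", call. = FALSE)
  }
  curve$a * ldm^(-curve$b)
}

#' Compare two sets of critical points on the linearized curve
#'
#' Tests whether two groups of critical points (varieties, years, seasons)
#' share one dilution curve, on the linearized scale
#' `ln Nc = ln a - b ln LDM`. Sequential analysis of variance: first an
#' F-test of the slope-by-group interaction (equal exponent `b`); then,
#' under a common slope, an F-test of the group main effect (equal
#' intercept `ln a`). The verdict is `"different"` when either test
#' rejects at `alpha`.
#'
#' @param points_a,points_b Critical-point data frames (>= 3 rows each,
#'   positive `ldm_max`/`nc`, non-degenerate `ldm_max`).
#' @param alpha Significance level.
#' @return A `curve_comparison` with `p_slope`, `p_intercept`, `alpha`,
#'   `verdict`.
#' @export
compare_curves <- function(points_a, points_b, alpha = 0.05) {
  if (!(is.numeric(alpha) && length(alpha) == 1 && alpha > 0 && alpha < 1)) {
    stop("`alpha` must be a single value in (0, 1)", call. = FALSE)
  }
  pa <- points_matrix(points_a); pb <- points_matrix(points_b)
  for (p in list(pa, pb)) {
    if (nrow(p) < 3) stop("each point set needs >= 3 points", call. = FALSE)
    if (any(p$ldm <= 0 | p$nc <= 0)) {
      stop("critical points must be positive", call. = FALSE)
    }
    if (var(log(p$ldm)) == 0) {
      stop("degenerate design: all ln(ldm) equal in one group",
           call. = FALSE)
    }
  }
  dat <- data.frame(
    lnnc = log(c(pa$nc, pb$nc)),
    lnldm = log(c(pa$ldm, pb$ldm)),
    grp = factor(rep(c("A", "B"), c(nrow(pa), nrow(pb))))
  )
  full <- lm(lnnc ~ lnldm * grp, data = dat)
  p_slope <- anova(full)["lnldm:grp", "Pr(>F)"]
  common <- lm(lnnc ~ lnldm + grp, data = dat)
  p_intercept <- anova(common)["grp", "Pr(>F)"]
  # identical point sets leave zero interaction/group SS; report p = 1
  if (is.na(p_slope)) p_slope <- 1
  if (is.na(p_intercept)) p_intercept <- 1
  structure(
    list(p_slope = p_slope, p_intercept = p_intercept, alpha = alpha,
         verdict = if (p_slope < alpha || p_intercept < alpha) "different"
                   else "not_different"),
    class = "curve_comparison"
  )
}

#' @export
print.curve_comparison <- function(x, ...) {
  cat("Linearized curve comparison (ln Nc ~ ln LDM):\n")
  cat(sprintf("  equal slope (b):        p = %.4g\n", x$p_slope))
  cat(sprintf("  equal intercept (ln a): p = %.4g\n", x$p_intercept))
  cat(sprintf("  verdict at alpha = %g: %s\n", x$alpha, x$verdict))
  invisible(x)
}
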