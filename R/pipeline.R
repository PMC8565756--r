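#' Run the full dilution-curve pipeline
#'
#' Orchestrates the whole analysis on one observation table: limitation
#' classification and critical-point extraction per sampling date, power-law
#' curve fitting per group (pooled by season, or per variety), a linearized
#' between-variety curve comparison within each season, the NNI table under
#' each group's curve, optional validation against hold-out data, and — when
#' yields are present — the quadratic relative-yield response to NNI at the
#' chosen stage. Optionally writes every result as CSV.
#'
#' @param input Path to an observation CSV, or a data frame accepted by
#'   [validate_observations()].
#' @param season Restrict to `"early"` or `"late"`; `NULL` keeps both.
#' @param pooling `"pooled_by_season"` (one curve per season, the default)
#'   or `"per_variety"` (one curve per season x variety).
#' @param method Classification method, see [extract_critical_points()].
#' @param alpha Significance level for classification and curve comparison;
#'   must lie in (0, 1).
#' @param fit_method Curve-fitting method, see [fit_curve()].
#' @param band Optimal-NNI band.
#' @param yield_stage Stage whose NNI enters the yield response.
#' @param holdout Optional hold-out data: either an observation table/path
#'   (points are extracted with the same `method`) or a critical-point data
#'   frame; each season curve is validated against the hold-out points of
#'   its season.
#' @param out_dir Optional directory for the CSV reports
#'   (`critical_points.csv`, `curve.csv`, `nni.csv`, `validation.csv`,
#'   `yield_response.csv`).
#' @param quiet Suppress the per-stage count messages.
#' @return A list bundle: `points`, `curves` (named list of
#'   [dilution_curve()]s), `comparisons`, `nni`, `validation`,
#'   `yield_response`, `counts`.
#' @examples
#' bundle <- run_pipeline(load_table2_fixture(), season = "early",
#'                        quiet = TRUE)
#' bundle$curves[["early"]]
#' @export
run_pipeline <- function(input,
                         season = NULL,
                         pooling = c("pooled_by_season", "per_variety"),
                         method = c("letters", "anova"),
                         alpha = 0.05,
                         fit_method = c("loglog_ols", "nonlinear_ls"),
                         band = c(0.95, 1.05),
                         yield_stage = "HS",
                         holdout = NULL,
                         out_dir = NULL,
                         quiet = FALSE) {
  pooling <- match.arg(pooling)
  method <- match.arg(method)
  fit_method <- match.arg(fit_method)
  if (!(is.numeric(alpha) && length(alpha) == 1 && alpha > 0 && alpha < 1)) {
    stop("`alpha` must be a single value in (0, 1)", call. = FALSE)
  }
  if (!is.null(season)) season <- match.arg(season, season_levels())

  table <- if (is.character(input)) read_observations(input) else
    validate_observations(input)
  if (!is.null(season)) table <- table[table$season == season, ]
  if (nrow(table) == 0) stop("no observations after filtering", call. = FALSE)

  say <- function(...) if (!quiet) message(sprintf(...))

  points <- extract_critical_points(table, method = method, alpha = alpha)
  skipped <- attr(points, "skipped")
  say("classified %d dates: %d critical points extracted, %d skipped",
      nrow(points) + length(skipped), nrow(points), length(skipped))
  if (nrow(points) == 0) stop("no usable sampling dates", call. = FALSE)

  key_of <- function(df) {
    if (pooling == "pooled_by_season") df$season
    else paste(df$season, df$variety, sep = "/")
  }
  points$group <- key_of(points)
  curves <- lapply(split(points, points$group), function(p) {
    fit_curve(p, method = fit_method, group = p$group[1])
  })
  for (g in names(curves)) {
    say("curve [%s]: a = %.3f, b = %.3f, R2 = %.3f (n = %d)",
        g, curves[[g]]$a, curves[[g]]$b, curves[[g]]$r2,
        curves[[g]]$n_points)
  }

  comparisons <- list()
  for (s in unique(points$season)) {
    vs <- unique(points$variety[points$season == s])
    if (length(vs) == 2) {
      pa <- points[points$season == s & points$variety == vs[1], ]
      pb <- points[points$season == s & points$variety == vs[2], ]
      if (nrow(pa) >= 3 && nrow(pb) >= 3) {
        cmp <- compare_curves(pa, pb, alpha = alpha)
        comparisons[[paste(s, vs[1], "vs", vs[2])]] <- cmp
        say("comparison [%s: %s vs %s]: p_slope = %.3f, p_intercept = %.3f (%s)",
            s, vs[1], vs[2], cmp$p_slope, cmp$p_intercept, cmp$verdict)
      }
    }
  }

  table$group <- key_of(table)
  nni <- dplyr::bind_rows(lapply(split(table, table$group), function(tb) {
    nni_table(tb[, setdiff(names(tb), "group")], curves[[tb$group[1]]],
              band = band)
  }))

  validation <- NULL
  if (!is.null(holdout)) {
    hp <- if (is.data.frame(holdout) &&
              all(c("ldm_max", "nc") %in% names(holdout))) {
      holdout
    } else {
      ht <- if (is.character(holdout)) read_observations(holdout) else
        validate_observations(holdout)
      extract_critical_points(ht, method = method, alpha = alpha)
    }
    hp$group <- key_of(hp)
    validation <- list()
    for (g in intersect(names(curves), unique(hp$group))) {
      rep_g <- validate_curve(curves[[g]], hp[hp$group == g, ])
      validation[[g]] <- rep_g
      say("validation [%s]: RMSE = %.3f, n-RMSE = %.2f%% (%s)",
          g, rep_g$rmse, rep_g$n_rmse, rep_g$stability)
    }
  }

  yield_response <- list()
  ytab <- table[!is.na(table$yield) & table$stage == yield_stage, ]
  if (nrow(ytab) > 0) {
    for (g in unique(ytab$group)) {
      tg <- ytab[ytab$group == g, ]
      trt <- tg |>
        dplyr::group_by(.data$variety, .data$season, .data$year,
                        .data$n_rate) |>
        dplyr::summarise(yield = mean(.data$yield), ldm = mean(.data$ldm),
                         pnc = mean(.data$pnc), .groups = "drop")
      trt <- trt |>
        dplyr::group_by(.data$season, .data$year) |>
        dplyr::mutate(ry = relative_yield(.data$yield)) |>
        dplyr::ungroup()
      nc <- suppressWarnings(evaluate_nc(curves[[g]], trt$ldm))
      trt$nni <- trt$pnc / nc
      if (nrow(trt) >= 4 && var(trt$nni) > 0) {
        yr <- fit_yield_response(trt$nni, trt$ry)
        yr$data <- trt
        yield_response[[g]] <- yr
        say("yield response [%s]: optimum NNI = %.3f, max RY = %.3f (R2 = %.3f)",
            g, yr$nni_opt, yr$ry_max, yr$r2)
      }
    }
  }

  bundle <- list(
    points = points, curves = curves, comparisons = comparisons,
    nni = nni, validation = validation, yield_response = yield_response,
    counts = list(dates_classified = nrow(points) + length(skipped),
                  points_extracted = nrow(points),
                  dates_skipped = length(skipped), skipped = skipped)
  )
  if (!is.null(out_dir)) write_bundle(bundle, out_dir)
  bundle
}

# CSV reports of a pipeline bundle, full numeric precision
write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, name) {
    write.csv(df, file.path(out_dir, name), row.names = FALSE, na = "")
  }
  wr(bundle$points, "critical_points.csv")
  wr(dplyr::bind_rows(lapply(names(bundle$curves), function(g) {
    cv <- bundle$curves[[g]]
    data.frame(group = g, a = cv$a, b = cv$b, r2 = cv$r2,
               n_points = cv$n_points, method = cv$fit_method)
  })), "curve.csv")
  wr(bundle$nni, "nni.csv")
  if (!is.null(bundle$validation)) {
    wr(dplyr::bind_rows(lapply(names(bundle$validation), function(g) {
      v <- bundle$validation[[g]]
      data.frame(group = g, rmse = v$rmse, n_rmse = v$n_rmse,
                 stability = v$stability, n = v$n)
    })), "validation.csv")
  }
  if (length(bundle$yield_response) > 0) {
    wr(dplyr::bind_rows(lapply(names(bundle$yield_response), function(g) {
      y <- bundle$yield_response[[g]]
      data.frame(group = g, c0 = y$c0, c1 = y$c1, c2 = y$c2, r2 = y$r2,
                 nni_opt = y$nni_opt, ry_max = y$ry_max, convex = y$convex,
                 n = y$n)
    })), "yield_response.csv")
  }
  invisible(out_dir)
}
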