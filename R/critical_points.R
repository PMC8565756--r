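#' Fit the oblique line through N-limited treatments
#'
#' Stage (b) of the Justes construction: ordinary least-squares line of PNC
#' on LDM through the N-limited treatment points of one sampling date.
#'
#' @param ldm,pnc Numeric vectors of the limited points (>= 2, `ldm` not
#'   all equal).
#' @return A list with `slope` (% N per t/ha) and `intercept` (% N).
#' @examples
#' fit_oblique(c(1, 2), c(2, 1)) # slope -1, intercept 3
#' @export
fit_oblique <- function(ldm, pnc) {
  if (length(ldm) != length(pnc)) stop("ldm and pnc differ in length",
                                       call. = FALSE)
  if (length(ldm) < 2) {
    stop("degenerate oblique fit: need >= 2 limited points", call. = FALSE)
  }
  if (var(ldm) == 0) {
    stop("degenerate oblique fit: zero LDM variance", call. = FALSE)
  }
  co <- coef(lm(pnc ~ ldm))
  list(slope = unname(co[2]), intercept = unname(co[1]))
}

#' Mean LDM of the non-limited treatments (the vertical line)
#'
#' Stage (c): the maximum LDM of a sampling date is the arithmetic mean of
#' the non-N-limited treatment mean LDMs.
#'
#' @param ldm Numeric vector of non-limited treatment LDMs (>= 1).
#' @return The mean, t/ha.
#' @export
vertical_ldm <- function(ldm) {
  if (length(ldm) == 0) stop("no non-limited treatments", call. = FALSE)
  mean(ldm)
}

#' Extract the critical point of one sampling date
#'
#' Stage (d): intersects the oblique line through the limited treatment
#' means with the vertical line at the non-limited mean LDM. The critical N
#' concentration is the oblique evaluated at that LDM, so the point lies on
#' both lines by construction. A non-positive oblique slope, or a critical
#' value outside the range of the date's observed PNC, is reported with a
#' warning but not rejected.
#'
#' @param classified A `limitation_result` for the date (must be usable).
#' @param means Mean-level observations of the same date (columns `n_rate`,
#'   `ldm`, `pnc`; one row per rate).
#' @return A one-row tibble: group key, `ldm_max`, `nc`, `oblique_slope`,
#'   `oblique_intercept`, `n_limited`.
#' @export
extract_point <- function(classified, means) {
  stopifnot(inherits(classified, "limitation_result"))
  if (!classified$usable) {
    stop("date not usable for critical-point extraction (needs >= 2 ",
         "limited and >= 1 non-limited treatments)", call. = FALSE)
  }
  m <- dplyr::left_join(classified$labels, means, by = "n_rate")
  if (any(is.na(m$ldm) | is.na(m$pnc))) {
    stop("means are missing some classified N rates", call. = FALSE)
  }
  lim <- m[m$label == "limited", ]
  nl <- m[m$label == "non_limited", ]
  ob <- fit_oblique(lim$ldm, lim$pnc)
  ldm_max <- vertical_ldm(nl$ldm)
  nc <- ob$intercept + ob$slope * ldm_max
  if (ob$slope <= 0) {
    warning("oblique slope is non-positive (", signif(ob$slope, 4),
            ") for stage ", classified$group$stage, call. = FALSE)
  }
  if (nc < min(m$pnc) || nc > max(m$pnc)) {
    warning("critical N ", signif(nc, 4),
            " falls outside the observed PNC range for stage ",
            classified$group$stage, call. = FALSE)
  }
  g <- classified$group
  tibble::tibble(
    variety = g$variety, season = g$season, year = g$year, stage = g$stage,
    ldm_max = ldm_max, nc = nc,
    oblique_slope = ob$slope, oblique_intercept = ob$intercept,
    n_limited = nrow(lim)
  )
}

# treatment means of one date (identity on mean-level records)
date_means <- function(obs) {
  obs |>
    dplyr::group_by(.data$n_rate) |>
    dplyr::summarise(ldm = mean(.data$ldm), pnc = mean(.data$pnc),
                     .groups = "drop")
}

#' Extract critical points for every usable sampling date of a trial
#'
#' Applies limitation classification and critical-point extraction to each
#' (variety, season, year, stage) group of an observation table. Dates that
#' are not usable (no contrast, or fewer than two limited treatments) are
#' skipped, mirroring the Justes convention of discarding uninformative
#' dates; their count is carried in the `skipped` attribute.
#'
#' The oblique line is always fitted to treatment means (one point per N
#' rate); with `oblique_level = "replicates"` the raw replicate values are
#' used instead.
#'
#' @param table A validated observation table (mean-level with letters for
#'   `method = "letters"`, replicate-level for `method = "anova"`).
#' @param method Classification method.
#' @param alpha Significance level for the ANOVA route.
#' @param oblique_level Fit the oblique to treatment `"means"` (default) or
#'   to raw `"replicates"`.
#' @return A tibble of critical points (one row per usable date) with
#'   attribute `skipped` naming the dates that emitted no point.
#' @examples
#' pts <- extract_critical_points(
#'   dplyr::filter(load_table2_fixture(), season == "early"))
#' pts
#' @export
extract_critical_points <- function(table,
                                    method = c("letters", "anova"),
                                    alpha = 0.05,
                                    oblique_level = c("means", "replicates")) {
  method <- match.arg(method)
  oblique_level <- match.arg(oblique_level)
  table <- validate_observations(table)
  groups <- table |>
    dplyr::group_by(.data$variety, .data$season, .data$year, .data$stage) |>
    dplyr::group_split()
  skipped <- character(0)
  out <- list()
  for (g in groups) {
    cl <- switch(method,
                 letters = classify_letters(g),
                 anova = classify_anova(g, alpha = alpha))
    tag <- paste(cl$group$variety, cl$group$season, cl$group$stage, sep = "/")
    if (!cl$usable) {
      skipped <- c(skipped, tag)
      next
    }
    means <- date_means(g)
    if (oblique_level == "replicates" && !any(is.na(g$replicate))) {
      # replace the limited means by replicate points for the oblique only
      lim_rates <- cl$labels$n_rate[cl$labels$label == "limited"]
      lim <- g[g$n_rate %in% lim_rates, ]
      nl_means <- means[!means$n_rate %in% lim_rates, ]
      ob <- fit_oblique(lim$ldm, lim$pnc)
      ldm_max <- vertical_ldm(nl_means$ldm)
      nc <- ob$intercept + ob$slope * ldm_max
      out[[length(out) + 1]] <- tibble::tibble(
        variety = cl$group$variety, season = cl$group$season,
        year = cl$group$year, stage = cl$group$stage,
        ldm_max = ldm_max, nc = nc,
        oblique_slope = ob$slope, oblique_intercept = ob$intercept,
        n_limited = length(lim_rates)
      )
    } else {
      out[[length(out) + 1]] <- extract_point(cl, means)
    }
  }
  res <- dplyr::bind_rows(out)
  attr(res, "skipped") <- skipped
  res
}
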