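#' @title Limitation classification of N treatments at one sampling date
#' @description Internal constructor of the classification result shared by
#'   [classify_anova()] and [classify_letters()].
#' @noRd
new_limitation_result <- function(group, labels, method, alpha) {
  usable <- sum(labels$label == "limited") >= 2 &&
    sum(labels$label == "non_limited") >= 1
  structure(
    list(group = group, labels = labels, method = method, alpha = alpha,
         usable = usable),
    class = "limitation_result"
  )
}

#' @export
print.limitation_result <- function(x, ...) {
  cat(sprintf("Limitation classification (%s%s) for %s / %s / %s:\n",
              x$method,
              if (is.na(x$alpha)) "" else sprintf(", alpha = %g", x$alpha),
              x$group$variety, x$group$season, x$group$stage))
  print(x$labels)
  cat(if (x$usable) "usable for critical-point extraction\n" else
        "not usable (needs >= 2 limited and >= 1 non-limited)\n")
  invisible(x)
}

group_key <- function(obs) {
  list(variety = unique(obs$variety)[1], season = unique(obs$season)[1],
       year = unique(obs$year)[1], stage = unique(obs$stage)[1])
}

check_one_date <- function(obs) {
  for (col in c("variety", "season", "stage")) {
    if (dplyr::n_distinct(obs[[col]]) != 1) {
      stop("observations must belong to a single (variety, season, year, ",
           "stage) group; found several `", col, "` values", call. = FALSE)
    }
  }
}

#' Classify N treatments by one-way ANOVA and Tukey comparisons
#'
#' Stage (a) of the Justes construction on replicate-level data: a one-way
#' ANOVA of LDM on N rate decides whether the date carries any biomass
#' signal; if the global F-test is significant at `alpha`, treatments whose
#' mean LDM is significantly lower (Tukey HSD) than the treatment with the
#' largest mean LDM are N-limited, the rest (including the top treatment
#' and any exact ties) non-N-limited. A non-significant F-test labels
#' every treatment non-limited and marks the date unusable.
#'
#' @param observations Replicate-level observations of one
#'   (variety, season, year, stage) group: >= 3 N rates, >= 2 replicates
#'   each.
#' @param alpha Significance level (default 0.05).
#' @return A `limitation_result` with per-rate labels, the method, `alpha`
#'   and the `usable` flag (>= 2 limited and >= 1 non-limited).
#' @examples
#' sim <- simulate_experiment(synthetic_config(seed = 1))
#' ts <- dplyr::filter(sim$table, stage == "TS")
#' classify_anova(ts)
#' @export
classify_anova <- function(observations, alpha = 0.05) {
  check_one_date(observations)
  if (!(is.numeric(alpha) && length(alpha) == 1 && alpha > 0 && alpha < 1)) {
    stop("`alpha` must be a single value in (0, 1)", call. = FALSE)
  }
  obs <- observations
  if (any(is.na(obs$replicate))) {
    stop("classify_anova needs replicate-level observations; ",
         "use classify_letters() for mean-level records", call. = FALSE)
  }
  reps <- table(obs$n_rate)
  if (length(reps) < 3) {
    stop("need >= 3 N-rate levels, got ", length(reps), call. = FALSE)
  }
  if (any(reps < 2)) {
    stop("insufficient replication: < 2 replicates at rate(s) ",
         paste(names(reps)[reps < 2], collapse = ", "), call. = FALSE)
  }

  rate <- factor(obs$n_rate)
  fit <- aov(ldm ~ rate, data = data.frame(ldm = obs$ldm, rate = rate))
  p_global <- summary(fit)[[1]][["Pr(>F)"]][1]
  means <- tapply(obs$ldm, rate, mean)
  rates <- as.numeric(names(means))
  top <- names(means)[means == max(means)]

  labels <- rep("non_limited", length(means))
  names(labels) <- names(means)
  # degenerate zero-variance data gives NaN F: no evidence of limitation
  if (is.finite(p_global) && p_global < alpha) {
    tk <- TukeyHSD(fit)$rate
    cmp <- rownames(tk)
    for (lev in setdiff(names(means), top)) {
      pair <- c(paste0(lev, "-", top[1]), paste0(top[1], "-", lev))
      row <- tk[cmp %in% pair, , drop = FALSE]
      if (nrow(row) >= 1 && row[1, "p adj"] < alpha &&
          means[lev] < max(means)) {
        labels[lev] <- "limited"
      }
    }
  }
  res <- new_limitation_result(
    group_key(obs),
    tibble::tibble(n_rate = rates, label = unname(labels[as.character(rates)])),
    method = "anova_posthoc", alpha = alpha
  )
  if (!(is.finite(p_global) && p_global < alpha)) res$usable <- FALSE
  res$p_global <- p_global
  res
}

#' Classify N treatments from published significance letters
#'
#' Stage (a) of the Justes construction on mean-level data that carries
#' compact letter displays (P < 0.05 post-hoc groupings) for LDM, as
#' published tables do: a treatment is non-N-limited when it shares at
#' least one letter with the treatment of maximal mean LDM (all treatments
#' tied for the maximum are non-limited); every other treatment is
#' N-limited.
#'
#' @param observations Mean-level observations of one
#'   (variety, season, year, stage) group with non-empty `sig_letter`.
#' @return A `limitation_result` (see [classify_anova()]); `alpha` is `NA`
#'   because the letters carry their own published level.
#' @examples
#' tab <- load_table2_fixture()
#' ts <- dplyr::filter(tab, variety == "Zhongjiazao 17", stage == "TS")
#' classify_letters(ts)
#' @export
classify_letters <- function(observations) {
  check_one_date(observations)
  obs <- observations
  if (any(is.na(obs$sig_letter) | !nzchar(obs$sig_letter))) {
    stop("missing significance letters; classify replicate-level data ",
         "with classify_anova() instead", call. = FALSE)
  }
  letters_of <- strsplit(obs$sig_letter, "")
  top_idx <- which(obs$ldm == max(obs$ldm))
  top_letters <- unique(unlist(letters_of[top_idx]))
  shares <- vapply(letters_of, function(l) any(l %in% top_letters), logical(1))
  labels <- ifelse(shares, "non_limited", "limited")
  labels[top_idx] <- "non_limited"
  ord <- order(obs$n_rate)
  new_limitation_result(
    group_key(obs),
    tibble::tibble(n_rate = obs$n_rate[ord], label = labels[ord]),
    method = "letters", alpha = NA_real_
  )
}
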