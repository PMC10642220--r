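# Summary artefacts: absolute/relative change tables and trend figures with
# prediction bands.

#' Absolute and relative change table
#'
#' For every indicator x sex cell and every (base year, comparison year)
#' pair: the absolute change in percentage points
#' (`100 * (p_comparison - p_base)`) and the relative change in per cent
#' (`100 * absolute / base`, computed from the unrounded base, then rounded).
#' A base prevalence of zero leaves the relative change missing with a
#' warning.
#'
#' @param series a `prevalence_series` (or any data frame with `indicator`,
#'   `sex`, `year`, `prevalence` as proportions).
#' @param base_years,comparison_years equal-length vectors pairing each
#'   comparison year with its base year (recycled if one is scalar).
#' @param digits rounding of the output columns (`c(absolute, relative)`);
#'   set `NULL` to keep full precision.
#' @return a data frame: `indicator`, `sex`, `base_year`, `comparison_year`,
#'   `base_prevalence` (%), `absolute_change` (pp), `relative_change` (%).
#' @export
change_table <- function(series, base_years, comparison_years,
                         digits = c(1, 1)) {
  n <- max(length(base_years), length(comparison_years))
  base_years <- rep_len(base_years, n)
  comparison_years <- rep_len(comparison_years, n)
  cells <- unique(series[c("indicator", "sex")])
  out <- list()
  for (r in seq_len(nrow(cells))) {
    ind <- cells$indicator[r]; sx <- cells$sex[r]
    sub <- series[series$indicator == ind & series$sex == sx, ]
    for (j in seq_len(n)) {
      pb <- sub$prevalence[sub$year == base_years[j]]
      pc <- sub$prevalence[sub$year == comparison_years[j]]
      if (!length(pb) || !length(pc))
        stop("series lacks ", ind, "/", sx, " at year ",
             base_years[j], " or ", comparison_years[j])
      abs_pp <- 100 * (pc - pb)
      rel <- if (pb == 0) {
        warning("base prevalence 0 for ", ind, "/", sx,
                "; relative change undefined")
        NA_real_
      } else 100 * abs_pp / (100 * pb)
      out[[length(out) + 1]] <- data.frame(
        indicator = ind, sex = sx,
        base_year = base_years[j], comparison_year = comparison_years[j],
        base_prevalence = 100 * pb,
        absolute_change = abs_pp, relative_change = rel)
    }
  }
  out <- do.call(rbind, out)
  if (!is.null(digits)) {
    out$absolute_change <- round(out$absolute_change, digits[1])
    out$relative_change <- round(out$relative_change, digits[2])
    out$base_prevalence <- round(out$base_prevalence, digits[1])
  }
  rownames(out) <- NULL
  out
}

#' Recompute a relative change from printed table cells
#'
#' Worked-example arithmetic: given a base prevalence (%) and an absolute
#' change (percentage points), the relative change in per cent rounded to
#' one decimal. Used to check published change tables for self-consistency.
#'
#' @param base_prevalence base prevalence in per cent.
#' @param absolute_change absolute change in percentage points.
#' @param digits rounding of the result.
#' @return relative change in per cent.
#' @export
relative_change <- function(base_prevalence, absolute_change, digits = 1) {
  if (any(base_prevalence == 0)) stop("base prevalence of 0 has no relative change")
  round(100 * absolute_change / base_prevalence, digits)
}

#' Trend and projection figure
#'
#' Per-sex prevalence curves over the observed and projected years with a
#' shaded prediction band and a vertical break at the last observed wave.
#' For the BMI indicator the three category curves are overlaid.
#'
#' @param series a `prevalence_series`.
#' @param indicators indicator name(s) to plot (BMI categories may be
#'   requested together via `"bmi"`).
#' @param path optional output file (PNG/SVG/PDF by extension); when `NULL`
#'   the ggplot object is returned without writing.
#' @param width,height device size in inches when writing.
#' @return the ggplot object, invisibly when written to file.
#' @export
trend_plot <- function(series, indicators, path = NULL,
                       width = 7, height = 4.5) {
  stopifnot(nrow(series) > 0)
  wanted <- unlist(lapply(indicators, function(i) {
    if (i == "bmi") paste0("bmi_", BMI_LEVELS) else i
  }))
  unknown <- setdiff(wanted, unique(series$indicator))
  if (length(unknown))
    stop("unknown indicator(s): ", paste(unknown, collapse = ", "))
  dat <- series[series$indicator %in% wanted, ]
  break_year <- if (any(dat$source == "observed-imputed"))
    max(dat$year[dat$source == "observed-imputed"]) else NA
  p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$year,
                                         y = 100 * .data$prevalence,
                                         colour = .data$indicator,
                                         fill = .data$indicator)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = 100 * .data$interval_low,
                                      ymax = 100 * .data$interval_high),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~sex) +
    ggplot2::labs(x = "Year", y = "Prevalence (%)",
                  colour = NULL, fill = NULL) +
    ggplot2::theme_minimal()
  if (!is.na(break_year))
    p <- p + ggplot2::geom_vline(xintercept = break_year, linetype = "dashed",
                                 colour = "grey40")
  if (!is.null(path)) {
    ggplot2::ggsave(path, p, width = width, height = height)
    return(invisible(p))
  }
  p
}
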