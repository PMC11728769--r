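#' Distribution summary of a cohort variable
#'
#' Numerical stand-in for the density-plot comparisons used to inspect
#' simulated cohorts: per group, a 1%..99% quantile grid, a normalized
#' histogram (masses sum to 1), and — when a reference table is supplied — a
#' two-sample Kolmogorov-Smirnov statistic against the same variable in the
#' reference.
#'
#' @param table Patient table.
#' @param variable Canonical variable name (e.g. `"height"`, `"crp"`) or a
#'   column name of the table.
#' @param group_by Optional column name to stratify by (e.g. `"sex"`).
#' @param reference Optional reference patient table.
#' @param bins Number of histogram bins (shared edges across groups).
#' @return Object of class `density_summary`; convert with
#'   [as.data.frame.density_summary()] for a long-format export (columns:
#'   variable, group, bin_low, bin_high, mass).
#' @export
density_summary <- function(table, variable, group_by = NULL,
                            reference = NULL, bins = 30) {
  cols <- var_columns()
  column <- if (variable %in% names(cols)) cols[[variable]] else variable
  if (!column %in% names(table)) {
    stop_config("unknown variable '%s'", variable)
  }
  if (!is.null(group_by) && !group_by %in% names(table)) {
    stop_config("unknown grouping column '%s'", group_by)
  }
  values <- table[[column]]
  groups <- if (is.null(group_by)) rep("all", length(values))
            else as.character(table[[group_by]])
  ref_values <- if (!is.null(reference)) {
    if (!column %in% names(reference)) {
      stop_config("reference table lacks column '%s'", column)
    }
    reference[[column]]
  } else NULL

  rng <- range(c(values, ref_values), finite = TRUE)
  if (rng[1] == rng[2]) rng <- rng + c(-0.5, 0.5)
  edges <- seq(rng[1], rng[2], length.out = bins + 1L)
  qs <- seq(0.01, 0.99, by = 0.01)

  per_group <- lapply(split(values, groups), function(x) {
    if (!length(x)) stop_config("empty group")
    h <- graphics::hist(x, breaks = edges, plot = FALSE)
    mass <- h$counts / sum(h$counts)
    ks <- if (!is.null(ref_values)) {
      suppressWarnings(stats::ks.test(x, ref_values)$statistic)
    } else NA_real_
    list(quantiles = stats::quantile(x, qs, names = FALSE),
         mass = mass, ks_statistic = unname(ks), n = length(x))
  })
  structure(list(variable = variable, column = column,
                 group_by = group_by %||% "none",
                 quantile_probs = qs, bin_edges = edges,
                 groups = per_group),
            class = "density_summary")
}

#' @rdname density_summary
#' @param x A `density_summary`.
#' @param ... Unused.
#' @export
as.data.frame.density_summary <- function(x, ...) {
  lo <- x$bin_edges[-length(x$bin_edges)]
  hi <- x$bin_edges[-1]
  do.call(rbind, lapply(names(x$groups), function(g) {
    data.frame(variable = x$variable, group = g, bin_low = lo, bin_high = hi,
               mass = x$groups[[g]]$mass, stringsAsFactors = FALSE)
  }))
}

#' @export
print.density_summary <- function(x, ...) {
  cat(sprintf("Density summary of %s (grouped by %s): %d group(s), %d bins\n",
              x$variable, x$group_by, length(x$groups),
              length(x$bin_edges) - 1L))
  for (g in names(x$groups)) {
    gg <- x$groups[[g]]
    med <- gg$quantiles[which(x$quantile_probs == 0.5)]
    cat(sprintf("  %-12s n=%6d median=%.4g%s\n", g, gg$n, med,
                if (!is.na(gg$ks_statistic))
                  sprintf(" KS=%.4f", gg$ks_statistic) else ""))
  }
  invisible(x)
}

#' Write a density summary as delimited text
#'
#' Long format suitable for external plotting: variable, group, bin_low,
#' bin_high, mass.
#'
#' @param summary A [density_summary()].
#' @param path Output file path.
#' @export
write_density_summary <- function(summary, path) {
  utils::write.csv(as.data.frame(summary), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
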