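# Regulatory-group assignment, grouped ECDFs, and KS comparison of groups.

#' Partition targets into regulatory groups
#'
#' Divides targets by the sign or the empirical quantiles of a signed
#' value: the perturbation statistic of a single factor (groups Down /
#' None / Up) or the regulatory interaction of two factors (groups
#' Competitive / None / Cooperative).  With \code{method = "sign"},
#' negative values go to the first group, zeros to the middle, positives
#' to the third.  With \code{method = "quantile"}, values strictly below
#' the lower empirical quantile go to the first group, strictly above the
#' upper quantile to the third, the rest to the middle.
#'
#' @param values Finite numeric vector (signed statistics or RI terms).
#' @param method \code{"sign"} or \code{"quantile"}.
#' @param quantiles Pair of probabilities \code{0 < q_low < q_high < 1}
#'   for the quantile method.
#' @param labels Three group labels, low/middle/high.
#' @return Factor of group labels, parallel to \code{values}, with levels
#'   \code{labels}.
#' @export
assign_groups <- function(values, method = c("sign", "quantile"),
                          quantiles = c(1 / 3, 2 / 3),
                          labels = c("Down", "None", "Up")) {
  method <- match.arg(method)
  if (any(!is.finite(values))) {
    stop_contract("values must be finite")
  }
  if (length(labels) != 3) {
    stop_contract("labels must have length 3 (low, middle, high)")
  }
  if (method == "sign") {
    out <- ifelse(values < 0, labels[1], ifelse(values > 0, labels[3],
                                                labels[2]))
  } else {
    if (length(quantiles) != 2 || !(0 < quantiles[1]) ||
          !(quantiles[1] < quantiles[2]) || !(quantiles[2] < 1)) {
      stop_contract("quantiles must satisfy 0 < q_low < q_high < 1")
    }
    if (length(unique(values)) == 1) {
      stop_contract("all values identical: quantile grouping is degenerate")
    }
    q <- stats::quantile(values, probs = quantiles, names = FALSE)
    out <- ifelse(values < q[1], labels[1], ifelse(values > q[2], labels[3],
                                                   labels[2]))
  }
  factor(out, levels = labels)
}

#' Per-group empirical cumulative distribution functions
#'
#' Splits \code{values} by group and returns one right-continuous ECDF per
#' non-empty group, each evaluable at any real as
#' (number of group values <= x) / group size.  Empty groups are omitted
#' with a warning.
#'
#' @param values Numeric vector (typically ranks or rank products).
#' @param groups Parallel factor or character vector of group labels.
#' @return Named list of \code{\link[stats]{ecdf}} functions.
#' @export
ecdf_by_group <- function(values, groups) {
  if (length(values) != length(groups)) {
    stop_contract("values and groups must be parallel (%d vs %d)",
                  length(values), length(groups))
  }
  parts <- split(values, groups)
  empty <- names(parts)[lengths(parts) == 0]
  if (length(empty) > 0) {
    warning(sprintf("omitting empty group(s): %s",
                    paste(empty, collapse = ", ")))
    parts <- parts[lengths(parts) > 0]
  }
  lapply(parts, stats::ecdf)
}

#' KS comparison of two regulatory groups
#'
#' Two-sample Kolmogorov-Smirnov test (via \code{\link[stats]{ks.test}})
#' between the values of two named groups.  \code{alternative =
#' "greater"} asserts that the first group's ECDF lies above the second's
#' (i.e. the first group concentrates at smaller values — for rank inputs,
#' at stronger targets); \code{"less"} is the reverse;
#' \code{"two_sided"} uses D = sup |F_a - F_b|.  Ties (common among
#' midranked data) make the p-value approximate; the standard caveat is
#' reported as a message rather than a warning.
#'
#' @param values Numeric vector of the ranking signal.
#' @param groups Parallel factor/character of group labels.
#' @param compare Ordered pair of group labels \code{c(a, b)}.
#' @param alternative \code{"two_sided"}, \code{"greater"} or
#'   \code{"less"}.
#' @return One-row data.frame: \code{group_a}, \code{group_b},
#'   \code{alternative}, \code{n_a}, \code{n_b}, \code{ks_statistic},
#'   \code{p_value}.
#' @export
test_predictions <- function(values, groups,
                             compare = c("Down", "Up"),
                             alternative = c("two_sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  if (length(values) != length(groups)) {
    stop_contract("values and groups must be parallel")
  }
  groups <- as.character(groups)
  if (length(compare) != 2) {
    stop_contract("compare must name exactly two groups")
  }
  unknown <- setdiff(compare, unique(groups))
  if (length(unknown) > 0) {
    stop_contract("unknown group label(s): %s", paste(unknown, collapse = ", "))
  }
  a <- values[groups == compare[1]]
  b <- values[groups == compare[2]]
  if (length(a) < 2 || length(b) < 2) {
    warning("group with fewer than 2 values; KS test may be uninformative")
  }
  res <- withCallingHandlers(
    stats::ks.test(a, b, alternative = sub("_", ".", alternative)),
    warning = function(w) {
      if (grepl("ties", conditionMessage(w))) {
        message("KS caveat: ", conditionMessage(w))
        invokeRestart("muffleWarning")
      }
    }
  )
  data.frame(group_a = compare[1], group_b = compare[2],
             alternative = alternative,
             n_a = length(a), n_b = length(b),
             ks_statistic = unname(res$statistic),
             p_value = unname(res$p.value),
             stringsAsFactors = FALSE)
}

#' Plot grouped ECDF step curves
#'
#' Step plot of the per-group ECDFs of the ranking signal, one curve per
#' group, matching [ecdf_by_group()] exactly (purely presentational).
#' When the target group of a factor pair concentrates at small rank
#' products its curve lies above the others.
#'
#' @inheritParams ecdf_by_group
#' @param file Optional output path; the image format follows the
#'   extension (png, pdf, svg).  When \code{NULL} nothing is written.
#' @param xlab X-axis label.
#' @return The ggplot object, invisibly.
#' @export
plot_predictions <- function(values, groups, file = NULL,
                             xlab = "rank product") {
  if (length(values) != length(groups)) {
    stop_contract("values and groups must be parallel")
  }
  df <- data.frame(value = values, group = factor(groups))
  df <- df[df$group %in% names(which(table(df$group) > 0)), , drop = FALSE]
  df$group <- droplevels(df$group)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$value,
                                        colour = .data$group)) +
    ggplot2::stat_ecdf(geom = "step", linewidth = 0.7) +
    ggplot2::labs(x = xlab, y = "ECDF", colour = "group") +
    ggplot2::theme_classic()
  if (!is.null(file)) {
    dev <- if (grepl("\\.svg$", file, ignore.case = TRUE)) {
      grDevices::svg
    } else {
      NULL
    }
    ggplot2::ggsave(file, plot = p, device = dev, width = 6, height = 4,
                    dpi = 150)
  }
  invisible(p)
}
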