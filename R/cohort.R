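#' Cross-neuron reporting: laminar assignment and group comparisons
#'
#' @name cohort_stats
NULL

#' Laminar depth boundaries (micrometres from the cortical surface)
#'
#' Cut-points between layers: L1-L2/3 at 157, L2/3-L4 at 575, L4-L5 at 900,
#' L5-L6 at 1411, L6-white matter at 1973.
#' @export
layer_boundaries <- function() {
  c("L1" = 157, "L2/3" = 575, "L4" = 900, "L5" = 1411, "L6" = 1973)
}

#' Assign a cortical layer from recording depth
#'
#' Half-open binning [lower, upper): a depth equal to a boundary belongs to
#' the deeper layer.
#'
#' @param depth_um depth(s) from the cortical surface, micrometres (>= 0).
#' @param boundaries named upper cut-points as from [layer_boundaries()].
#' @return character vector of layer labels ("L1", "L2/3", "L4", "L5", "L6",
#'   "WM").
#' @export
assign_layer <- function(depth_um, boundaries = layer_boundaries()) {
  if (any(depth_um < 0)) stop("depth must be >= 0")
  labels <- c(names(boundaries), "WM")
  labels[findInterval(depth_um, boundaries, left.open = FALSE) + 1L]
}

#' Group comparison wrapper
#'
#' Dispatches to the named standard test and returns its statistic and
#' two-sided p-value.
#'
#' @param values numeric vector (for correlation: x).
#' @param groups group labels aligned with `values` (two-group tests and
#'   Kruskal-Wallis), or the y variable for "pearson", or the paired second
#'   sample for "signed-rank".
#' @param test one of "rank-sum", "mann-whitney" (synonyms: two-sided Wilcoxon
#'   rank-sum), "signed-rank" (paired), "kruskal-wallis", "pearson".
#' @return list with `statistic`, `p_value`, `test`, and `estimate` for
#'   correlation.
#' @export
group_compare <- function(values, groups,
                          test = c("rank-sum", "mann-whitney", "signed-rank",
                                   "kruskal-wallis", "pearson")) {
  test <- match.arg(test)
  if (test %in% c("rank-sum", "mann-whitney")) {
    g <- factor(groups)
    if (nlevels(g) != 2) stop("rank-sum test needs exactly 2 groups")
    ht <- stats::wilcox.test(values[g == levels(g)[1]],
                             values[g == levels(g)[2]], exact = FALSE)
  } else if (test == "signed-rank") {
    ht <- stats::wilcox.test(values, groups, paired = TRUE, exact = FALSE)
  } else if (test == "kruskal-wallis") {
    ht <- stats::kruskal.test(values, factor(groups))
  } else {
    if (stats::sd(values) == 0 || stats::sd(groups) == 0) {
      stop("degenerate input: constant vector for correlation")
    }
    ht <- stats::cor.test(values, groups, method = "pearson")
  }
  out <- list(statistic = unname(ht$statistic), p_value = ht$p.value,
              test = test)
  if (test == "pearson") out$estimate <- unname(ht$estimate)
  out
}

#' Summary tables across decoded neurons
#'
#' @param neuron_results data frame with one row per neuron: `neuron_id`,
#'   `area_tag`, `depth`, `performance` (%), optionally `shuffled_performance`
#'   and per-state columns.
#' @param holm apply Holm correction to the per-table Kruskal-Wallis p-values
#'   (the default reports raw p-values).
#' @return list of data frames: `by_area`, `by_area_layer`, and `layer_tests`
#'   (Kruskal-Wallis across layers within each area, where >= 2 layers have
#'   >= 2 neurons).
#' @export
build_report <- function(neuron_results, holm = FALSE) {
  stopifnot(nrow(neuron_results) >= 1)
  nr <- neuron_results
  nr$layer <- assign_layer(nr$depth)
  agg <- function(df, by) {
    out <- do.call(rbind, lapply(split(df, df[by], drop = TRUE), function(g) {
      row <- g[1, by, drop = FALSE]
      row$n <- nrow(g)
      row$mean_performance <- mean(g$performance)
      row$sd_performance <- if (nrow(g) > 1) stats::sd(g$performance) else NA_real_
      row
    }))
    rownames(out) <- NULL
    out
  }
  by_area <- agg(nr, "area_tag")
  by_area_layer <- agg(nr, c("area_tag", "layer"))
  tests <- list()
  for (a in unique(nr$area_tag)) {
    g <- nr[nr$area_tag == a, ]
    sizes <- table(g$layer)
    if (sum(sizes >= 2) >= 2) {
      kw <- stats::kruskal.test(g$performance, factor(g$layer))
      tests[[a]] <- data.frame(area_tag = a, H = unname(kw$statistic),
                               p_value = kw$p.value)
    }
  }
  layer_tests <- if (length(tests)) do.call(rbind, tests) else
    data.frame(area_tag = character(0), H = numeric(0), p_value = numeric(0))
  rownames(layer_tests) <- NULL
  if (holm && nrow(layer_tests)) {
    layer_tests$p_holm <- stats::p.adjust(layer_tests$p_value, "holm")
  }
  list(by_area = by_area, by_area_layer = by_area_layer,
       layer_tests = layer_tests)
}
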