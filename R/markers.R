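#' Two-group difference test with a normality gate
#'
#' Screens one compound's contents across a two-group contrast. Each
#' group's distribution is first assessed with a Shapiro-Wilk test at
#' alpha = 0.05 (only meaningful for groups of 3 or more values with
#' nonzero variance; smaller or constant groups count as non-normal).
#' When both groups pass, a Welch two-sample t-test is used; otherwise
#' the Wilcoxon rank-sum test. The direction is read off the group
#' medians (falling back to means on tied medians). Two constant groups
#' with the same value yield p = 1 and an undefined direction.
#'
#' @param values Numeric contents, one per germplasm.
#' @param groups Two-level group label per value.
#' @param positive Which level is the positive group; defaults to the
#'   first level encountered.
#' @return A one-row tibble: `p_value`, `direction`
#'   (`"higher-in-positive"`, `"lower-in-positive"` or `"none"`) and
#'   `method` used.
#' @export
group_difference_test <- function(values, groups, positive = NULL) {
  groups <- as.character(groups)
  levels <- unique(groups)
  if (length(levels) != 2) abort("exactly two groups are required")
  positive <- positive %||% levels[1]
  if (!positive %in% levels) abort("positive level not found in groups")
  x <- values[groups == positive]
  y <- values[groups != positive]
  if (length(x) < 2 || length(y) < 2) {
    abort("both groups need at least 2 values")
  }
  if (var(x) == 0 && var(y) == 0 && x[1] == y[1]) {
    return(tibble::tibble(p_value = 1, direction = "none",
                          method = "degenerate"))
  }
  normal <- function(v) {
    length(v) >= 3 && length(v) <= 5000 && var(v) > 0 &&
      shapiro.test(v)$p.value >= 0.05
  }
  if (normal(x) && normal(y)) {
    p <- t.test(x, y)$p.value
    method <- "welch"
  } else {
    p <- suppressWarnings(wilcox.test(x, y)$p.value)
    method <- "wilcoxon"
  }
  dx <- median(x) - median(y)
  if (dx == 0) dx <- mean(x) - mean(y)
  direction <- if (dx > 0) "higher-in-positive" else if (dx < 0)
    "lower-in-positive" else "none"
  tibble::tibble(p_value = p, direction = direction, method = method)
}

#' Standard contrasts of a citrus volatile panel
#'
#' Builds the contrasts the biomarker analysis runs on: each of
#' loose-skin mandarin (LSM), sweet orange (SW), pomelo (P) and lemon
#' (Lem) against the other three of those species (clementines are
#' excluded from "rest"); clementine (CCL) against its parents LSM and
#' SW together; and wild against cultivar germplasms where origin flags
#' are known. A contrast whose groups cannot both muster two germplasms
#' is omitted with a warning.
#'
#' @param data A volatile profile table.
#' @return A tibble with one row per available contrast: `contrast`
#'   name, target `species` (`NA` for the wild/cultivar contrast) and
#'   list-columns `positive` and `negative` of germplasm identifiers.
#' @export
standard_contrasts <- function(data) {
  validate_volatiles(data)
  four <- c("LSM", "SW", "P", "Lem")
  rows <- list()
  skip <- character()
  add <- function(rows, name, species, pos, neg) {
    if (length(pos) >= 2 && length(neg) >= 2) {
      rows[[name]] <- tibble::tibble(
        contrast = name, species = species,
        positive = list(pos), negative = list(neg)
      )
    } else {
      skip <<- c(skip, name)
    }
    rows
  }
  for (sp in four) {
    pos <- data$germplasm[data$species == sp]
    neg <- data$germplasm[data$species %in% setdiff(four, sp)]
    rows <- add(rows, paste0(sp, "_vs_rest"), sp, pos, neg)
  }
  pos <- data$germplasm[data$species == "CCL"]
  neg <- data$germplasm[data$species %in% c("LSM", "SW")]
  rows <- add(rows, "CCL_vs_LSM_SW", "CCL", pos, neg)
  if ("origin" %in% names(data)) {
    pos <- data$germplasm[data$origin == "wild"]
    neg <- data$germplasm[data$origin == "cultivar"]
    rows <- add(rows, "wild_vs_cultivar", NA_character_, pos, neg)
  }
  if (length(skip) > 0) {
    warn(paste0("contrast(s) omitted for lack of germplasms: ",
                paste(skip, collapse = ", ")))
  }
  dplyr::bind_rows(rows)
}

#' Select marker compounds for one contrast
#'
#' Fits a one-vs-rest PLS-DA on the contrast's germplasms, computes VIP
#' scores, tests each compound with [group_difference_test()], and keeps
#' the compounds passing both gates: VIP strictly above `vip_threshold`
#' and p-value strictly below `p_threshold`. Entries are ordered by VIP,
#' descending. No multiple-testing correction is applied by default,
#' matching the plain p < 0.05 gate customary in this screening; set
#' `adjust = "BH"` for Benjamini-Hochberg adjusted p-values instead.
#'
#' @param data A volatile profile table.
#' @param positive,negative Character vectors of germplasm identifiers
#'   forming the contrast, or pass a one-row slice of
#'   [standard_contrasts()] via `contrast_row`.
#' @param contrast_row Optional one-row contrast tibble; overrides
#'   `positive`/`negative` and names the result.
#' @param contrast Name recorded on the result.
#' @param vip_threshold VIP gate (strict, default 1.5).
#' @param p_threshold Significance gate (strict, default 0.05).
#' @param n_components PLS-DA components (default 2).
#' @param scaling Scaling mode for the PLS-DA fit.
#' @param adjust P-value adjustment method (`"none"` or any
#'   [stats::p.adjust()] method) applied before gating.
#' @return A tibble of class `marker_set` with columns `compound`,
#'   `vip`, `p_value`, `direction`, sorted by VIP descending; the
#'   contrast name and thresholds are attached as attributes.
#' @export
select_markers <- function(data, positive = NULL, negative = NULL,
                           contrast_row = NULL, contrast = NULL,
                           vip_threshold = 1.5, p_threshold = 0.05,
                           n_components = 2, scaling = "autoscale",
                           adjust = "none") {
  validate_volatiles(data)
  if (!is.null(contrast_row)) {
    positive <- contrast_row$positive[[1]]
    negative <- contrast_row$negative[[1]]
    contrast <- contrast %||% contrast_row$contrast[1]
  }
  if (is.null(positive) || is.null(negative)) {
    abort("a contrast (positive and negative germplasm sets) is required")
  }
  if (length(intersect(positive, negative)) > 0) {
    abort("contrast groups overlap")
  }
  missing <- setdiff(c(positive, negative), data$germplasm)
  if (length(missing) > 0) {
    abort(paste0("germplasm(s) not in table: ",
                 paste(missing, collapse = ", ")))
  }
  contrast <- contrast %||% "contrast"
  sub <- data[match(c(positive, negative), data$germplasm), ]
  labels <- rep(c("positive", "rest"), c(length(positive),
                                         length(negative)))
  model <- fit_plsda(sub, groups = labels, n_components = n_components,
                     scaling = scaling)
  vip <- vip_scores(model)
  tests <- purrr::map(compound_names(sub), function(cn) {
    group_difference_test(sub[[cn]], labels, positive = "positive")
  })
  stats_tbl <- dplyr::bind_rows(tests)
  stats_tbl$compound <- compound_names(sub)
  out <- dplyr::inner_join(vip, stats_tbl, by = "compound")
  if (adjust != "none") {
    out$p_value <- stats::p.adjust(out$p_value, method = adjust)
  }
  out <- out[out$vip > vip_threshold & out$p_value < p_threshold, ]
  out <- out[order(-out$vip), c("compound", "vip", "p_value",
                                "direction")]
  out <- tibble::as_tibble(out)
  attr(out, "contrast") <- contrast
  attr(out, "vip_threshold") <- vip_threshold
  attr(out, "p_threshold") <- p_threshold
  class(out) <- c("marker_set", class(out))
  out
}

#' VIP lollipop plot of a marker set or VIP table
#'
#' @param vip A `marker_set` or a tibble with `compound` and `vip`
#'   columns.
#' @param vip_threshold Gate drawn as a dashed line.
#' @param top Show at most this many compounds (by VIP).
#' @return A ggplot.
#' @export
plot_vip <- function(vip, vip_threshold = 1.5, top = 30) {
  df <- dplyr::slice_max(tibble::as_tibble(vip), .data$vip, n = top)
  df$compound <- stats::reorder(df$compound, df$vip)
  ggplot2::ggplot(df, ggplot2::aes(.data$vip, .data$compound)) +
    ggplot2::geom_segment(ggplot2::aes(x = 0, xend = .data$vip,
                                       yend = .data$compound),
                          colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = vip_threshold, linetype = "dashed") +
    ggplot2::labs(x = "VIP", y = NULL)
}
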