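#' The four published single-marker classification rules
#'
#' Each rule is an independent binary classifier tying one marker
#' compound to one species: a germplasm is called loose-skin mandarin
#' when its beta-elemene content is strictly higher than 16 ng/g, and
#' sweet orange, pomelo or lemon when valencene, nootkatone or limettin
#' respectively is detected (content > 0). The rules are evaluated
#' independently, not fused into one multi-class decision.
#'
#' @return A tibble with one row per rule: `marker` (ASCII key),
#'   `compound` (display name), `species`, `mode` (`"threshold"` or
#'   `"presence"`) and `threshold` in ng/g (`NA` for presence rules).
#' @export
default_rules <- function() {
  tibble::tibble(
    marker = c("beta_elemene", "valencene", "nootkatone", "limettin"),
    compound = c("β-elemene", "valencene", "nootkatone", "limettin"),
    species = c("LSM", "SW", "P", "Lem"),
    mode = c("threshold", "presence", "presence", "presence"),
    threshold = c(16, NA, NA, NA)
  )
}

#' Apply one marker rule to contents
#'
#' @param contents Nonnegative numeric contents (ng/g) of the rule's
#'   marker compound.
#' @param rule A one-row rule tibble as in [default_rules()].
#' @return Logical vector: `TRUE` where the rule fires. Threshold rules
#'   require content strictly above the threshold (a content exactly at
#'   the threshold is negative); presence rules fire on any content > 0.
#' @export
apply_rule <- function(contents, rule) {
  if (any(contents < 0, na.rm = TRUE)) abort("contents must be >= 0")
  if (rule$mode[1] == "threshold") {
    if (is.na(rule$threshold[1]) || rule$threshold[1] <= 0) {
      abort("threshold rule requires a positive threshold")
    }
    contents > rule$threshold[1]
  } else {
    contents > 0
  }
}

#' Evaluate marker rules on a call table
#'
#' Each rule is scored against the full table: a germplasm is correctly
#' handled when the rule's boolean call equals whether the germplasm's
#' actual species is the rule's target. Confusion counts, the exact
#' accuracy fraction and the misclassified germplasms are reported per
#' rule.
#'
#' @param calls A tibble with `germplasm`, `actual_species` and one
#'   logical column per marker, e.g. from [load_table2()].
#' @param rules A rule tibble as in [default_rules()].
#' @return A tibble of class `rule_evaluation` with one row per rule:
#'   `marker`, `species`, `tp`, `fp`, `tn`, `fn`, `n`, `accuracy` (exact
#'   fraction) and a list-column `misclassified` of germplasm ids. The
#'   per-germplasm prediction table is attached as attribute
#'   `"predictions"`.
#' @export
evaluate_rules <- function(calls, rules = default_rules()) {
  missing <- setdiff(rules$marker, names(calls))
  if (length(missing) > 0) {
    abort(paste0("marker(s) missing from call table: ",
                 paste(missing, collapse = ", ")))
  }
  n <- nrow(calls)
  preds <- calls[c("germplasm", "actual_species")]
  rows <- purrr::map(seq_len(nrow(rules)), function(i) {
    marker <- rules$marker[i]
    pred <- as.logical(calls[[marker]])
    if (any(is.na(pred))) {
      abort(paste0("call column '", marker, "' has missing values"))
    }
    truth <- calls$actual_species == rules$species[i]
    tibble::tibble(
      marker = marker,
      species = rules$species[i],
      tp = sum(pred & truth), fp = sum(pred & !truth),
      tn = sum(!pred & !truth), fn = sum(!pred & truth),
      n = n,
      accuracy = sum(pred == truth) / n,
      misclassified = list(calls$germplasm[pred != truth])
    )
  })
  out <- dplyr::bind_rows(rows)
  for (i in seq_len(nrow(rules))) {
    preds[[rules$marker[i]]] <- as.logical(calls[[rules$marker[i]]])
  }
  attr(out, "predictions") <- preds
  class(out) <- c("rule_evaluation", class(out))
  out
}

#' Evaluate marker rules on a volatile profile table
#'
#' Looks up each rule's marker compound among the table's compound
#' columns (names are matched after normalisation, so "beta_elemene",
#' "β-elemene" and the legacy "nootkanone" spelling all resolve),
#' applies the rule's threshold or presence call to the contents, and
#' scores the calls as in [evaluate_rules()].
#'
#' @param data A volatile profile table.
#' @param rules A rule tibble as in [default_rules()].
#' @return A `rule_evaluation` tibble.
#' @export
evaluate_on_matrix <- function(data, rules = default_rules()) {
  validate_volatiles(data)
  cmp <- compound_names(data)
  keys <- normalize_compound(cmp)
  calls <- data[c("germplasm", "species")]
  names(calls)[2] <- "actual_species"
  for (i in seq_len(nrow(rules))) {
    j <- which(keys == normalize_compound(rules$marker[i]))
    if (length(j) == 0) {
      abort(paste0("compound '", rules$compound[i],
                   "' not found in the profile table"))
    }
    calls[[rules$marker[i]]] <- apply_rule(data[[cmp[j[1]]]], rules[i, ])
  }
  evaluate_rules(calls, rules)
}

#' @export
print.rule_evaluation <- function(x, ...) {
  cat("Marker rule evaluation on", x$n[1], "germplasms\n")
  for (i in seq_len(nrow(x))) {
    mis <- x$misclassified[[i]]
    cat(sprintf("  %-13s -> %-3s accuracy %s (%d/%d)%s\n",
                x$marker[i], x$species[i],
                format_accuracy(x$accuracy[i]),
                x$n[i] - length(mis), x$n[i],
                if (length(mis) > 0)
                  paste0("  misclassified: ",
                         paste(mis, collapse = ", ")) else ""))
  }
  invisible(x)
}

#' @method tidy rule_evaluation
#' @export
tidy.rule_evaluation <- function(x, ...) {
  out <- tibble::as_tibble(x)
  out$n_misclassified <- lengths(out$misclassified)
  out$misclassified <- NULL
  out
}

#' @method autoplot rule_evaluation
#' @export
autoplot.rule_evaluation <- function(object, ...) {
  df <- tidy(object)
  df$marker <- factor(df$marker, levels = df$marker)
  ggplot2::ggplot(df, ggplot2::aes(.data$marker, .data$accuracy)) +
    ggplot2::geom_col() +
    ggplot2::scale_y_continuous(labels = function(v) paste0(100 * v, "%"),
                                limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "accuracy")
}

#' Format an accuracy fraction as a display percentage
#'
#' @param accuracy Accuracy fraction in `[0, 1]`.
#' @return Character, e.g. `"90.0%"`; exact 1 prints as `"100.00%"`.
#' @export
format_accuracy <- function(accuracy) {
  ifelse(accuracy == 1, "100.00%",
         paste0(formatC(100 * accuracy, format = "f", digits = 1), "%"))
}
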