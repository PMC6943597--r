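#' PLS-DA by NIPALS on a volatile profile table
#'
#' Partial least squares discriminant analysis: the group membership is
#' dummy-coded (one centered indicator column per group) and regressed on
#' the scaled content matrix with the NIPALS PLS2 algorithm. Components
#' are extracted one at a time: the inner loop alternates weight, score
#' and response-weight updates until the weight vector changes by less
#' than `tol`, then X is deflated by the extracted component and the
#' response residual updated. Score vectors of different components are
#' mutually orthogonal and each weight vector has unit norm; the sign
#' indeterminacy is resolved by making the largest-magnitude weight entry
#' positive. The explained response sum-of-squares of each component
#' (`ssy`) feeds the VIP computation in [vip_scores()].
#'
#' @param data A volatile profile table, a `scaled_volatiles` object or a
#'   bare numeric matrix.
#' @param groups Group label per germplasm (two or more groups, each with
#'   at least two members). Defaults to the table's `species` column.
#' @param n_components Number of components to extract (default 2, the
#'   usual choice for 2-D score plots).
#' @param scaling Scaling mode when `data` is not pre-scaled.
#' @param tol Convergence tolerance of the NIPALS inner loop.
#' @param max_iter Maximum inner-loop iterations per component; hitting
#'   it records a non-convergence flag on the model and warns.
#' @return An object of class `plsda`: weights `W` (compound x A, unit
#'   columns), X-loadings `P`, scores `T` (germplasm x A), Y-loadings
#'   `Q`, per-component explained response sum-of-squares `ssy`, the
#'   total response sum-of-squares `ssy_total`, group levels and coding,
#'   and convergence diagnostics.
#' @export
fit_plsda <- function(data, groups = NULL, n_components = 2,
                      scaling = "autoscale", tol = 1e-10,
                      max_iter = 500) {
  if (inherits(data, "scaled_volatiles")) {
    scaled <- data
  } else if (is.data.frame(data)) {
    validate_volatiles(data)
    if (is.null(groups)) groups <- data$species
    scaled <- scale_volatiles(data, mode = scaling)
  } else {
    scaled <- scale_volatiles(as.matrix(data), mode = scaling)
  }
  if (is.null(groups)) groups <- scaled$species
  if (is.null(groups)) abort("group labels are required")
  groups <- as.character(groups)
  x <- scaled$values
  if (length(groups) != nrow(x)) {
    abort("one group label per germplasm is required")
  }
  levels <- unique(groups)
  if (length(levels) < 2) abort("PLS-DA needs at least 2 groups")
  if (any(table(groups) < 2)) {
    abort("every group needs at least 2 members")
  }
  if (n_components < 1) abort("n_components must be >= 1")

  # centered dummy response, one indicator column per group
  y <- vapply(levels, function(g) as.numeric(groups == g),
              numeric(length(groups)))
  y <- scale(y, center = TRUE, scale = FALSE)
  fit <- nipals_pls(x, y, n_components = n_components, tol = tol,
                    max_iter = max_iter)
  if (any(!fit$converged)) {
    warn(paste0("NIPALS did not converge for component(s) ",
                paste(which(!fit$converged), collapse = ", "),
                " within ", max_iter, " iterations"))
  }
  structure(
    c(fit,
      list(groups = groups, levels = levels, scaling = scaled$mode,
           compounds = colnames(x), germplasm = rownames(x),
           tol = tol, max_iter = max_iter)),
    class = "plsda"
  )
}

# NIPALS PLS2 core on pre-scaled matrices: X (n x p), Y (n x g, centered)
nipals_pls <- function(x, y, n_components, tol = 1e-10, max_iter = 500) {
  n <- nrow(x)
  p <- ncol(x)
  g <- ncol(y)
  ssy_total <- sum(y^2)
  W <- matrix(0, p, n_components)
  P <- matrix(0, p, n_components)
  Tm <- matrix(0, n, n_components)
  Q <- matrix(0, g, n_components)
  ssy <- numeric(n_components)
  converged <- logical(n_components)
  iterations <- integer(n_components)
  e <- x
  f <- y
  a <- 0L
  while (a < n_components) {
    a <- a + 1L
    u <- f[, which.max(colSums(f^2))]
    w <- crossprod(e, u)
    if (sqrt(sum(w^2)) < .Machine$double.eps * 100) {
      a <- a - 1L
      warn(paste0("response residual exhausted; returning ", a,
                  " component(s)"))
      break
    }
    w <- w / sqrt(sum(w^2))
    for (it in seq_len(max_iter)) {
      t_vec <- e %*% w
      q <- crossprod(f, t_vec) / sum(t_vec^2)
      u <- f %*% q / sum(q^2)
      w_new <- crossprod(e, u)
      w_new <- w_new / sqrt(sum(w_new^2))
      delta <- sqrt(sum((w_new - w)^2))
      w <- w_new
      if (delta < tol) break
    }
    converged[a] <- delta < tol
    iterations[a] <- it
    # fix the sign: largest-magnitude weight entry positive
    j <- which.max(abs(w))
    if (w[j] < 0) w <- -w
    t_vec <- e %*% w
    tt <- sum(t_vec^2)
    p_load <- crossprod(e, t_vec) / tt
    q <- crossprod(f, t_vec) / tt
    W[, a] <- w
    P[, a] <- p_load
    Tm[, a] <- t_vec
    Q[, a] <- q
    ssy[a] <- tt * sum(q^2)
    e <- e - tcrossprod(t_vec, p_load)
    f <- f - tcrossprod(t_vec, q)
  }
  keep <- seq_len(a)
  dimnames(W) <- list(colnames(x), paste0("comp", seq_len(n_components)))
  list(
    W = W[, keep, drop = FALSE], P = P[, keep, drop = FALSE],
    T = Tm[, keep, drop = FALSE], Q = Q[, keep, drop = FALSE],
    ssy = ssy[keep], ssy_total = ssy_total,
    n_components = a, converged = converged[keep],
    iterations = iterations[keep]
  )
}

#' @export
print.plsda <- function(x, ...) {
  cat("PLS-DA (NIPALS), ", x$n_components, " component(s), groups: ",
      paste(x$levels, collapse = ", "), "\n", sep = "")
  cat("explained response variance:",
      paste0(round(100 * x$ssy / x$ssy_total, 1), "%", collapse = ", "),
      "\n")
  invisible(x)
}

#' @method glance plsda
#' @export
glance.plsda <- function(x, ...) {
  tibble::tibble(
    n_germplasms = nrow(x$T),
    n_compounds = nrow(x$W),
    n_components = x$n_components,
    r2y = sum(x$ssy) / x$ssy_total,
    converged = all(x$converged)
  )
}

#' Tidy a fitted PLS-DA model
#'
#' @param x A `plsda` object.
#' @param matrix `"weights"`, `"loadings"` (both per compound and
#'   component) or `"scores"` (per germplasm and component).
#' @param ... Unused.
#' @method tidy plsda
#' @export
tidy.plsda <- function(x, matrix = c("weights", "loadings", "scores"),
                       ...) {
  matrix <- match.arg(matrix)
  m <- switch(matrix, weights = x$W, loadings = x$P, scores = x$T)
  unit <- if (matrix == "scores") "germplasm" else "compound"
  ids <- if (matrix == "scores") x$germplasm else x$compounds
  out <- tibble::as_tibble(m, .name_repair = "minimal")
  names(out) <- paste0("comp", seq_len(ncol(m)))
  out[[unit]] <- ids %||% seq_len(nrow(m))
  tidyr::pivot_longer(out, -dplyr::all_of(unit), names_to = "component",
                      values_to = "value")
}

#' Score plot of a fitted PLS-DA model
#'
#' @param object A `plsda` object.
#' @param components Two component indices to plot.
#' @param ... Unused.
#' @method autoplot plsda
#' @export
autoplot.plsda <- function(object, components = c(1, 2), ...) {
  df <- tibble::tibble(
    x = object$T[, components[1]],
    y = object$T[, components[2]],
    group = object$groups
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y,
                                   colour = .data$group)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = paste("Component", components[1]),
                  y = paste("Component", components[2]))
}

#' Variable importance in projection (VIP) scores
#'
#' For a fitted PLS-DA model with p compounds and unit-norm weight
#' vectors w_a, the VIP of compound j is
#' sqrt(p * sum_a(ssy_a * w_aj^2) / sum_a(ssy_a)), where ssy_a is the
#' response sum-of-squares explained by component a. The normalization
#' makes the mean squared VIP exactly 1 (sum of squared VIPs = p), so a
#' VIP above 1 marks an above-average contributor; the conventional
#' selection gate in volatile biomarker mining is VIP > 1.5.
#'
#' @param model A fitted `plsda` object.
#' @return A tibble with columns `compound` and `vip`, in model column
#'   order.
#' @export
vip_scores <- function(model) {
  if (!inherits(model, "plsda")) abort("model must be a plsda fit")
  if (all(model$ssy == 0)) {
    abort("response unexplained: every component has zero explained SS")
  }
  p <- nrow(model$W)
  w2 <- model$W^2  # columns already unit norm
  vip <- sqrt(p * as.numeric(w2 %*% model$ssy) / sum(model$ssy))
  tibble::tibble(
    compound = model$compounds %||% paste0("V", seq_len(p)),
    vip = vip
  )
}
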