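#' Principal component analysis of a volatile profile table
#'
#' PCA by singular value decomposition of the scaled content matrix.
#' Scores are the projections of the scaled rows onto orthonormal
#' loadings, and the explained-variance ratio of component a is
#' sigma_a^2 / sum(sigma_i^2) over all singular values, so the ratios of
#' the returned components are non-increasing and sum to at most 1.
#'
#' @param data A volatile profile table or a `scaled_volatiles` object.
#' @param n_components Number of components to return. Values above the
#'   matrix rank are truncated to the rank with a warning.
#' @param scaling Scaling mode passed to [scale_volatiles()] when `data`
#'   is not already scaled.
#' @return An object of class `citrus_pca`: list with `scores`
#'   (germplasm x component), `loadings` (compound x component,
#'   orthonormal), `explained_variance_ratio`, `singular_values` (all of
#'   them) and the species labels when available.
#' @export
fit_pca <- function(data, n_components = 2, scaling = "autoscale") {
  scaled <- if (inherits(data, "scaled_volatiles")) data else
    scale_volatiles(data, mode = scaling)
  x <- scaled$values
  if (n_components < 1) abort("n_components must be >= 1")
  if (n_components > min(nrow(x) - 1, ncol(x))) {
    abort("n_components must be <= min(rows - 1, columns)")
  }
  dec <- svd(x)
  tot <- sum(dec$d^2)
  rank <- sum(dec$d > dec$d[1] * 1e-12)
  if (n_components > rank) {
    warn(paste0("requested ", n_components, " components but rank is ",
                rank, "; truncating"))
    n_components <- rank
  }
  idx <- seq_len(n_components)
  loadings <- dec$v[, idx, drop = FALSE]
  # deterministic sign: largest-magnitude loading entry positive
  for (a in idx) {
    j <- which.max(abs(loadings[, a]))
    if (loadings[j, a] < 0) loadings[, a] <- -loadings[, a]
  }
  scores <- x %*% loadings
  dimnames(loadings) <- list(colnames(x), paste0("PC", idx))
  dimnames(scores) <- list(rownames(x), paste0("PC", idx))
  structure(
    list(scores = scores, loadings = loadings,
         explained_variance_ratio = dec$d[idx]^2 / tot,
         singular_values = dec$d,
         species = scaled$species, scaling = scaled$mode),
    class = "citrus_pca"
  )
}

#' @export
print.citrus_pca <- function(x, ...) {
  pct <- round(100 * x$explained_variance_ratio)
  cat("PCA of volatile profiles (", x$scaling, " scaling)\n", sep = "")
  cat(nrow(x$scores), "germplasms,", nrow(x$loadings), "compounds,",
      ncol(x$scores), "components\n")
  cat("explained variance:", paste0(pct, "%", collapse = ", "), "\n")
  invisible(x)
}

#' Tidy a fitted PCA
#'
#' @param x A `citrus_pca` object.
#' @param matrix `"scores"` (one row per germplasm and component),
#'   `"loadings"` (per compound and component) or `"eigenvalues"` (per
#'   component).
#' @param ... Unused.
#' @method tidy citrus_pca
#' @export
tidy.citrus_pca <- function(x, matrix = c("scores", "loadings",
                                          "eigenvalues"), ...) {
  matrix <- match.arg(matrix)
  if (matrix == "eigenvalues") {
    return(tibble::tibble(
      component = seq_along(x$explained_variance_ratio),
      std_dev = x$singular_values[seq_along(x$explained_variance_ratio)] /
        sqrt(nrow(x$scores) - 1),
      explained_variance_ratio = x$explained_variance_ratio
    ))
  }
  m <- if (matrix == "scores") x$scores else x$loadings
  unit <- if (matrix == "scores") "germplasm" else "compound"
  out <- tibble::as_tibble(m, rownames = unit)
  tidyr::pivot_longer(out, -dplyr::all_of(unit), names_to = "component",
                      values_to = "value")
}

#' @method glance citrus_pca
#' @export
glance.citrus_pca <- function(x, ...) {
  tibble::tibble(
    n_germplasms = nrow(x$scores),
    n_compounds = nrow(x$loadings),
    n_components = ncol(x$scores),
    cum_variance = sum(x$explained_variance_ratio)
  )
}

#' Score plot of a fitted PCA
#'
#' @param object A `citrus_pca` object.
#' @param components Two component indices to plot.
#' @param ... Unused.
#' @return A ggplot of the score plane coloured by species when labels
#'   are available.
#' @method autoplot citrus_pca
#' @export
autoplot.citrus_pca <- function(object, components = c(1, 2), ...) {
  df <- tibble::as_tibble(object$scores[, components, drop = FALSE],
                          rownames = "germplasm")
  names(df)[2:3] <- c("x", "y")
  if (!is.null(object$species)) df$species <- object$species
  pct <- round(100 * object$explained_variance_ratio[components], 1)
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::labs(
      x = paste0("PC", components[1], " (", pct[1], "%)"),
      y = paste0("PC", components[2], " (", pct[2], "%)")
    )
  if (!is.null(object$species)) {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$species))
  } else {
    p + ggplot2::geom_point()
  }
}
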