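#' Column-wise scaling of a volatile profile table
#'
#' Centers and scales the germplasm-by-compound content matrix prior to
#' PCA or PLS-DA. `"autoscale"` (the default for both downstream models)
#' divides each centered column by its sample standard deviation,
#' `"pareto"` by the square root of the standard deviation, and
#' `"center"` leaves the scale at 1. Zero-variance columns are centered,
#' given scale 1 and flagged rather than dropped, so column indices stay
#' aligned with the input. The recorded transform can be re-applied to
#' held-out rows.
#'
#' @param data A volatile profile table or a bare numeric matrix.
#' @param mode Scaling mode: `"autoscale"`, `"pareto"` or `"center"`.
#' @return An object of class `scaled_volatiles`: list with `values`
#'   (scaled matrix), `center`, `scale`, `zero_variance` flags, `mode`,
#'   and the germplasm/species metadata when the input carried it.
#' @export
scale_volatiles <- function(data, mode = c("autoscale", "pareto",
                                           "center")) {
  mode <- match.arg(mode)
  if (is.data.frame(data)) {
    validate_volatiles(data)
    m <- compound_matrix(data)
    species <- data$species
  } else {
    m <- as.matrix(data)
    species <- NULL
  }
  if (nrow(m) < 2) abort("scaling needs at least 2 germplasms")
  center <- colMeans(m)
  sds <- apply(m, 2, sd)
  zero_var <- sds == 0
  scl <- switch(mode,
    autoscale = ifelse(zero_var, 1, sds),
    pareto = ifelse(zero_var, 1, sqrt(sds)),
    center = rep(1, ncol(m))
  )
  values <- sweep(sweep(m, 2, center), 2, scl, "/")
  structure(
    list(values = values, center = center, scale = scl,
         zero_variance = zero_var, mode = mode, species = species),
    class = "scaled_volatiles"
  )
}

#' Apply a stored scaling transform to new rows
#'
#' @param scaled A `scaled_volatiles` object from [scale_volatiles()].
#' @param newdata A volatile profile table or matrix with the same
#'   compound columns.
#' @return Numeric matrix of scaled values.
#' @export
apply_scaling <- function(scaled, newdata) {
  m <- if (is.data.frame(newdata)) compound_matrix(newdata) else
    as.matrix(newdata)
  if (!identical(colnames(m), names(scaled$center))) {
    m <- m[, names(scaled$center), drop = FALSE]
  }
  sweep(sweep(m, 2, scaled$center), 2, scaled$scale, "/")
}
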