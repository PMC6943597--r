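# small random volatile tables for property-style tests
random_volatiles <- function(n = 10, p = 8, seed = NULL,
                             species = NULL, zero_frac = 0.2) {
  if (!is.null(seed)) set.seed(seed)
  m <- matrix(rexp(n * p, rate = 0.05), nrow = n)
  m[matrix(runif(n * p) < zero_frac, nrow = n)] <- 0
  colnames(m) <- sprintf("C%02d", seq_len(p))
  if (is.null(species)) {
    species <- rep(c("LSM", "SW"), length.out = n)
  }
  as_volatiles(m, germplasm = sprintf("G%03d", seq_len(n)),
               species = species)
}

# random pre-scaled X and centered dummy Y for NIPALS property tests
random_xy <- function(n = 12, p = 8, groups = 2, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  x <- scale(matrix(rnorm(n * p), nrow = n))
  labels <- sample(rep(paste0("g", seq_len(groups)),
                       length.out = n))
  y <- vapply(unique(labels), function(g) as.numeric(labels == g),
              numeric(n))
  y <- scale(y, center = TRUE, scale = FALSE)
  list(x = x, y = y, labels = labels)
}
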