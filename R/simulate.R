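#' Simulate a species-labelled volatile matrix with planted markers
#'
#' Contents are drawn log-normally: the log content of a background
#' compound is N(base_log_mean, base_log_sd) in every species, so
#' non-marker compounds are exchangeable across species. Each species is
#' assigned `n_markers_per_species` marker compounds (disjoint across
#' species); inside its own species an up-marker's log mean is shifted by
#' `+log_effect` and a down-marker's by `-log_effect`. Detection
#' censoring is a hard limit (values below `detection_limit` are set to
#' 0) plus independent Bernoulli dropout at rate `dropout_rate`,
#' reproducing the zero-inflation that the presence filter must handle.
#'
#' The default group sizes mirror an unbalanced citrus panel of 29
#' loose-skin mandarins, 24 sweet oranges, 8 pomelos, 5 lemons and 16
#' clementine mandarins, so simulated geometry matches the panels that
#' the one-vs-rest contrasts are designed for.
#'
#' @param n_per_species Named integer vector, germplasms per species.
#' @param n_compounds Number of compounds (columns).
#' @param n_markers_per_species Planted markers per species.
#' @param log_effect Log-scale mean shift of a marker in its species.
#' @param base_log_mean,base_log_sd Background log-normal parameters
#'   (log ng/g).
#' @param detection_limit Contents below this value are recorded as 0
#'   (ng/g).
#' @param dropout_rate Probability that a value is independently lost to
#'   random non-detection.
#' @param marker_direction `"up"`, `"down"` or `"mixed"` (each planted
#'   marker up or down with equal probability).
#' @param wild_fraction Fraction of germplasms flagged `"wild"`; the rest
#'   are `"cultivar"`. Use 0 for an all-`"unknown"` origin column.
#' @param seed Integer seed; the same seed reproduces the output exactly.
#' @return A list of class `volatile_sim` with elements `profiles` (a
#'   volatile profile tibble) and `truth` (tibble of planted markers:
#'   `species`, `compound`, `direction`).
#' @export
simulate_volatiles <- function(n_per_species = c(LSM = 29, SW = 24, P = 8,
                                                 Lem = 5, CCL = 16),
                               n_compounds = 89,
                               n_markers_per_species = 3,
                               log_effect = 3,
                               base_log_mean = log(50),
                               base_log_sd = 1,
                               dropout_rate = 0.05,
                               detection_limit = 1,
                               marker_direction = c("up", "down", "mixed"),
                               wild_fraction = 0.2,
                               seed = NULL) {
  marker_direction <- match.arg(marker_direction)
  if (is.null(names(n_per_species)) || any(!nzchar(names(n_per_species)))) {
    abort("n_per_species must be a named vector of positive counts")
  }
  if (any(n_per_species < 1)) abort("n_per_species entries must be >= 1")
  if (detection_limit < 0) abort("detection_limit must be >= 0")
  if (dropout_rate < 0 || dropout_rate > 1) {
    abort("dropout_rate must be in [0, 1]")
  }
  n_species <- length(n_per_species)
  if (n_markers_per_species * n_species > n_compounds) {
    abort("more planted markers requested than compounds available")
  }
  if (!is.null(seed)) set.seed(seed)

  species <- rep(names(n_per_species), n_per_species)
  n <- length(species)
  germplasm <- sprintf("G%03d", seq_len(n))
  compounds <- sprintf("C%02d", seq_len(n_compounds))

  marker_ids <- sample(compounds, n_markers_per_species * n_species)
  truth <- tibble::tibble(
    species = rep(names(n_per_species), each = n_markers_per_species),
    compound = marker_ids,
    direction = switch(marker_direction,
      up = rep("up", length(marker_ids)),
      down = rep("down", length(marker_ids)),
      mixed = sample(c("up", "down"), length(marker_ids), replace = TRUE)
    )
  )

  mu <- matrix(base_log_mean, nrow = n, ncol = n_compounds,
               dimnames = list(germplasm, compounds))
  for (i in seq_len(nrow(truth))) {
    shift <- if (truth$direction[i] == "up") log_effect else -log_effect
    mu[species == truth$species[i], truth$compound[i]] <-
      base_log_mean + shift
  }
  contents <- exp(mu + matrix(rnorm(n * n_compounds, sd = base_log_sd),
                              nrow = n))
  contents[contents < detection_limit] <- 0
  if (dropout_rate > 0) {
    drop <- matrix(runif(n * n_compounds) < dropout_rate, nrow = n)
    contents[drop] <- 0
  }

  origin <- rep("unknown", n)
  if (wild_fraction > 0) {
    n_wild <- round(wild_fraction * n)
    origin <- rep("cultivar", n)
    origin[sample(n, n_wild)] <- "wild"
  }

  profiles <- as_volatiles(contents, germplasm = germplasm,
                           species = species, origin = origin)
  structure(list(profiles = profiles, truth = truth),
            class = "volatile_sim")
}

#' Marker-recovery experiment on simulated matrices
#'
#' Repeatedly simulates a volatile matrix with planted markers, runs
#' one-vs-rest marker selection for every species, and scores how many
#' planted markers are recovered with the correct direction (up-markers
#' as higher-in-species, down-markers as lower) and how many selected
#' compounds were never planted. Replicate r uses seed `seed + r` so the
#' whole report is reproducible from a single seed.
#'
#' @param n_replicates Number of simulated replicates.
#' @param vip_threshold,p_threshold Selection gates passed to
#'   [select_markers()].
#' @param n_components PLS-DA components per contrast.
#' @param seed Base integer seed.
#' @param ... Simulation settings passed to [simulate_volatiles()]. The
#'   default geometry here drops clementines and wild flags so every
#'   planted marker has a plain one-vs-rest contrast.
#' @param n_per_species,wild_fraction See [simulate_volatiles()].
#' @return A tibble of class `recovery_report` with one row per
#'   replicate: `replicate`, `seed`, `n_planted`, `n_recovered`,
#'   `recovery` (fraction with matching direction) and `n_false`
#'   (selected compounds that were not planted for that species).
#'   Summarise with [glance()].
#' @export
recovery_experiment <- function(n_replicates = 50,
                                n_per_species = c(LSM = 29, SW = 24,
                                                  P = 8, Lem = 5),
                                wild_fraction = 0,
                                vip_threshold = 1.5,
                                p_threshold = 0.05,
                                n_components = 2,
                                seed = 1, ...) {
  reps <- purrr::map(seq_len(n_replicates), function(r) {
    rep_seed <- seed + r
    sim <- simulate_volatiles(n_per_species = n_per_species,
                              wild_fraction = wild_fraction,
                              seed = rep_seed, ...)
    contrasts <- species_contrasts(sim$profiles)
    hits <- 0L
    false_sel <- 0L
    n_planted <- 0L
    for (sp in unique(sim$truth$species)) {
      row <- contrasts[contrasts$species == sp, ]
      if (nrow(row) == 0) next
      markers <- select_markers(
        sim$profiles,
        positive = row$positive[[1]], negative = row$negative[[1]],
        contrast = row$contrast[1],
        vip_threshold = vip_threshold, p_threshold = p_threshold,
        n_components = n_components
      )
      planted <- sim$truth[sim$truth$species == sp, ]
      n_planted <- n_planted + nrow(planted)
      want_dir <- ifelse(planted$direction == "up",
                         "higher-in-positive", "lower-in-positive")
      found <- match(planted$compound, markers$compound)
      ok <- !is.na(found) & markers$direction[found] == want_dir
      hits <- hits + sum(ok)
      false_sel <- false_sel +
        sum(!markers$compound %in% planted$compound)
    }
    tibble::tibble(replicate = r, seed = rep_seed,
                   n_planted = n_planted, n_recovered = hits,
                   recovery = hits / n_planted, n_false = false_sel)
  })
  out <- dplyr::bind_rows(reps)
  class(out) <- c("recovery_report", class(out))
  out
}

#' @method glance recovery_report
#' @export
glance.recovery_report <- function(x, ...) {
  tibble::tibble(
    n_replicates = nrow(x),
    mean_recovery = mean(x$recovery),
    sd_recovery = sd(x$recovery),
    mean_false = mean(x$n_false)
  )
}

# the four one-species-vs-rest contrasts (rest excludes clementines),
# used by recovery_experiment; the public module surface is
# standard_contrasts()
species_contrasts <- function(data) {
  out <- suppressWarnings(standard_contrasts(data))
  out <- out[!is.na(out$species), ]
  out
}
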