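#' Run the full biomarker-mining pipeline
#'
#' Orchestrates the stages end to end on one volatile panel: presence
#' filtering, per-species presence (Venn) accounting, PCA, the standard
#' contrasts with VIP + significance marker selection, and — when the
#' four rule marker compounds are present among the columns — the
#' four-rule classification. Every result is written as CSV into
#' `out_dir` together with a plain-text manifest of all settings, so a
#' run is auditable and reproducible from its output directory alone.
#' Input files are never modified.
#'
#' @param data A volatile profile table; alternatively give `path` and
#'   `label_path` to read one from CSV.
#' @param out_dir Output directory (created if needed).
#' @param path,label_path Content and label CSVs, used when `data` is
#'   missing.
#' @param min_detection Presence filter threshold (default 5).
#' @param scaling Scaling mode for PCA and PLS-DA.
#' @param n_components Components for PCA and PLS-DA (default 2).
#' @param vip_threshold,p_threshold Marker selection gates.
#' @param rules Rule tibble for the classification stage, or `NULL` to
#'   skip it.
#' @param seed Optional integer seed recorded in the manifest and set
#'   before any stage runs.
#' @return Invisibly, a list with the filtered table, presence summary,
#'   PCA fit, marker sets and rule evaluation (`NULL` where skipped).
#' @export
run_pipeline <- function(data = NULL, out_dir,
                         path = NULL, label_path = NULL,
                         min_detection = 5, scaling = "autoscale",
                         n_components = 2, vip_threshold = 1.5,
                         p_threshold = 0.05, rules = default_rules(),
                         seed = NULL) {
  if (is.null(data)) {
    if (is.null(path) || is.null(label_path)) {
      abort("either data or both path and label_path are required")
    }
    data <- read_volatiles(path, label_path)
  }
  validate_volatiles(data)
  if (!is.null(seed)) set.seed(seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character()
  note <- function(...) {
    log_lines <<- c(log_lines, paste0(...))
  }

  note("stage filter: min_detection = ", min_detection)
  filtered <- filter_min_detection(data, min_detection)
  note("retained ", length(compound_names(filtered)), " of ",
       length(compound_names(data)), " compounds")
  write_volatiles(filtered, file.path(out_dir, "filtered_matrix.csv"),
                  file.path(out_dir, "labels.csv"))

  note("stage presence: species = ",
       paste(unique(filtered$species), collapse = ", "))
  presence <- presence_summary(filtered)
  readr::write_csv(
    dplyr::select(tibble::as_tibble(presence), -"compounds"),
    file.path(out_dir, "presence_summary.csv"), progress = FALSE
  )

  note("stage pca: n_components = ", n_components, ", scaling = ",
       scaling)
  pca <- fit_pca(filtered, n_components = n_components,
                 scaling = scaling)
  readr::write_csv(
    tibble::as_tibble(pca$scores, rownames = "germplasm"),
    file.path(out_dir, "pca_scores.csv"), progress = FALSE
  )
  readr::write_csv(
    tidy(pca, "eigenvalues"),
    file.path(out_dir, "pca_variance.csv"), progress = FALSE
  )

  contrasts <- suppressWarnings(standard_contrasts(filtered))
  marker_sets <- list()
  for (i in seq_len(nrow(contrasts))) {
    name <- contrasts$contrast[i]
    note("stage markers: contrast ", name, " (",
         length(contrasts$positive[[i]]), " vs ",
         length(contrasts$negative[[i]]), ")")
    ms <- select_markers(filtered, contrast_row = contrasts[i, ],
                         vip_threshold = vip_threshold,
                         p_threshold = p_threshold,
                         n_components = n_components,
                         scaling = scaling)
    marker_sets[[name]] <- ms
    readr::write_csv(tibble::as_tibble(ms),
                     file.path(out_dir, paste0("markers_", name, ".csv")),
                     progress = FALSE)
  }

  evaluation <- NULL
  if (!is.null(rules)) {
    keys <- normalize_compound(compound_names(filtered))
    have <- all(normalize_compound(rules$marker) %in% keys)
    if (have) {
      note("stage evaluate: ", nrow(rules), " rules")
      evaluation <- evaluate_on_matrix(filtered, rules)
      readr::write_csv(tidy(evaluation),
                       file.path(out_dir, "rule_evaluation.csv"),
                       progress = FALSE)
    } else {
      note("stage evaluate skipped: rule markers not in compound set")
    }
  }

  manifest <- c(
    paste0("min_detection = ", min_detection),
    paste0("scaling = ", scaling),
    paste0("n_components = ", n_components),
    paste0("vip_threshold = ", vip_threshold),
    paste0("p_threshold = ", p_threshold),
    paste0("seed = ", if (is.null(seed)) "none" else seed),
    paste0("n_germplasms = ", nrow(filtered)),
    paste0("n_compounds_input = ", length(compound_names(data))),
    paste0("n_compounds_retained = ", length(compound_names(filtered))),
    paste0("contrasts = ", paste(contrasts$contrast, collapse = ", "))
  )
  writeLines(manifest, file.path(out_dir, "manifest.txt"))
  writeLines(log_lines, file.path(out_dir, "run.log"))

  invisible(list(filtered = filtered, presence = presence, pca = pca,
                 marker_sets = marker_sets, evaluation = evaluation,
                 out_dir = out_dir))
}
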