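#' Volatile profile tables
#'
#' A volatile profile table is a tibble with one row per germplasm and the
#' identifier columns `germplasm`, `species` and `origin`, followed by one
#' numeric column per compound holding contents in ng/g fresh weight.
#' A content of exactly 0 means the compound was not detected in that
#' germplasm; there is no separate missing-value code.
#'
#' @param data A data frame to validate as a volatile profile table.
#' @return `validate_volatiles()` returns `data` invisibly after checking
#'   the invariants; it aborts with an informative message naming the
#'   offending row, column or cell otherwise.
#' @name volatiles
NULL

id_columns <- c("germplasm", "species", "origin")

#' Compound columns of a volatile profile table
#'
#' @param data A volatile profile table (see [volatiles]).
#' @return Character vector of compound column names, in table order.
#' @export
compound_names <- function(data) {
  setdiff(names(data), id_columns)
}

#' Extract the germplasm-by-compound content matrix
#'
#' @param data A volatile profile table.
#' @return Numeric matrix, rows named by germplasm, columns by compound.
#' @export
compound_matrix <- function(data) {
  cmp <- compound_names(data)
  m <- as.matrix(data[cmp])
  storage.mode(m) <- "double"
  rownames(m) <- data$germplasm
  m
}

#' @rdname volatiles
#' @export
validate_volatiles <- function(data) {
  if (!is.data.frame(data)) {
    abort("a volatile profile table must be a data frame")
  }
  missing_ids <- setdiff(c("germplasm", "species"), names(data))
  if (length(missing_ids) > 0) {
    abort(paste0("missing required column(s): ",
                 paste(missing_ids, collapse = ", ")))
  }
  dup <- data$germplasm[duplicated(data$germplasm)]
  if (length(dup) > 0) {
    abort(paste0("duplicated germplasm identifier(s): ",
                 paste(unique(dup), collapse = ", ")))
  }
  cmp <- compound_names(data)
  dup_cmp <- cmp[duplicated(cmp)]
  if (length(dup_cmp) > 0) {
    abort(paste0("duplicated compound identifier(s): ",
                 paste(unique(dup_cmp), collapse = ", ")))
  }
  for (cn in cmp) {
    x <- data[[cn]]
    if (!is.numeric(x)) {
      abort(paste0("compound column '", cn, "' is not numeric"))
    }
    bad <- which(!is.finite(x) | x < 0)
    if (length(bad) > 0) {
      abort(paste0("negative or non-finite content in compound '", cn,
                   "', germplasm '", data$germplasm[bad[1]], "'"))
    }
  }
  invisible(data)
}

#' Assemble a volatile profile table from contents and labels
#'
#' @param contents Data frame or matrix of nonnegative contents,
#'   germplasms in rows and compounds in columns.
#' @param germplasm Character vector of germplasm identifiers.
#' @param species Character vector of species labels, one per germplasm.
#' @param origin Optional character vector of `"wild"`, `"cultivar"` or
#'   `"unknown"` flags; defaults to `"unknown"`.
#' @return A validated volatile profile tibble.
#' @export
as_volatiles <- function(contents, germplasm, species,
                         origin = rep("unknown", length(germplasm))) {
  contents <- as.data.frame(contents)
  if (nrow(contents) != length(germplasm)) {
    abort("contents and germplasm identifiers have different lengths")
  }
  if (length(species) != length(germplasm) ||
      length(origin) != length(germplasm)) {
    abort("species and origin must have one entry per germplasm")
  }
  out <- tibble::tibble(
    germplasm = as.character(germplasm),
    species = as.character(species),
    origin = as.character(origin)
  )
  out <- dplyr::bind_cols(out, tibble::as_tibble(contents))
  validate_volatiles(out)
  out
}

#' Read a volatile profile table from delimited text
#'
#' The content file is comma-separated with a header row of compound
#' identifiers and the germplasm identifier in the first column. The label
#' file maps each germplasm to its species and, optionally, a
#' wild/cultivar origin flag. Row and column order of the content file is
#' preserved.
#'
#' @param path Path to the content CSV.
#' @param label_path Path to the label CSV with columns `germplasm`,
#'   `species` and optionally `origin`.
#' @return A validated volatile profile tibble.
#' @export
read_volatiles <- function(path, label_path) {
  contents <- readr::read_csv(path, show_col_types = FALSE,
                              progress = FALSE)
  names(contents)[1] <- "germplasm"
  labels <- readr::read_csv(label_path, show_col_types = FALSE,
                            progress = FALSE)
  if (!all(c("germplasm", "species") %in% names(labels))) {
    abort("label file must have columns 'germplasm' and 'species'")
  }
  missing_lab <- setdiff(contents$germplasm, labels$germplasm)
  if (length(missing_lab) > 0) {
    abort(paste0("germplasm(s) missing from label file: ",
                 paste(missing_lab, collapse = ", ")))
  }
  idx <- match(contents$germplasm, labels$germplasm)
  origin <- if ("origin" %in% names(labels)) {
    as.character(labels$origin[idx])
  } else {
    rep("unknown", nrow(contents))
  }
  as_volatiles(contents[-1],
               germplasm = as.character(contents$germplasm),
               species = as.character(labels$species[idx]),
               origin = origin)
}

#' Write a volatile profile table to delimited text
#'
#' Inverse of [read_volatiles()]: the content matrix and the label table
#' are written to two CSV files that round-trip back to an identical
#' profile table.
#'
#' @param data A volatile profile table.
#' @param path Output path for the content CSV.
#' @param label_path Output path for the label CSV.
#' @return `data`, invisibly.
#' @export
write_volatiles <- function(data, path, label_path) {
  validate_volatiles(data)
  readr::write_csv(data[c("germplasm", compound_names(data))], path,
                   progress = FALSE)
  readr::write_csv(data[intersect(id_columns, names(data))], label_path,
                   progress = FALSE)
  invisible(data)
}

#' Keep compounds detected in a minimum number of germplasms
#'
#' A compound counts as detected in a germplasm when its content is
#' strictly greater than zero. Compounds detected in fewer than
#' `min_germplasms` germplasms are dropped; germplasms and the order of
#' the surviving compounds are unchanged. The default of 5 matches the
#' convention of requiring a compound in at least five germplasms before
#' it enters multivariate analysis.
#'
#' @param data A volatile profile table.
#' @param min_germplasms Positive integer detection threshold.
#' @return The filtered volatile profile tibble.
#' @export
filter_min_detection <- function(data, min_germplasms = 5) {
  validate_volatiles(data)
  if (length(min_germplasms) != 1 || min_germplasms < 1) {
    abort("min_germplasms must be a single integer >= 1")
  }
  cmp <- compound_names(data)
  keep <- vapply(cmp, function(cn) sum(data[[cn]] > 0) >= min_germplasms,
                 logical(1))
  data[c(intersect(id_columns, names(data)), cmp[keep])]
}

#' Per-species compound presence and Venn region counts
#'
#' A compound is present in a species when it is detected (content > 0)
#' in at least one germplasm of that species. For k species all
#' 2^k - 1 exclusive Venn regions are counted; compounds detected in no
#' listed species fall in no region, so the region counts sum to the size
#' of the union of the per-species presence sets.
#'
#' @param data A volatile profile table.
#' @param species Character vector of species labels to compare; defaults
#'   to every species present in `data`.
#' @return A tibble of class `presence_summary` with one row per Venn
#'   region: one logical membership column per species, the region label,
#'   the compound count and a list-column of the compounds in the region.
#'   The per-species presence sets are attached as attribute `"presence"`.
#' @export
presence_summary <- function(data, species = NULL) {
  validate_volatiles(data)
  if (is.null(species)) {
    species <- unique(data$species)
  }
  unknown <- setdiff(species, data$species)
  if (length(unknown) > 0) {
    abort(paste0("species label(s) not in table: ",
                 paste(unknown, collapse = ", ")))
  }
  cmp <- compound_names(data)
  presence <- lapply(species, function(s) {
    rows <- data$species == s
    cmp[vapply(cmp, function(cn) any(data[[cn]][rows] > 0), logical(1))]
  })
  names(presence) <- species
  k <- length(species)
  membership <- vapply(presence, function(set) cmp %in% set,
                       logical(length(cmp)))
  membership <- matrix(membership, nrow = length(cmp),
                       dimnames = list(cmp, species))
  combos <- expand.grid(rep(list(c(FALSE, TRUE)), k))[-1, , drop = FALSE]
  names(combos) <- species
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    mask <- as.logical(combos[i, ])
    in_region <- apply(membership, 1, function(m) all(m == mask))
    region_cmp <- cmp[in_region]
    c(as.list(combos[i, ]),
      list(region = paste(species[mask], collapse = "&"),
           n_compounds = length(region_cmp),
           compounds = list(region_cmp)))
  })
  out <- dplyr::bind_rows(lapply(rows, tibble::as_tibble))
  attr(out, "presence") <- presence
  class(out) <- c("presence_summary", class(out))
  out
}

# canonical compound key: lower-case, Greek beta spelled out, alphanumeric
# only, with the "nootkanone" spelling folded into "nootkatone"
normalize_compound <- function(x) {
  x <- tolower(x)
  x <- gsub("β", "beta", x)
  x <- gsub("[^a-z0-9]", "", x)
  x[x == "nootkanone"] <- "nootkatone"
  x
}

#' Load the packaged 30-germplasm marker call table
#'
#' Returns the packaged transcription of the published verification set:
#' 30 citrus germplasms (10 loose-skin mandarins, 9 sweet oranges, 6
#' pomelos and 5 lemon-group accessions) with yes/no detection calls for
#' the four marker compounds beta-elemene, valencene, nootkatone and
#' limettin. The lemon group follows the source labels verbatim, so it
#' includes finger citron and two limes.
#'
#' @return A tibble with columns `germplasm`, `actual_species` and one
#'   logical call column per marker.
#' @export
load_table2 <- function() {
  path <- system.file("extdata", "table2_marker_calls.csv",
                      package = "citrusvol", mustWork = TRUE)
  calls <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  for (cn in setdiff(names(calls), c("germplasm", "actual_species"))) {
    x <- toupper(calls[[cn]])
    if (!all(x %in% c("Y", "N"))) {
      abort(paste0("call column '", cn, "' has entries other than Y/N"))
    }
    calls[[cn]] <- x == "Y"
  }
  calls
}
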