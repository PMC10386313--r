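# the eight elements quantified alongside the fatty-acid profile
MINERAL_NAMES <- c("Ca", "Mg", "Na", "K", "P", "S", "Zn", "Fe")

# strings treated as missing on CSV read (case-insensitive)
MISSING_MARKERS <- c("", "na", "nan")

#' Construct a profile matrix
#'
#' The central data container: an `n x p` numeric matrix of concentrations
#' with a boolean mask of observed cells, per-sample month labels and
#' complete/partial tags, and per-variable roles (`"FAME"` or `"mineral"`).
#' Values at unobserved cells are stored as `NA` and never read.
#'
#' @param values Numeric matrix, samples in rows, variables in columns.
#' @param mask Logical matrix of the same shape, `TRUE` = observed. Defaults
#'   to `!is.na(values)`.
#' @param sample_ids Character vector of unique sample identifiers; defaults
#'   to row names or `S1..Sn`.
#' @param labels Per-sample class label (production month), character or
#'   factor of length `n`.
#' @param var_names Variable names; default column names.
#' @param var_roles Per-variable role, `"FAME"` or `"mineral"`. When `NULL`,
#'   a variable is tagged `"mineral"` iff its name is one of
#'   Ca, Mg, Na, K, P, S, Zn, Fe, and `"FAME"` otherwise.
#' @param completeness Optional per-sample tag `"complete"`/`"partial"`.
#'   Derived from the mask when `NULL` (complete iff fully observed); when
#'   supplied it must be consistent with the mask.
#' @return An object of class `profile_matrix`.
#' @export
profile_matrix <- function(values, mask = NULL, sample_ids = NULL, labels,
                           var_names = NULL, var_roles = NULL,
                           completeness = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  n <- nrow(values)
  p <- ncol(values)
  if (is.null(mask)) mask <- !is.na(values)
  mask <- as.matrix(mask)
  if (!is.logical(mask) || !identical(dim(mask), dim(values))) {
    stop("`mask` must be a logical matrix with the same shape as `values`")
  }
  if (anyNA(values[mask])) stop("observed cells (mask = TRUE) must not be NA")
  values[!mask] <- NA_real_

  sample_ids <- as.character(sample_ids %||% rownames(values) %||%
                               paste0("S", seq_len(n)))
  if (length(sample_ids) != n) stop("`sample_ids` must have length nrow(values)")
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample ids: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  }
  if (length(labels) != n) stop("`labels` must have length nrow(values)")
  labels <- if (is.factor(labels)) labels else factor(labels, levels = unique(labels))

  var_names <- as.character(var_names %||% colnames(values) %||%
                              paste0("V", seq_len(p)))
  if (length(var_names) != p) stop("`var_names` must have length ncol(values)")
  if (is.null(var_roles)) {
    var_roles <- ifelse(var_names %in% MINERAL_NAMES, "mineral", "FAME")
  }
  var_roles <- as.character(var_roles)
  if (length(var_roles) != p || !all(var_roles %in% c("FAME", "mineral"))) {
    stop("`var_roles` must be length ncol(values) with values 'FAME'/'mineral'")
  }

  derived <- unname(ifelse(rowSums(!mask) == 0L, "complete", "partial"))
  if (is.null(completeness)) {
    completeness <- derived
  } else {
    completeness <- as.character(completeness)
    if (length(completeness) != n ||
        !all(completeness %in% c("complete", "partial"))) {
      stop("`completeness` must be length n with values 'complete'/'partial'")
    }
    bad <- completeness == "complete" & derived != "complete"
    if (any(bad)) {
      stop("samples tagged complete but with missing cells: ",
           paste(sample_ids[bad], collapse = ", "))
    }
  }

  dimnames(values) <- dimnames(mask) <- list(sample_ids, var_names)
  structure(
    list(values = values, mask = mask, sample_ids = sample_ids,
         labels = labels, completeness = completeness,
         var_names = var_names, var_roles = var_roles),
    class = "profile_matrix"
  )
}

#' @export
dim.profile_matrix <- function(x) dim(x$values)

#' @export
print.profile_matrix <- function(x, ...) {
  n_partial <- sum(x$completeness == "partial")
  cat(sprintf("profile_matrix: %d samples x %d variables (%d FAME, %d mineral)\n",
              nrow(x$values), ncol(x$values),
              sum(x$var_roles == "FAME"), sum(x$var_roles == "mineral")))
  cat(sprintf("  classes: %s\n",
              paste(sprintf("%s=%d", levels(x$labels), table(x$labels)),
                    collapse = ", ")))
  cat(sprintf("  %d complete, %d partial samples; %d missing cells\n",
              nrow(x$values) - n_partial, n_partial, sum(!x$mask)))
  invisible(x)
}

#' Subset samples of a profile matrix
#'
#' Row subsetting by index, logical vector, or sample id. Completeness tags
#' are recomputed from the sub-mask.
#'
#' @param x A `profile_matrix`.
#' @param i Row selector.
#' @param ... Ignored.
#' @return A `profile_matrix` with the selected samples.
#' @export
`[.profile_matrix` <- function(x, i, ...) {
  if (is.character(i)) i <- match(i, x$sample_ids)
  if (anyNA(i)) stop("unknown sample id in subset")
  profile_matrix(
    values = x$values[i, , drop = FALSE],
    mask = x$mask[i, , drop = FALSE],
    sample_ids = x$sample_ids[i],
    labels = x$labels[i],
    var_names = x$var_names,
    var_roles = x$var_roles
  )
}

fame_cols <- function(pm) which(pm$var_roles == "FAME")
mineral_cols <- function(pm) which(pm$var_roles == "mineral")

#' Read a profile matrix from CSV
#'
#' Expects a header row, a sample-id column, a label column, and one numeric
#' column per variable. Empty cells, `NA` and `NaN` (case-insensitive) are
#' treated as missing; any other non-numeric cell is a parse error reported
#' with its row and column. Completeness tags are derived from the mask.
#'
#' @param path CSV file path.
#' @param id_col,label_col Names of the sample-id and label columns.
#' @param var_roles Optional explicit role vector for the variable columns;
#'   by default the 8 standard mineral names are tagged `"mineral"`.
#' @return A [profile_matrix()].
#' @export
read_profile_csv <- function(path, id_col = "sample_id", label_col = "label",
                             var_roles = NULL) {
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  for (col in c(id_col, label_col)) {
    if (!col %in% names(raw)) stop("column '", col, "' not found in ", path)
  }
  ids <- raw[[id_col]]
  if (anyDuplicated(ids)) {
    stop("duplicate sample ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  var_names <- setdiff(names(raw), c(id_col, label_col))
  vals <- matrix(NA_real_, nrow(raw), length(var_names),
                 dimnames = list(ids, var_names))
  for (j in seq_along(var_names)) {
    cell <- raw[[var_names[j]]]
    missing <- is.na(cell) | tolower(trimws(cell)) %in% MISSING_MARKERS
    num <- suppressWarnings(as.numeric(cell))
    bad <- !missing & is.na(num)
    if (any(bad)) {
      stop(sprintf("non-numeric value '%s' at row %d, column '%s' of %s",
                   cell[which(bad)[1]], which(bad)[1], var_names[j], path))
    }
    num[missing] <- NA_real_
    vals[, j] <- num
  }
  profile_matrix(vals, sample_ids = ids, labels = raw[[label_col]],
                 var_names = var_names, var_roles = var_roles)
}

#' Write a profile matrix to CSV
#'
#' Missing cells are written as `NA`. Re-reading reproduces values at observed
#' cells and the mask exactly.
#'
#' @param pm A `profile_matrix`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_profile_csv <- function(pm, path) {
  df <- data.frame(sample_id = pm$sample_ids, label = as.character(pm$labels),
                   check.names = FALSE, stringsAsFactors = FALSE)
  df <- cbind(df, as.data.frame(pm$values, check.names = FALSE))
  utils::write.csv(df, path, row.names = FALSE, na = "NA")
  invisible(path)
}

#' Run configuration for the validation protocols
#'
#' Bundles the tunables shared by the Monte-Carlo validation drivers: the
#' model-order sweep, number of iterations, master seed and the calibration
#' fraction of complete samples.
#'
#' @param n_components Integer vector of model orders to sweep.
#' @param n_iterations Number of Monte-Carlo iterations (default 20).
#' @param seed Master seed; every source of randomness in a run derives from it.
#' @param calibration_complete_fraction Fraction of complete samples assigned
#'   to calibration at each iteration (default 0.85).
#' @param holdout_fraction Fraction of complete samples held out per month in
#'   the imputation protocol (default 0.2).
#' @return A list of class `run_config`.
#' @export
run_config <- function(n_components = 1:8, n_iterations = 20L, seed = 1L,
                       calibration_complete_fraction = 0.85,
                       holdout_fraction = 0.2) {
  stopifnot(length(n_iterations) == 1L, n_iterations >= 1,
            calibration_complete_fraction > 0,
            calibration_complete_fraction < 1,
            holdout_fraction > 0, holdout_fraction < 1,
            all(n_components >= 1))
  structure(list(n_components = as.integer(n_components),
                 n_iterations = as.integer(n_iterations),
                 seed = as.integer(seed),
                 calibration_complete_fraction = calibration_complete_fraction,
                 holdout_fraction = holdout_fraction),
            class = "run_config")
}
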