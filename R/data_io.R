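#' @useDynLib qsarscreen, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom e1071 svm naiveBayes
#' @importFrom ranger ranger
#' @importFrom xgboost xgb.train
#' @importFrom class knn
#' @importFrom jsonlite write_json
#' @importFrom yaml read_yaml
#' @importFrom stats predict quantile rnorm rlogis runif sd var median
#'   pchisq qnorm qlogis uniroot setNames
#' @importFrom utils read.csv write.csv head modifyList
NULL

# Canonical ADMET endpoint names, in fixed order.
ADMET_PROPERTIES <- c("Caco-2", "CYP3A4", "hERG", "HOB", "MN")

#' Validate and construct a descriptor matrix
#'
#' A descriptor matrix is an n x p numeric matrix with unique compound
#' identifiers as row names and unique descriptor names as column names.
#' All entries must be finite; missing values are rejected rather than
#' imputed.
#'
#' @param values numeric matrix of descriptor values.
#' @param compound_ids character vector of unique compound identifiers.
#' @param descriptor_names character vector of unique descriptor names.
#' @return a numeric matrix with class `descriptor_matrix`.
#' @export
descriptor_matrix <- function(values, compound_ids = rownames(values),
                              descriptor_names = colnames(values)) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("descriptor values must be numeric")
  if (is.null(compound_ids) || is.null(descriptor_names))
    stop("compound_ids and descriptor_names are required")
  compound_ids <- as.character(compound_ids)
  descriptor_names <- as.character(descriptor_names)
  if (length(compound_ids) != nrow(values))
    stop("compound_ids length does not match row count")
  if (length(descriptor_names) != ncol(values))
    stop("descriptor_names length does not match column count")
  dup <- compound_ids[duplicated(compound_ids)]
  if (length(dup))
    stop("duplicate compound id(s): ", paste(unique(dup), collapse = ", "))
  dupd <- descriptor_names[duplicated(descriptor_names)]
  if (length(dupd))
    stop("duplicate descriptor name(s): ", paste(unique(dupd), collapse = ", "))
  if (any(!is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1, ]
    stop(sprintf("non-finite descriptor value at compound '%s', descriptor '%s'",
                 compound_ids[bad[1]], descriptor_names[bad[2]]))
  }
  dimnames(values) <- list(compound_ids, descriptor_names)
  class(values) <- c("descriptor_matrix", class(values))
  values
}

#' Read a descriptor table from CSV
#'
#' Reads a PaDEL-style descriptor CSV: one identifier column (default
#' `"Name"`) and numeric descriptor columns, preserving file column order.
#'
#' @param path path to a CSV file with a header row.
#' @param id_column name of the identifier column.
#' @return a [descriptor_matrix()].
#' @export
read_descriptor_table <- function(path, id_column = "Name") {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(df) == 0L || ncol(df) <= 1L) stop("empty descriptor table: ", path)
  if (!id_column %in% names(df))
    stop("identifier column '", id_column, "' not found in ", path)
  ids <- as.character(df[[id_column]])
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicate compound id(s): ", paste(unique(dup), collapse = ", "))
  vals <- df[, setdiff(names(df), id_column), drop = FALSE]
  for (j in seq_along(vals)) {
    col <- vals[[j]]
    if (is.character(col) || is.logical(col) || is.factor(col))
      col <- suppressWarnings(as.numeric(as.character(col)))
    bad <- which(!is.finite(col))
    if (length(bad))
      stop(sprintf("non-numeric or missing value in column '%s', row %d (compound '%s')",
                   names(vals)[j], bad[1], ids[bad[1]]))
    vals[[j]] <- col
  }
  descriptor_matrix(as.matrix(vals), compound_ids = ids,
                    descriptor_names = names(vals))
}

#' Read an activity or ADMET label table from CSV
#'
#' With `schema = "activity"` the file must carry the identifier column and
#' either a `pIC50` column or an `IC50` column (converted via
#' [ic50_to_pic50()] using `ic50_unit`). With `schema = "admet"` the file
#' must carry the five binary endpoint columns Caco-2, CYP3A4, hERG, HOB
#' and MN, strictly coded 0/1.
#'
#' @param path path to a CSV file.
#' @param schema `"activity"` or `"admet"`.
#' @param id_column identifier column name.
#' @param ic50_unit unit of an IC50 column, one of `"nM"`, `"uM"`, `"M"`.
#' @return for `"activity"`, a data.frame with columns `compound_id`,
#'   `pic50`; for `"admet"`, a data.frame with `compound_id` plus the five
#'   0/1 endpoint columns.
#' @export
read_label_table <- function(path, schema = c("activity", "admet"),
                             id_column = "Name", ic50_unit = "nM") {
  schema <- match.arg(schema)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!id_column %in% names(df))
    stop("identifier column '", id_column, "' not found in ", path)
  ids <- as.character(df[[id_column]])
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicate compound id(s): ", paste(unique(dup), collapse = ", "))
  if (schema == "activity") {
    if ("pIC50" %in% names(df)) {
      p <- as.numeric(df[["pIC50"]])
    } else if ("IC50" %in% names(df)) {
      p <- ic50_to_pic50(as.numeric(df[["IC50"]]), unit = ic50_unit)
    } else stop("activity table needs a 'pIC50' or 'IC50' column")
    if (any(!is.finite(p))) stop("non-finite activity value in ", path)
    data.frame(compound_id = ids, pic50 = p, stringsAsFactors = FALSE)
  } else {
    miss <- setdiff(ADMET_PROPERTIES, names(df))
    if (length(miss))
      stop("missing ADMET column(s): ", paste(miss, collapse = ", "))
    out <- data.frame(compound_id = ids, stringsAsFactors = FALSE)
    for (prop in ADMET_PROPERTIES) {
      v <- df[[prop]]
      if (!all(v %in% c(0, 1)))
        stop("ADMET column '", prop, "' has values outside {0,1}")
      out[[prop]] <- as.integer(v)
    }
    out
  }
}

#' Convert IC50 to pIC50
#'
#' pIC50 is the negative base-10 logarithm of the molar IC50; higher values
#' mean stronger inhibition.
#'
#' @param ic50_value positive IC50 value(s).
#' @param unit unit of `ic50_value`: `"nM"`, `"uM"` or `"M"`.
#' @return pIC50 value(s).
#' @examples
#' ic50_to_pic50(1000, "nM")  # 6
#' @export
ic50_to_pic50 <- function(ic50_value, unit = c("nM", "uM", "M")) {
  unit <- match.arg(unit)
  if (any(!is.finite(ic50_value)) || any(ic50_value <= 0))
    stop("IC50 values must be positive and finite")
  scale <- c(nM = 1e-9, uM = 1e-6, M = 1)[[unit]]
  -log10(ic50_value * scale)
}

#' Remove uninformative descriptor columns
#'
#' `mode = "zero_constant"` removes columns that are identically zero;
#' `mode = "zero_variance"` removes all constant columns (any value).
#'
#' @param m a [descriptor_matrix()].
#' @param mode removal rule.
#' @return list with `matrix` (surviving columns, order preserved) and
#'   `removed` (names of dropped columns in original column order).
#' @export
drop_uninformative_descriptors <- function(m,
                                           mode = c("zero_constant", "zero_variance")) {
  mode <- match.arg(mode)
  drop <- if (mode == "zero_constant") {
    apply(m, 2, function(x) all(x == 0))
  } else {
    apply(m, 2, function(x) max(x) == min(x))
  }
  if (all(drop)) stop("all descriptor columns are uninformative; degenerate dataset")
  kept <- m[, !drop, drop = FALSE]
  list(matrix = descriptor_matrix(kept),
       removed = colnames(m)[drop])
}

#' Fit min-max normalization statistics
#'
#' Statistics are intended to be fitted on the training partition only and
#' then applied to any partition with [apply_minmax()].
#'
#' @param m a [descriptor_matrix()] (training partition).
#' @param fitted_on optional label recording which partition was used.
#' @return an object of class `minmax_stats` with per-descriptor `min` and
#'   `max`.
#' @export
fit_minmax <- function(m, fitted_on = "train") {
  structure(list(min = apply(m, 2, min), max = apply(m, 2, max),
                 descriptor_names = colnames(m), fitted_on = fitted_on),
            class = "minmax_stats")
}

#' Apply min-max normalization
#'
#' Transforms each descriptor to `(x - min) / (max - min)` using fitted
#' statistics. Values outside the fitted range are not clamped, so test
#' values can fall outside \[0, 1\]. Descriptors that were constant during
#' fitting map to 0 with a warning.
#'
#' @param m a [descriptor_matrix()].
#' @param stats a `minmax_stats` object from [fit_minmax()].
#' @return the normalized [descriptor_matrix()].
#' @export
apply_minmax <- function(m, stats) {
  if (!inherits(stats, "minmax_stats")) stop("stats must come from fit_minmax()")
  miss <- setdiff(colnames(m), stats$descriptor_names)
  if (length(miss))
    stop("normalization stats missing for descriptor(s): ",
         paste(miss, collapse = ", "))
  mn <- stats$min[colnames(m)]
  mx <- stats$max[colnames(m)]
  rng <- mx - mn
  const <- rng == 0
  if (any(const)) {
    warning("constant descriptor(s) map to 0 after min-max: ",
            paste(colnames(m)[const], collapse = ", "))
    rng[const] <- 1
  }
  out <- sweep(sweep(unclass(m), 2, mn, "-"), 2, rng, "/")
  out[, const] <- 0
  descriptor_matrix(out)
}

#' Split compound identifiers into train and test sets
#'
#' A uniformly random permutation driven solely by `seed`; the training set
#' takes the first `floor(ratio * n)` identifiers.
#'
#' @param ids character vector of identifiers.
#' @param ratio training fraction in (0, 1).
#' @param seed integer seed.
#' @return list with `train_ids`, `test_ids`, `seed`.
#' @export
split_train_test <- function(ids, ratio = 0.8, seed = 1L) {
  if (ratio <= 0 || ratio >= 1) stop("ratio must be in (0, 1)")
  n <- length(ids)
  n_train <- floor(ratio * n)
  if (n < 2L || n_train < 1L || n_train >= n)
    stop("too few identifiers for a nonempty train/test split")
  perm <- with_seed(seed, sample.int(n))
  list(train_ids = ids[perm[seq_len(n_train)]],
       test_ids = ids[perm[(n_train + 1L):n]],
       seed = as.integer(seed))
}

# Evaluate an expression under a local RNG seed, restoring the caller's
# RNG state afterwards.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic fan-out of one pipeline seed into per-component seeds,
# kept within the 32-bit integer range.
fanout_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 7919 + 104729 * as.numeric(index)) %% 2147483647)
}

#' Write a descriptor matrix to CSV
#'
#' Inverse of [read_descriptor_table()]; finite doubles round-trip
#' bit-identically.
#'
#' @param m a [descriptor_matrix()].
#' @param path output path.
#' @param id_column identifier column name.
#' @export
write_descriptor_table <- function(m, path, id_column = "Name") {
  df <- data.frame(rownames(m), unclass(m), check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_column
  write.csv(format(df, digits = 17, trim = TRUE), path, row.names = FALSE,
            quote = FALSE)
  invisible(path)
}
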