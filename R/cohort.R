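#' Define a cohort variable
#'
#' A variable schema entry describes one covariate column: its name, whether
#' it is continuous or categorical, the ordered category labels (categorical
#' only, coded as consecutive integers starting at 1 so that logarithms of
#' codes are defined), and a non-negative positivity offset added to
#' continuous values before log-transformation and removed on output.
#'
#' @param name Variable name (must match the CSV header).
#' @param kind `"continuous"` or `"categorical"`.
#' @param categories Ordered character vector of category labels
#'   (categorical only, at least 2). The first label receives code 1.
#' @param positivity_offset Non-negative value added to continuous
#'   observations so that every observed value is strictly positive.
#' @return A `vp_variable` list.
#' @export
vp_variable <- function(name, kind = c("continuous", "categorical"),
                        categories = NULL, positivity_offset = 0) {
  kind <- match.arg(kind)
  if (kind == "categorical") {
    if (is.null(categories) || length(categories) < 2L)
      stop("categorical variable '", name, "' needs >= 2 categories",
           call. = FALSE)
    if (anyDuplicated(categories))
      stop("duplicate category labels in '", name, "'", call. = FALSE)
    categories <- as.character(categories)
    positivity_offset <- 0
  } else {
    categories <- NULL
    if (positivity_offset < 0)
      stop("positivity_offset must be >= 0", call. = FALSE)
  }
  structure(list(name = as.character(name), kind = kind,
                 categories = categories,
                 positivity_offset = positivity_offset),
            class = "vp_variable")
}

#' Assemble a variable schema
#'
#' @param ... `vp_variable` entries (or a single list of them).
#' @return A `vp_schema`: an ordered list of `vp_variable` entries.
#' @export
vp_schema <- function(...) {
  vars <- list(...)
  if (length(vars) == 1L && !inherits(vars[[1L]], "vp_variable"))
    vars <- vars[[1L]]
  if (!length(vars)) stop("schema needs at least one variable", call. = FALSE)
  ok <- vapply(vars, inherits, logical(1), "vp_variable")
  if (!all(ok)) stop("all schema entries must be vp_variable objects",
                     call. = FALSE)
  nms <- vapply(vars, `[[`, character(1), "name")
  if (anyDuplicated(nms))
    stop("duplicate variable names in schema", call. = FALSE)
  names(vars) <- nms
  structure(vars, class = "vp_schema")
}

schema_names <- function(schema)
  unname(vapply(schema, `[[`, character(1), "name"))
schema_kinds <- function(schema)
  unname(vapply(schema, `[[`, character(1), "kind"))
schema_offsets <- function(schema)
  vapply(schema, function(v) v$positivity_offset %||% 0, numeric(1))

`%||%` <- function(a, b) if (is.null(a)) b else a

n_categories <- function(variable) length(variable$categories)

#' Read a variable schema from JSON
#'
#' The file is a JSON array of objects with fields `name`, `kind`,
#' `categories` (categorical only) and optional `positivity_offset`.
#'
#' @param path Path to the schema JSON file.
#' @return A `vp_schema`.
#' @export
read_schema <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  vars <- lapply(raw, function(v)
    vp_variable(v$name, v$kind,
                categories = if (!is.null(v$categories))
                  unlist(v$categories, use.names = FALSE),
                positivity_offset = v$positivity_offset %||% 0))
  vp_schema(vars)
}

#' Write a variable schema to JSON
#'
#' @param schema A `vp_schema`.
#' @param path Output path.
#' @export
write_schema <- function(schema, path) {
  out <- lapply(schema, function(v) {
    x <- list(name = v$name, kind = v$kind)
    if (v$kind == "categorical") x$categories <- v$categories
    if ((v$positivity_offset %||% 0) != 0)
      x$positivity_offset <- v$positivity_offset
    x
  })
  jsonlite::write_json(unname(out), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Construct a cohort
#'
#' A cohort couples a patient-by-covariate table with its schema. Categorical
#' columns are stored as integer codes `1..k` (the position of the label in
#' the schema's `categories`); `NA` is the explicit missing marker.
#' Continuous variables whose observed minimum (plus the declared offset) is
#' not strictly positive get an automatic positivity offset of
#' `1 - min(observed)` recorded in the schema, so the log-transform is
#' always defined.
#'
#' @param data A data.frame with one column per schema variable. Categorical
#'   columns may hold either labels or integer codes.
#' @param schema A `vp_schema`.
#' @param ids Optional character vector of per-row identifiers.
#' @return A `vp_cohort` with elements `data`, `schema`, `ids`.
#' @export
vp_cohort <- function(data, schema, ids = NULL) {
  stopifnot(is.data.frame(data), inherits(schema, "vp_schema"))
  nms <- schema_names(schema)
  missing_cols <- setdiff(nms, names(data))
  if (length(missing_cols))
    stop("data lacks schema column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  data <- data[nms]
  n <- nrow(data)
  if (is.null(ids)) ids <- sprintf("P%04d", seq_len(n))
  ids <- as.character(ids)
  if (length(ids) != n) stop("ids length must equal nrow(data)", call. = FALSE)

  for (v in schema) {
    col <- data[[v$name]]
    if (v$kind == "categorical") {
      if (is.character(col) || is.factor(col)) {
        col <- as.character(col)
        col[!is.na(col) & col == ""] <- NA
        codes <- match(col, v$categories)
        bad <- which(!is.na(col) & is.na(codes))
        if (length(bad))
          stop("unknown category label '", col[bad[1L]], "' in column '",
               v$name, "', row ", bad[1L], call. = FALSE)
        data[[v$name]] <- as.integer(codes)
      } else {
        codes <- as.integer(col)
        k <- n_categories(v)
        bad <- which(!is.na(codes) & (codes < 1L | codes > k))
        if (length(bad))
          stop("categorical code out of range 1..", k, " in column '",
               v$name, "', row ", bad[1L], call. = FALSE)
        data[[v$name]] <- codes
      }
    } else {
      col <- as.numeric(col)
      obs <- col[!is.na(col)]
      if (length(obs) && min(obs) + v$positivity_offset <= 0) {
        v$positivity_offset <- 1 - min(obs)
        schema[[v$name]] <- v
      }
      data[[v$name]] <- col
    }
  }
  structure(list(data = data, schema = schema, ids = ids),
            class = "vp_cohort")
}

#' @export
print.vp_cohort <- function(x, ...) {
  kinds <- schema_kinds(x$schema)
  cat("Virtual-population cohort: ", nrow(x$data), " patients x ",
      length(x$schema), " covariates (", sum(kinds == "continuous"),
      " continuous, ", sum(kinds == "categorical"), " categorical)\n",
      sep = "")
  nmiss <- sum(is.na(as.matrix(x$data)))
  if (nmiss) cat("Missing cells:", nmiss, "\n")
  invisible(x)
}

#' @export
dim.vp_cohort <- function(x) dim(x$data)

#' Read a cohort from CSV plus schema JSON
#'
#' The CSV must carry a header matching the schema names and a `patient_id`
#' first column. Empty cells and `NA` become missing markers; categorical
#' labels are encoded to integer codes.
#'
#' @param path Cohort CSV path.
#' @param schema_path Schema JSON path (or an already-built `vp_schema`).
#' @return A `vp_cohort`.
#' @export
read_cohort <- function(path, schema_path) {
  schema <- if (inherits(schema_path, "vp_schema")) schema_path
            else read_schema(schema_path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                        na.strings = c("", "NA"))
  if (anyDuplicated(names(df)))
    stop("duplicate column in ", path, ": ",
         names(df)[duplicated(names(df))][1L], call. = FALSE)
  if (!"patient_id" %in% names(df))
    stop("cohort CSV must have a 'patient_id' column", call. = FALSE)
  ids <- as.character(df[["patient_id"]])
  vp_cohort(df[setdiff(names(df), "patient_id")], schema, ids = ids)
}

#' Write a cohort to CSV
#'
#' Categorical codes are decoded back to their labels; continuous values are
#' written as stored (positivity offsets live in the schema, not the data).
#'
#' @param cohort A `vp_cohort`.
#' @param path Output CSV path.
#' @export
write_cohort <- function(cohort, path) {
  df <- cohort$data
  for (v in cohort$schema)
    if (v$kind == "categorical")
      df[[v$name]] <- v$categories[df[[v$name]]]
  df <- cbind(patient_id = cohort$ids, df)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Encode a cohort as a numeric matrix with missing mask
#'
#' Categorical cells become their integer codes; continuous cells are shifted
#' by the schema's positivity offset so every non-missing entry is strictly
#' positive. The mask marks missing cells (`TRUE` = missing).
#'
#' @param cohort A `vp_cohort`.
#' @return List with `values` (n x p numeric matrix) and `mask`
#'   (n x p logical matrix, `TRUE` where missing).
#' @export
encode_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "vp_cohort"))
  m <- as.matrix(as.data.frame(lapply(cohort$data, as.numeric)))
  colnames(m) <- schema_names(cohort$schema)
  rownames(m) <- cohort$ids
  off <- schema_offsets(cohort$schema)
  m <- sweep(m, 2L, off, `+`)
  mask <- is.na(m)
  list(values = m, mask = mask)
}

#' Decode an encoded matrix back into a cohort
#'
#' Inverse of [encode_cohort()]: removes positivity offsets and rounds/clamps
#' categorical columns to valid integer codes.
#'
#' @param values n x p numeric matrix in encoded (offset) space.
#' @param schema The `vp_schema` the matrix was encoded under.
#' @param ids Optional row identifiers.
#' @return A `vp_cohort`.
#' @export
decode_cohort <- function(values, schema, ids = NULL) {
  off <- schema_offsets(schema)
  values <- sweep(values, 2L, off, `-`)
  df <- as.data.frame(values)
  names(df) <- schema_names(schema)
  rownames(df) <- NULL
  for (v in schema)
    if (v$kind == "categorical") {
      k <- n_categories(v)
      df[[v$name]] <- as.integer(pmin(pmax(round(df[[v$name]]), 1L), k))
    }
  if (is.null(ids) && !is.null(rownames(values))) ids <- rownames(values)
  vp_cohort(df, schema, ids = ids)
}
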