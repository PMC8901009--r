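#' Two-sample Kolmogorov-Smirnov goodness-of-fit statistic
#'
#' The supremum distance between the empirical CDFs of the real and virtual
#' samples, `sup |F_real - F_virtual|`, in [0, 1]; smaller means better
#' marginal agreement. Applied to categorical variables it acts on the
#' integer codes, which is still a valid sup-difference statistic on a
#' discrete support. Only the statistic is reported, never a p-value.
#'
#' @param real_values,virtual_values Non-empty numeric samples.
#' @return KS statistic in [0, 1].
#' @export
ks_gof <- function(real_values, virtual_values) {
  real_values <- real_values[!is.na(real_values)]
  virtual_values <- virtual_values[!is.na(virtual_values)]
  if (!length(real_values) || !length(virtual_values))
    stop("both samples must be non-empty", call. = FALSE)
  unname(suppressWarnings(
    stats::ks.test(real_values, virtual_values)$statistic))
}

#' Sample moments: mean, SD, skewness, kurtosis
#'
#' SD uses the 1/(n-1) convention; skewness is `m3 / m2^1.5` and kurtosis is
#' Pearson's `m4 / m2^2` (a normal distribution gives 3), with `m_j` the
#' central sample moments normalized by n. With `excess = TRUE` kurtosis is
#' reported as `m4/m2^2 - 3`. Higher moments are `NA` when undefined
#' (constant sample, or too few observations).
#'
#' @param values Numeric sample.
#' @param excess Report excess kurtosis instead of Pearson kurtosis.
#' @return Named vector `c(mean, sd, skewness, kurtosis)`.
#' @export
sample_moments <- function(values, excess = FALSE) {
  values <- values[!is.na(values)]
  n <- length(values)
  out <- c(mean = NA_real_, sd = NA_real_, skewness = NA_real_,
           kurtosis = NA_real_)
  if (n >= 1L) out["mean"] <- mean(values)
  if (n >= 2L) out["sd"] <- stats::sd(values)
  m2 <- mean((values - mean(values))^2)
  if (n >= 3L && m2 > 0)
    out["skewness"] <- mean((values - mean(values))^3) / m2^1.5
  if (n >= 4L && m2 > 0) {
    k <- mean((values - mean(values))^4) / m2^2
    out["kurtosis"] <- if (excess) k - 3 else k
  }
  out
}

#' Category percentage table for a real/virtual cohort pair
#'
#' Per categorical variable, the percentage of each category in the real and
#' in the virtual cohort; percentages within a cohort sum to 100.
#'
#' @param real,virtual `vp_cohort`s sharing a schema.
#' @return data.frame with columns `variable`, `category`, `real_pct`,
#'   `virtual_pct`.
#' @export
categorical_table <- function(real, virtual) {
  check_shared_schema(real, virtual)
  rows <- list()
  for (v in real$schema)
    if (v$kind == "categorical") {
      k <- n_categories(v)
      pr <- tabulate(real$data[[v$name]], nbins = k)
      pv <- tabulate(virtual$data[[v$name]], nbins = k)
      rows[[v$name]] <- data.frame(
        variable = v$name, category = v$categories,
        real_pct = 100 * pr / sum(pr), virtual_pct = 100 * pv / sum(pv))
    }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out %||% data.frame(variable = character(0), category = character(0),
                      real_pct = numeric(0), virtual_pct = numeric(0))
}

check_shared_schema <- function(real, virtual) {
  if (!identical(schema_names(real$schema), schema_names(virtual$schema)) ||
      !identical(schema_kinds(real$schema), schema_kinds(virtual$schema)))
    stop("real and virtual cohorts must share a schema", call. = FALSE)
}

#' Validate a virtual cohort against its real source
#'
#' Computes, per variable: the two-sample KS goodness-of-fit statistic
#' between real and virtual values, and mean/SD/skewness/kurtosis for both
#' cohorts; for categorical variables, the category percentage table.
#' Summarizes the per-variable gof values as mean +/- SD, and compares the
#' pairwise Pearson correlation matrices (computed on log-transformed
#' encoded values) by their elementwise maximum absolute difference.
#' Zero-variance columns yield `NA` correlations and are ignored in the
#' maximum. A legacy block reports the mean and SD of the raw data columns
#' of each cohort.
#'
#' @param real,virtual `vp_cohort`s sharing a schema (no missing cells in
#'   columns being compared is not required; `NA`s are dropped per variable).
#' @param excess_kurtosis Passed to [sample_moments()].
#' @return A `vp_report`.
#' @export
vp_validate <- function(real, virtual, excess_kurtosis = FALSE) {
  check_shared_schema(real, virtual)
  nms <- schema_names(real$schema)
  per_variable <- lapply(nms, function(nm) {
    rv <- as.numeric(real$data[[nm]])
    vv <- as.numeric(virtual$data[[nm]])
    list(variable = nm, kind = real$schema[[nm]]$kind,
         gof = ks_gof(rv, vv),
         real = as.list(sample_moments(rv, excess = excess_kurtosis)),
         virtual = as.list(sample_moments(vv, excess = excess_kurtosis)))
  })
  names(per_variable) <- nms
  gof <- vapply(per_variable, `[[`, numeric(1), "gof")

  cor_real <- safe_cor(real)
  cor_virtual <- safe_cor(virtual)
  dmat <- abs(cor_real - cor_virtual)
  max_cor_diff <- if (all(is.na(dmat))) NA_real_ else max(dmat, na.rm = TRUE)

  legacy <- list(
    real = list(mean_of_columns = mean(colMeans(raw_matrix(real),
                                                na.rm = TRUE)),
                sd_of_columns = mean(apply(raw_matrix(real), 2, stats::sd,
                                           na.rm = TRUE))),
    virtual = list(mean_of_columns = mean(colMeans(raw_matrix(virtual),
                                                   na.rm = TRUE)),
                   sd_of_columns = mean(apply(raw_matrix(virtual), 2,
                                              stats::sd, na.rm = TRUE))))

  structure(list(per_variable = per_variable,
                 summary = list(mean_gof = mean(gof),
                                sd_gof = stats::sd(gof)),
                 categorical = categorical_table(real, virtual),
                 correlation = list(real = cor_real, virtual = cor_virtual,
                                    max_abs_diff = max_cor_diff),
                 legacy_column_summary = legacy,
                 kurtosis_convention = if (excess_kurtosis) "excess"
                                       else "pearson"),
            class = "vp_report")
}

raw_matrix <- function(cohort)
  as.matrix(as.data.frame(lapply(cohort$data, as.numeric)))

safe_cor <- function(cohort) {
  lg <- log_transform(encode_cohort(cohort))
  x <- lg$values
  x[lg$mask] <- NA
  sds <- apply(x, 2, stats::sd, na.rm = TRUE)
  cc <- suppressWarnings(stats::cor(x, use = "pairwise.complete.obs"))
  cc[sds == 0 | is.na(sds), ] <- NA
  cc[, sds == 0 | is.na(sds)] <- NA
  diag(cc) <- 1
  cc
}

#' @export
print.vp_report <- function(x, ...) {
  cat("Real-vs-virtual validation (kurtosis convention: ",
      x$kurtosis_convention, ")\n", sep = "")
  cat(sprintf("  mean gof %.3f +/- %.3f over %d variables\n",
              x$summary$mean_gof, x$summary$sd_gof, length(x$per_variable)))
  cat(sprintf("  max |cor_real - cor_virtual| = %.3f\n",
              x$correlation$max_abs_diff))
  worst <- sort(vapply(x$per_variable, `[[`, numeric(1), "gof"),
                decreasing = TRUE)
  cat("  worst gof:", paste(sprintf("%s=%.3f", names(worst)[1:min(3,
      length(worst))], worst[1:min(3, length(worst))]), collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
summary.vp_report <- function(object, ...) {
  data.frame(variable = names(object$per_variable),
             kind = vapply(object$per_variable, `[[`, character(1), "kind"),
             gof = vapply(object$per_variable, `[[`, numeric(1), "gof"),
             real_mean = vapply(object$per_variable,
                                function(v) v$real$mean, numeric(1)),
             virtual_mean = vapply(object$per_variable,
                                   function(v) v$virtual$mean, numeric(1)),
             row.names = NULL)
}

#' Serialize a validation report to JSON
#'
#' @param report A `vp_report`.
#' @param path Output path.
#' @export
write_report <- function(report, path) {
  out <- unclass(report)
  out$correlation$real <- as.data.frame(out$correlation$real)
  out$correlation$virtual <- as.data.frame(out$correlation$virtual)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' Read a serialized validation report
#'
#' @param path Path written by [write_report()].
#' @return A `vp_report`.
#' @export
read_report <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  raw$correlation$real <- as.matrix(raw$correlation$real)
  raw$correlation$virtual <- as.matrix(raw$correlation$virtual)
  raw$per_variable <- lapply(raw$per_variable, function(v) {
    v$real <- as.list(v$real); v$virtual <- as.list(v$virtual); v
  })
  structure(raw, class = "vp_report")
}

#' Render a validation report as Markdown tables
#'
#' Emits a moments table, a categorical percentage table and a gof table
#' (two-decimal percentages), plus the summary line.
#'
#' @param report A `vp_report`.
#' @return Character vector of Markdown lines.
#' @export
render_report <- function(report) {
  pv <- report$per_variable
  fmt <- function(x) ifelse(is.na(x), "-", sprintf("%.2f", x))
  lines <- c(
    sprintf("Kurtosis convention: %s", report$kurtosis_convention), "",
    "## Moments (real vs virtual)", "",
    paste("| variable | real mean | real SD | real skew | real kurt |",
          "virt mean | virt SD | virt skew | virt kurt |"),
    "|---|---|---|---|---|---|---|---|---|")
  for (v in pv)
    lines <- c(lines, sprintf("| %s | %s | %s | %s | %s | %s | %s | %s | %s |",
      v$variable, fmt(v$real$mean), fmt(v$real$sd), fmt(v$real$skewness),
      fmt(v$real$kurtosis), fmt(v$virtual$mean), fmt(v$virtual$sd),
      fmt(v$virtual$skewness), fmt(v$virtual$kurtosis)))
  ct <- report$categorical
  lines <- c(lines, "", "## Categorical percentages", "",
             "| variable | category | real % | virtual % |",
             "|---|---|---|---|")
  if (nrow(ct))
    lines <- c(lines, sprintf("| %s | %s | %.2f | %.2f |", ct$variable,
                              ct$category, ct$real_pct, ct$virtual_pct))
  lines <- c(lines, "", "## Goodness of fit", "",
             "| variable | gof |", "|---|---|",
             vapply(pv, function(v) sprintf("| %s | %.4f |", v$variable,
                                            v$gof), character(1)),
             "",
             sprintf("Mean gof %.4f +/- %.4f", report$summary$mean_gof,
                     report$summary$sd_gof))
  unname(lines)
}
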