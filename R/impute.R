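#' Euclidean norm of a latent vector
#'
#' The length (magnitude) of Z: `sqrt(sum(Z^2))`. This is the quantity the
#' imputation minimizes over all latent vectors consistent with the known
#' entries of a patient row.
#'
#' @param z Numeric vector.
#' @return Non-negative scalar.
#' @export
vector_norm <- function(z) sqrt(sum(z^2))

#' Recover the minimum-norm latent vector for a partially observed row
#'
#' A patient's log-space row satisfies `x' = mu + K Z`. When some entries of
#' `x'` are missing the system is underdetermined: infinitely many Z
#' reproduce the known entries. The imputation picks the Z of least
#' Euclidean norm, computed as the Moore-Penrose pseudoinverse solution of
#' the subsystem restricted to the known rows of K. When repaired zero
#' eigenvalues make that subsystem inconsistent, the same pseudoinverse
#' yields the least-squares solution of minimum norm; the residual then
#' flags the inconsistency.
#'
#' @param x_known Numeric p-vector in log (shifted) space with `NA` at
#'   missing positions.
#' @param model A `vp_model` of matching dimension.
#' @return List with `Z` (p-vector), `residual` (max abs reconstruction
#'   error at known entries), `norm` (`||Z||`).
#' @export
solve_latent <- function(x_known, model) {
  p <- length(model$mu)
  if (length(x_known) != p)
    stop("row length ", length(x_known), " does not match model dimension ",
         p, call. = FALSE)
  known <- which(!is.na(x_known))
  if (!length(known))
    stop("row has no known entries; nothing to condition on", call. = FALSE)
  A <- model$K[known, , drop = FALSE]
  b <- x_known[known] - model$mu[known]
  Z <- as.numeric(MASS::ginv(A) %*% b)
  residual <- max(abs(A %*% Z - b))
  list(Z = Z, residual = residual, norm = vector_norm(Z))
}

#' Impute missing cohort values by inverse sampling
#'
#' Fills every missing cell of the cohort by the inverse of the generation
#' equation: for each incomplete row the minimum-norm latent Z reproducing
#' the known log-space entries is recovered ([solve_latent()]), the full row
#' is reconstructed as `mu + K Z`, exponentiated, and positivity offsets are
#' removed. Missing categorical cells are discretized with the same midpoint
#' rule (same boundary-tie convention) as generation. Rows without missing
#' cells are untouched, so the procedure is idempotent.
#'
#' For a multivariate normal the minimum-norm reconstruction of the missing
#' block equals the conditional mean given the observed block, which is why
#' imputed values track strongly correlated covariates.
#'
#' @param cohort A `vp_cohort`, possibly with missing cells.
#' @param model A `vp_model` sharing the cohort's schema. Defaults to a
#'   pairwise-complete fit of the cohort itself
#'   (`vp_fit(cohort, use = "pairwise")`).
#' @param iterate If `TRUE`, refit the model on the imputed cohort and
#'   re-impute until the largest cell change is below `tol` (at most
#'   `max_rounds` rounds).
#' @param max_rounds,tol Iteration controls.
#' @return A `vp_imputation` with elements `cohort` (complete), `latents`
#'   (per-imputed-row Z), `residuals`, `norms`, `imputed_cells`
#'   (row/column coordinates), `rounds`.
#' @export
vp_impute <- function(cohort, model = NULL, iterate = FALSE,
                      max_rounds = 10L, tol = 1e-6) {
  stopifnot(inherits(cohort, "vp_cohort"))
  if (is.null(model)) model <- vp_fit(cohort, use = "pairwise")
  if (!identical(schema_names(model$schema), schema_names(cohort$schema)))
    stop("model and cohort schemas do not match", call. = FALSE)

  res <- impute_once(cohort, model)
  rounds <- 1L
  if (iterate) {
    repeat {
      if (rounds >= max_rounds) break
      model2 <- vp_fit(res$cohort)
      res2 <- impute_once(cohort, model2)
      delta <- max(abs(as.matrix(encode_cohort(res2$cohort)$values) -
                       as.matrix(encode_cohort(res$cohort)$values)))
      res <- res2
      rounds <- rounds + 1L
      if (delta < tol) break
    }
  }
  res$rounds <- rounds
  res
}

impute_once <- function(cohort, model) {
  lg <- log_transform(encode_cohort(cohort))
  x <- lg$values
  x[lg$mask] <- NA
  rows <- which(rowSums(lg$mask) > 0L)
  latents <- list()
  residuals <- numeric(0)
  norms <- numeric(0)
  cells <- NULL
  for (i in rows) {
    sol <- solve_latent(x[i, ], model)
    recon <- model$mu + as.numeric(model$K %*% sol$Z)
    miss <- which(lg$mask[i, ])
    x[i, miss] <- recon[miss]
    id <- cohort$ids[i]
    latents[[id]] <- sol$Z
    residuals[id] <- sol$residual
    norms[id] <- sol$norm
    cells <- rbind(cells, data.frame(row = i, id = id,
                                     variable = colnames(x)[miss]))
  }
  filled <- exp(x)
  # categorical cells: discretize with the midpoint rule before decoding
  for (v in model$schema)
    if (v$kind == "categorical") {
      j <- v$name
      m <- lg$mask[, j]
      if (any(m))
        filled[m, j] <- discretize(filled[m, j],
                                   seq_len(n_categories(v) - 1L) + 0.5)
    }
  out <- decode_cohort(filled, cohort$schema, ids = cohort$ids)
  structure(list(cohort = out, latents = latents, residuals = residuals,
                 norms = norms,
                 imputed_cells = cells %||%
                   data.frame(row = integer(0), id = character(0),
                              variable = character(0))),
            class = "vp_imputation")
}

#' @export
print.vp_imputation <- function(x, ...) {
  cat("Inverse-sampling imputation\n")
  cat("  rows imputed :", length(x$latents), "\n")
  cat("  cells filled :", nrow(x$imputed_cells), "\n")
  if (length(x$residuals))
    cat("  max residual :", format(max(x$residuals), digits = 3), "\n")
  if (!is.null(x$rounds)) cat("  rounds       :", x$rounds, "\n")
  invisible(x)
}

#' Write an imputation report to JSON
#'
#' Lists per-row latent norms, reconstruction residuals at known entries,
#' and the coordinates of every imputed cell.
#'
#' @param imputation A `vp_imputation`.
#' @param path Output path.
#' @export
write_imputation_report <- function(imputation, path) {
  out <- list(n_rows_imputed = length(imputation$latents),
              n_cells_imputed = nrow(imputation$imputed_cells),
              norms = as.list(imputation$norms),
              residuals = as.list(imputation$residuals),
              imputed_cells = imputation$imputed_cells)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
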