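#' Elementwise log-transform of an encoded matrix
#'
#' Takes the natural logarithm of every non-missing entry. All covariates are
#' modelled as log-normal, so sampling and fitting happen on this scale;
#' categorical codes start at 1 precisely so that this transform is defined.
#'
#' @param encoded List with `values` and `mask` as returned by
#'   [encode_cohort()], or a bare numeric matrix (no mask).
#' @return Same structure with `values` log-transformed; mask unchanged.
#' @export
log_transform <- function(encoded) {
  if (is.matrix(encoded)) encoded <- list(values = encoded,
                                          mask = is.na(encoded))
  v <- encoded$values
  bad <- which(!encoded$mask & v <= 0, arr.ind = TRUE)
  if (nrow(bad))
    stop("non-positive entry at row ", bad[1L, 1L], ", column ",
         colnames(v)[bad[1L, 2L]] %||% bad[1L, 2L],
         "; apply a positivity offset first", call. = FALSE)
  v[!encoded$mask] <- log(v[!encoded$mask])
  list(values = v, mask = encoded$mask)
}

#' Eigendecompose a covariance matrix with PSD repair
#'
#' Decomposes a symmetric covariance matrix as Sigma = U Lambda U'. Empirical
#' covariances of collinear covariates can carry tiny negative eigenvalues
#' from rounding; eigenvalues below `1e-12 * max(Lambda)` are clipped to 0 so
#' the square root in the sampling matrix is always defined.
#'
#' @param sigma Symmetric p x p matrix.
#' @param tol Asymmetry tolerance.
#' @return List with `U` (orthonormal eigenvectors, columns) and `Lambda`
#'   (non-negative eigenvalues, decreasing).
#' @export
decompose_covariance <- function(sigma, tol = 1e-10) {
  sigma <- as.matrix(sigma)
  if (nrow(sigma) != ncol(sigma) ||
      max(abs(sigma - t(sigma))) > tol * max(1, max(abs(sigma))))
    stop("sigma must be symmetric", call. = FALSE)
  e <- eigen((sigma + t(sigma)) / 2, symmetric = TRUE)
  lam <- e$values
  lam[lam < 1e-12 * max(lam, 0)] <- 0
  list(U = e$vectors, Lambda = lam)
}

#' Fit the joint multivariate log-normal model
#'
#' Encodes the cohort (categorical codes, positivity offsets), takes natural
#' logarithms, and estimates the log-space mean vector `mu` and covariance
#' matrix `sigma` (1/(n-1) normalization). `sigma` is decomposed as
#' U Lambda U' and the sampling matrix `K = U Lambda^(1/2)` is stored, so
#' that `mu + K %*% z` with standard-normal `z` has the fitted log-space
#' distribution.
#'
#' The cohort must be complete: impute missing values first (see
#' [vp_impute()]). With `use = "pairwise"` the moments are instead estimated
#' from pairwise-complete observations, which is how the model used *for*
#' imputation is obtained from an incomplete source.
#'
#' @param cohort A `vp_cohort`.
#' @param backend `"eigen"` (default; K = U Lambda^(1/2)) or `"cholesky"`
#'   (K = L with Sigma = L L'). Both satisfy K K' = Sigma, so the sampled
#'   distribution is identical.
#' @param mean_norm `"n"` (sample mean, default) or `"n-1"`, which divides
#'   the covariate sums by n-1 instead.
#' @param use `"complete"` (error on any missing cell) or `"pairwise"`
#'   (pairwise-complete moment estimates, for pre-imputation fitting).
#' @return A `vp_model` with elements `mu`, `sigma`, `U`, `Lambda`, `K`,
#'   `schema`, `n_source`, `backend`, `mean_norm`.
#' @export
vp_fit <- function(cohort, backend = c("eigen", "cholesky"),
                   mean_norm = c("n", "n-1"), use = c("complete", "pairwise")) {
  stopifnot(inherits(cohort, "vp_cohort"))
  backend <- match.arg(backend)
  mean_norm <- match.arg(mean_norm)
  use <- match.arg(use)
  n <- nrow(cohort$data)
  if (n < 2L) stop("need at least 2 patients to fit", call. = FALSE)

  lg <- log_transform(encode_cohort(cohort))
  x <- lg$values
  if (use == "complete") {
    if (any(lg$mask))
      stop("cohort has missing cells; impute first (vp_impute) or fit with ",
           "use = \"pairwise\"", call. = FALSE)
    mu <- colSums(x) / if (mean_norm == "n") n else n - 1L
    sigma <- stats::cov(x)
  } else {
    x[lg$mask] <- NA
    nobs <- colSums(!lg$mask)
    if (any(nobs < 2L))
      stop("column(s) with fewer than 2 observed values: ",
           paste(colnames(x)[nobs < 2L], collapse = ", "), call. = FALSE)
    mu <- colSums(x, na.rm = TRUE) / if (mean_norm == "n") nobs else nobs - 1L
    sigma <- stats::cov(x, use = "pairwise.complete.obs")
    sigma[is.na(sigma)] <- 0
    sigma <- (sigma + t(sigma)) / 2
  }

  dec <- decompose_covariance(sigma)
  K <- switch(backend,
    eigen = dec$U %*% diag(sqrt(dec$Lambda), length(dec$Lambda)),
    cholesky = {
      ch <- suppressWarnings(chol(sigma, pivot = TRUE))
      piv <- attr(ch, "pivot")
      t(ch[, order(piv), drop = FALSE])
    })
  dimnames(K) <- list(colnames(sigma), NULL)

  structure(list(mu = mu, sigma = sigma, U = dec$U, Lambda = dec$Lambda,
                 K = K, schema = cohort$schema, n_source = n,
                 backend = backend, mean_norm = mean_norm),
            class = "vp_model")
}

#' @export
print.vp_model <- function(x, ...) {
  cat("Joint multivariate log-normal model\n")
  cat("  covariates :", length(x$mu), "\n")
  cat("  fitted on  :", x$n_source, "patients\n")
  cat("  backend    :", x$backend,
      if (x$mean_norm != "n") sprintf("(mean norm 1/(n-1))") else "", "\n")
  cat("  rank(Sigma):", sum(x$Lambda > 0), "of", length(x$Lambda), "\n")
  invisible(x)
}

#' @export
summary.vp_model <- function(object, ...) {
  tab <- data.frame(variable = names(object$mu),
                    kind = schema_kinds(object$schema),
                    log_mean = unname(object$mu),
                    log_sd = sqrt(diag(object$sigma)),
                    row.names = NULL)
  out <- list(table = tab, n_source = object$n_source,
              rank = sum(object$Lambda > 0), p = length(object$mu))
  class(out) <- "summary.vp_model"
  out
}

#' @export
print.summary.vp_model <- function(x, ...) {
  cat("Joint multivariate log-normal model: ", x$p, " covariates, fitted on ",
      x$n_source, " patients (Sigma rank ", x$rank, ")\n\n", sep = "")
  print(x$table, digits = 4)
  invisible(x)
}

#' @export
coef.vp_model <- function(object, ...) object$mu

#' Serialize a fitted model to JSON
#'
#' @param model A `vp_model`.
#' @param path Output path.
#' @export
write_model <- function(model, path) {
  out <- list(mu = unname(model$mu), sigma = unname(model$sigma),
              U = unname(model$U), Lambda = model$Lambda,
              variables = names(model$mu),
              schema = lapply(model$schema, function(v) {
                x <- list(name = v$name, kind = v$kind)
                if (v$kind == "categorical") x$categories <- v$categories
                if ((v$positivity_offset %||% 0) != 0)
                  x$positivity_offset <- v$positivity_offset
                x
              }),
              n_source = model$n_source, backend = model$backend,
              mean_norm = model$mean_norm)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a serialized model from JSON
#'
#' @param path Path written by [write_model()].
#' @return A `vp_model`.
#' @export
read_model <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  schema <- vp_schema(lapply(raw$schema, function(v)
    vp_variable(v$name, v$kind,
                categories = if (!is.null(v$categories))
                  unlist(v$categories, use.names = FALSE),
                positivity_offset = v$positivity_offset %||% 0)))
  raw$variables <- unlist(raw$variables, use.names = FALSE)
  mu <- stats::setNames(unlist(raw$mu, use.names = FALSE), raw$variables)
  p <- length(mu)
  sigma <- do.call(rbind, lapply(raw$sigma, unlist, use.names = FALSE))
  raw$U <- do.call(rbind, lapply(raw$U, unlist, use.names = FALSE))
  raw$Lambda <- unlist(raw$Lambda, use.names = FALSE)
  dimnames(sigma) <- list(raw$variables, raw$variables)
  dec <- list(U = raw$U, Lambda = raw$Lambda)
  K <- dec$U %*% diag(sqrt(dec$Lambda), length(dec$Lambda))
  dimnames(K) <- list(raw$variables, NULL)
  structure(list(mu = mu, sigma = sigma, U = dec$U, Lambda = dec$Lambda,
                 K = K, schema = schema, n_source = raw$n_source,
                 backend = raw$backend, mean_norm = raw$mean_norm),
            class = "vp_model")
}
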