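#' Draw standard-normal latent vectors
#'
#' The only source of randomness in virtual-patient generation: `k`
#' independent p-dimensional standard-normal vectors, reproducible by seed.
#'
#' @param p Dimension.
#' @param k Number of vectors.
#' @param seed Integer seed.
#' @return p x k numeric matrix (one latent vector per column).
#' @export
sample_latent <- function(p, k, seed) {
  if (k < 0) stop("k must be >= 0", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  matrix(stats::rnorm(p * k), nrow = p, ncol = k)
}

#' Build a discretization rule for a categorical variable
#'
#' Simulated categorical covariates come back from the sampler as continuous
#' values and must be matched to integer codes at critical values (CrV). Two
#' rules are supported: `midpoint` places the boundary between codes j and
#' j+1 at (j + (j+1))/2 — the rule used after back-transforming from the
#' log scale, where code spacing is again linear; `lognormal_quantile`
#' places boundary i at `exp(mu + sigma * qnorm(P_i))` with `mu = mean(ln x)`,
#' `sigma = SD(ln x)` and `P_i` the cumulative empirical proportion of the
#' first i categories.
#'
#' @param variable Variable name (must be categorical in the schema).
#' @param cohort A `vp_cohort` supplying the empirical distribution.
#' @param method `"midpoint"` (default) or `"lognormal_quantile"`.
#' @return A `vp_rule` with `variable`, `method`, `boundaries` (k-1 strictly
#'   increasing critical values), `k`.
#' @export
build_rule <- function(variable, cohort, method = c("midpoint",
                                                    "lognormal_quantile")) {
  method <- match.arg(method)
  v <- cohort$schema[[variable]]
  if (is.null(v)) stop("unknown variable '", variable, "'", call. = FALSE)
  if (v$kind != "categorical")
    stop("'", variable, "' is continuous; discretization rules apply to ",
         "categorical variables", call. = FALSE)
  k <- n_categories(v)
  if (method == "midpoint") {
    boundaries <- seq_len(k - 1L) + 0.5
  } else {
    codes <- cohort$data[[variable]]
    codes <- codes[!is.na(codes)]
    counts <- tabulate(codes, nbins = k)
    if (any(counts == 0L))
      stop("category with zero observations in '", variable,
           "'; lognormal_quantile rule is degenerate", call. = FALSE)
    lx <- log(codes)
    mu <- mean(lx)
    sdl <- stats::sd(lx)
    cump <- cumsum(counts / sum(counts))[seq_len(k - 1L)]
    boundaries <- crv(mu, sdl, cump)
  }
  structure(list(variable = variable, method = method,
                 boundaries = boundaries, k = k), class = "vp_rule")
}

#' Critical value of a log-normal categorical covariate
#'
#' `CrV(mu, sigma, P) = exp(mu + sigma * qnorm(P))`: the log-normal quantile
#' at cumulative proportion P, used as the boundary between adjacent codes.
#'
#' @param mu Mean of log-values.
#' @param sigma SD of log-values.
#' @param p Cumulative proportion(s) in (0, 1).
#' @return Critical value(s).
#' @export
crv <- function(mu, sigma, p) exp(mu + sigma * stats::qnorm(p))

#' Discretize simulated continuous values to integer codes
#'
#' Returns code j for values in `[boundary_{j-1}, boundary_j)` with
#' `boundary_0 = -Inf`, `boundary_k = +Inf`; a value exactly at a boundary
#' goes to the upper code, and results are clamped to `1..k`. Total function:
#' never errors on finite input.
#'
#' @param values Numeric vector of simulated values.
#' @param rule A `vp_rule` from [build_rule()] (or a bare numeric vector of
#'   strictly increasing boundaries).
#' @return Integer codes in `1..k`.
#' @export
discretize <- function(values, rule) {
  boundaries <- if (inherits(rule, "vp_rule")) rule$boundaries else rule
  if (is.unsorted(boundaries, strictly = TRUE))
    stop("boundaries must be strictly increasing", call. = FALSE)
  as.integer(findInterval(values, boundaries) + 1L)
}

#' Generate a virtual cohort from a fitted model
#'
#' Samples `k` virtual patients: each log-space row is `mu + K %*% z` with a
#' fresh standard-normal latent `z` (so the log-space rows have exactly the
#' fitted mean and covariance in distribution), rows are exponentiated back
#' to the positive scale, positivity offsets are removed, and categorical
#' columns are discretized to integer codes via their rules (midpoint by
#' default). Every continuous output is strictly positive on the shifted
#' scale by construction — no rejection step is ever needed.
#'
#' @param model A `vp_model`.
#' @param k Number of virtual patients.
#' @param seed Integer seed (latent draws are the only randomness).
#' @param rules Optional named list of `vp_rule` overrides; defaults to
#'   midpoint rules for every categorical variable.
#' @return A `vp_cohort` of `k` virtual patients.
#' @export
vp_generate <- function(model, k, seed = 1L, rules = NULL) {
  stopifnot(inherits(model, "vp_model"))
  if (k < 0) stop("k must be >= 0", call. = FALSE)
  p <- length(model$mu)
  Z <- sample_latent(p, k, seed)
  logx <- t(model$mu + model$K %*% Z)   # k x p, log (shifted) scale
  x <- exp(logx)
  colnames(x) <- names(model$mu)
  rownames(x) <- sprintf("V%05d", seq_len(max(k, 0L)))

  kinds <- schema_kinds(model$schema)
  for (v in model$schema)
    if (v$kind == "categorical") {
      rule <- rules[[v$name]]
      if (is.null(rule))
        rule <- structure(list(variable = v$name, method = "midpoint",
                               boundaries = seq_len(n_categories(v) - 1L) + 0.5,
                               k = n_categories(v)), class = "vp_rule")
      codes <- discretize(x[, v$name], rule)
      x[, v$name] <- pmin(pmax(codes, 1L), rule$k)
    }
  decode_cohort(x, model$schema)
}

#' Simulate virtual patients from a fitted model
#'
#' `simulate()` method wrapping [vp_generate()].
#'
#' @param object A `vp_model`.
#' @param nsim Number of virtual patients.
#' @param seed Integer seed.
#' @param ... Passed to [vp_generate()] (e.g. `rules`).
#' @return A `vp_cohort`.
#' @export
simulate.vp_model <- function(object, nsim = 1, seed = 1L, ...) {
  vp_generate(object, k = nsim, seed = seed, ...)
}
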