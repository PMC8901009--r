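# Independent oracles used across the suite. Each reimplements the checked
# quantity by a different route (closed form, enumeration, brute force) and
# must stay independent of the package code paths it verifies.

# Eigenpairs of a symmetric 2x2 matrix via the characteristic polynomial.
eigen2_oracle <- function(s) {
  stopifnot(nrow(s) == 2, ncol(s) == 2)
  tr <- s[1, 1] + s[2, 2]
  det_ <- s[1, 1] * s[2, 2] - s[1, 2] * s[2, 1]
  disc <- sqrt(max(tr^2 / 4 - det_, 0))
  lam <- c(tr / 2 + disc, tr / 2 - disc)
  vecs <- sapply(lam, function(l) {
    if (abs(s[1, 2]) > 1e-14) v <- c(s[1, 2], l - s[1, 1])
    else if (abs(s[1, 1] - l) < abs(s[2, 2] - l)) v <- c(1, 0)
    else v <- c(0, 1)
    v / sqrt(sum(v^2))
  })
  list(values = lam, vectors = vecs)
}

# Two-sample ECDF sup-distance by direct evaluation at all pooled points.
ks_oracle <- function(a, b) {
  pts <- sort(unique(c(a, b)))
  Fa <- vapply(pts, function(t) mean(a <= t), numeric(1))
  Fb <- vapply(pts, function(t) mean(b <= t), numeric(1))
  max(abs(Fa - Fb))
}

# Least-norm latent by grid search (p = 2): among grid points satisfying
# the known constraints within tol, the smallest Euclidean norm.
grid_min_norm <- function(K, mu, x_known, step = 0.01, lim = 5, tol = 1e-3) {
  stopifnot(ncol(K) == 2)
  known <- which(!is.na(x_known))
  b <- x_known[known] - mu[known]
  A <- K[known, , drop = FALSE]
  g <- seq(-lim, lim, by = step)
  feasible <- matrix(TRUE, length(g), length(g))
  for (r in seq_len(nrow(A)))
    feasible <- feasible &
      abs(outer(A[r, 1] * g, A[r, 2] * g, `+`) - b[r]) <= tol
  if (!any(feasible)) return(Inf)
  norms <- sqrt(outer(g^2, g^2, `+`))
  min(norms[feasible])
}

# Linked-population size by brute-force enumeration of all (i, j, k) pairs.
brute_population_size <- function(A, B, C, config) {
  total <- nrow(C)
  for (k in seq_len(nrow(C))) {
    na <- 0
    for (i in seq_len(nrow(A)))
      if (matching_weight(A[i, ], C[k, ], config$fields_AC) >
          config$threshold_AC) na <- na + 1
    nb <- 0
    for (j in seq_len(nrow(B)))
      if (matching_weight(B[j, ], C[k, ], config$fields_BC) >
          config$threshold_BC) nb <- nb + 1
    total <- total + na * nb
  }
  total
}

# Small two-variable continuous truth with adjustable log-space correlation.
tiny_truth <- function(r = 0.9, sds = c(0.5, 0.4), mu = c(0, 1)) {
  nms <- c("x1", "x2")
  sigma <- diag(sds) %*% matrix(c(1, r, r, 1), 2) %*% diag(sds)
  dimnames(sigma) <- list(nms, nms)
  vp_truth(stats::setNames(mu, nms), sigma,
           vp_schema(vp_variable("x1"), vp_variable("x2")),
           cut_probs = list())
}

# Mixed 3-variable truth (2 continuous + 1 binary) for small end-to-end runs.
mixed_truth <- function(r = 0.6, prev_yes = 0.3) {
  nms <- c("x1", "x2", "flag")
  R <- matrix(c(1, r, 0.2,
                r, 1, 0.1,
                0.2, 0.1, 1), 3, byrow = TRUE)
  sds <- c(0.5, 0.3, 0.4)
  sigma <- diag(sds) %*% R %*% diag(sds)
  dimnames(sigma) <- list(nms, nms)
  vp_truth(stats::setNames(c(0.5, 1.2, log(1.5)), nms), sigma,
           vp_schema(vp_variable("x1"), vp_variable("x2"),
                     vp_variable("flag", "categorical",
                                 categories = c("No", "Yes"))),
           cut_probs = list(flag = c(1 - prev_yes, 1)))
}

# Toy linkage tables with overlapping band/label fields.
toy_linkage <- function(na = 3, nb = 3, nc = 2, seed = 1) {
  set.seed(seed)
  bands <- c("50s", "60s", "70s")
  sexes <- c("M", "F")
  vessels <- c("LAD", "LCX", "RCA")
  sten <- c("50-70", "70-90")
  list(
    A = data.frame(age_band = sample(bands, na, TRUE),
                   sex = sample(sexes, na, TRUE)),
    B = data.frame(sten_band = sample(sten, nb, TRUE),
                   vessel = sample(vessels, nb, TRUE)),
    C = data.frame(age_band = sample(bands, nc, TRUE),
                   sex = sample(sexes, nc, TRUE),
                   sten_band = sample(sten, nc, TRUE),
                   vessel = sample(vessels, nc, TRUE)))
}

default_config <- function(tac = 0, tbc = 0)
  vp_linkage_config(tac, tbc,
                    list(vp_field("age_band"), vp_field("sex")),
                    list(vp_field("sten_band"), vp_field("vessel")))
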