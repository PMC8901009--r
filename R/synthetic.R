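with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

#' Ground truth for a synthetic clinical cohort
#'
#' Bundles a known log-space mean vector and covariance matrix, the variable
#' schema, and per-categorical cumulative cut proportions, so cohorts with
#' fully known statistical structure can be drawn for testing.
#'
#' @param mu_true Named log-space mean vector.
#' @param sigma_true Log-space covariance matrix (symmetric PSD; repaired by
#'   eigenvalue clipping if marginally indefinite).
#' @param schema A `vp_schema` over the same variables.
#' @param cut_probs Named list: per categorical variable, the cumulative
#'   category proportions, strictly increasing and ending at 1.
#' @return A `vp_truth`.
#' @export
vp_truth <- function(mu_true, sigma_true, schema, cut_probs) {
  stopifnot(inherits(schema, "vp_schema"))
  nms <- schema_names(schema)
  stopifnot(identical(names(mu_true), nms),
            identical(colnames(sigma_true), nms))
  if (max(abs(sigma_true - t(sigma_true))) > 1e-8)
    stop("sigma_true must be symmetric", call. = FALSE)
  dec <- decompose_covariance(sigma_true)
  sigma_true <- dec$U %*% diag(dec$Lambda, length(dec$Lambda)) %*% t(dec$U)
  dimnames(sigma_true) <- list(nms, nms)
  for (nm in names(cut_probs)) {
    cp <- cut_probs[[nm]]
    if (is.unsorted(cp, strictly = TRUE) || abs(cp[length(cp)] - 1) > 1e-12)
      stop("cut_probs for '", nm, "' must be strictly increasing and end ",
           "at 1", call. = FALSE)
  }
  cat_vars <- nms[schema_kinds(schema) == "categorical"]
  if (!setequal(names(cut_probs), cat_vars))
    stop("cut_probs must cover exactly the categorical variables",
         call. = FALSE)
  structure(list(mu_true = mu_true, sigma_true = sigma_true,
                 schema = schema, cut_probs = cut_probs),
            class = "vp_truth")
}

#' Default SMARTool-like synthetic ground truth
#'
#' A 20-covariate preset emulating a coronary-artery-disease cohort of the
#' kind used to seed virtual populations: 10 positive continuous covariates
#' (age, BMI, lipid panel, glucose, creatinine, systolic pressure, CRP) with
#' field-typical means and coefficients of variation, and 10 binary risk
#' factors (male sex, family history, current/past smoking, diabetes,
#' dyslipidemia, hypertension, metabolic syndrome, obesity, statin use) at
#' prevalences matching a real 186-patient CAD cohort. Log-space
#' correlations encode standard clinical relationships (total cholesterol
#' with LDL, BMI with obesity, glucose with diabetes, pressure with
#' hypertension, ...); the matrix is projected to the nearest PSD
#' correlation matrix by eigenvalue clipping.
#'
#' @return A `vp_truth`.
#' @export
smartool_truth <- function() {
  cont <- data.frame(
    name = c("age_years", "bmi", "total_chol", "ldl", "hdl",
             "triglycerides", "glucose", "creatinine", "systolic_bp",
             "crp"),
    mean = c(63, 27.5, 185, 105, 47, 130, 105, 0.9, 132, 2.0),
    cv   = c(0.15, 0.15, 0.22, 0.30, 0.25, 0.45, 0.25, 0.20, 0.12, 0.80))
  cats <- data.frame(
    name = c("gender_male", "family_history", "smoking_current",
             "smoking_past", "diabetes", "dyslipidemia", "hypertension",
             "metabolic_syndrome", "obesity", "statins"),
    prev_yes = c(0.5699, 0.4892, 0.1290, 0.3871, 0.1452, 0.6935, 0.6129,
                 0.0054, 0.1774, 0.4570))

  sd_log_c <- sqrt(log(1 + cont$cv^2))
  mu_log_c <- log(cont$mean) - sd_log_c^2 / 2
  sd_log_b <- rep(0.4, nrow(cats))          # latent scale; cuts are quantiles
  mu_log_b <- rep(log(1.5), nrow(cats))

  nms <- c(cont$name, cats$name)
  mu <- stats::setNames(c(mu_log_c, mu_log_b), nms)
  sdv <- stats::setNames(c(sd_log_c, sd_log_b), nms)

  R <- diag(length(nms))
  dimnames(R) <- list(nms, nms)
  set_r <- function(a, b, r) {
    R[a, b] <<- r
    R[b, a] <<- r
  }
  set_r("total_chol", "ldl", 0.85)
  set_r("total_chol", "hdl", 0.15)
  set_r("total_chol", "triglycerides", 0.35)
  set_r("ldl", "triglycerides", 0.25)
  set_r("bmi", "triglycerides", 0.35)
  set_r("bmi", "glucose", 0.30)
  set_r("bmi", "systolic_bp", 0.25)
  set_r("bmi", "obesity", 0.75)
  set_r("bmi", "hdl", -0.25)
  set_r("bmi", "crp", 0.30)
  set_r("age_years", "systolic_bp", 0.30)
  set_r("age_years", "hypertension", 0.30)
  set_r("glucose", "diabetes", 0.65)
  set_r("glucose", "metabolic_syndrome", 0.30)
  set_r("systolic_bp", "hypertension", 0.55)
  set_r("total_chol", "dyslipidemia", 0.40)
  set_r("ldl", "dyslipidemia", 0.35)
  set_r("ldl", "statins", -0.30)
  set_r("dyslipidemia", "statins", 0.45)
  set_r("gender_male", "hdl", -0.30)
  set_r("smoking_current", "smoking_past", -0.45)

  e <- eigen((R + t(R)) / 2, symmetric = TRUE)
  lam <- pmax(e$values, 1e-8)
  R <- e$vectors %*% diag(lam) %*% t(e$vectors)
  R <- stats::cov2cor(R)
  dimnames(R) <- list(nms, nms)
  sigma <- diag(sdv) %*% R %*% diag(sdv)
  dimnames(sigma) <- list(nms, nms)

  schema <- vp_schema(c(
    lapply(cont$name, vp_variable, kind = "continuous"),
    lapply(cats$name, vp_variable, kind = "categorical",
           categories = c("No", "Yes"))))
  cut_probs <- stats::setNames(
    lapply(cats$prev_yes, function(p) c(1 - p, 1)), cats$name)
  vp_truth(mu, sigma, schema, cut_probs)
}

#' Draw a synthetic cohort from a ground truth
#'
#' Samples `n` rows from the multivariate normal `(mu_true, sigma_true)` in
#' log space, exponentiates, and cuts each categorical variable at the
#' log-normal quantiles implied by its cumulative cut proportions (so
#' category prevalences match the truth in expectation). Reproducible by
#' seed; no missing cells.
#'
#' @param truth A `vp_truth`.
#' @param n Number of patients (>= 1).
#' @param seed Integer seed.
#' @return A `vp_cohort`.
#' @export
make_cohort <- function(truth, n, seed = 1L) {
  stopifnot(inherits(truth, "vp_truth"))
  if (n < 1L) stop("n must be >= 1", call. = FALSE)
  nms <- names(truth$mu_true)
  p <- length(nms)
  dec <- decompose_covariance(truth$sigma_true)
  K <- dec$U %*% diag(sqrt(dec$Lambda), p)
  Z <- with_seed(seed, matrix(stats::rnorm(p * n), nrow = p))
  x <- exp(t(truth$mu_true + K %*% Z))
  colnames(x) <- nms
  sds <- sqrt(diag(truth$sigma_true))
  for (nm in names(truth$cut_probs)) {
    cp <- truth$cut_probs[[nm]]
    thr <- exp(truth$mu_true[nm] +
                 sds[nm] * stats::qnorm(cp[-length(cp)]))
    x[, nm] <- findInterval(x[, nm], thr) + 1L
  }
  df <- as.data.frame(x)
  vp_cohort(df, truth$schema, ids = sprintf("S%04d", seq_len(n)))
}

#' Inject missing cells completely at random
#'
#' Masks each cell independently with probability `rate` (MCAR). Rows that
#' would lose every cell have their mask redrawn, so at least one cell per
#' row always stays observed. The hidden true values are returned for
#' scoring imputation.
#'
#' @param cohort A complete `vp_cohort`.
#' @param rate Missingness probability in [0, 1).
#' @param seed Integer seed.
#' @return List with `cohort` (masked) and `truth` (data.frame `row`,
#'   `variable`, `true_value` — codes for categorical cells).
#' @export
inject_missing <- function(cohort, rate, seed = 1L) {
  stopifnot(inherits(cohort, "vp_cohort"))
  if (rate < 0 || rate >= 1)
    stop("rate must be in [0, 1)", call. = FALSE)
  n <- nrow(cohort$data)
  p <- ncol(cohort$data)
  mask <- with_seed(seed, {
    m <- matrix(stats::runif(n * p) < rate, n, p)
    full <- which(rowSums(m) == p)
    while (length(full)) {
      m[full, ] <- matrix(stats::runif(length(full) * p) < rate,
                          length(full), p)
      full <- full[rowSums(m[full, , drop = FALSE]) == p]
    }
    m
  })
  df <- cohort$data
  hidden <- NULL
  for (j in seq_len(p)) {
    rows <- which(mask[, j])
    if (!length(rows)) next
    hidden <- rbind(hidden, data.frame(
      row = rows, variable = names(df)[j],
      true_value = as.numeric(df[rows, j])))
    df[rows, j] <- NA
  }
  list(cohort = vp_cohort(df, cohort$schema, ids = cohort$ids),
       truth = hidden %||% data.frame(row = integer(0),
                                      variable = character(0),
                                      true_value = numeric(0)))
}

#' Simulate an arterial geometry-feature table
#'
#' Emits one row per (patient, time point) with a monotone stenosis
#' progression: each patient follows a saturating growth curve from a
#' baseline stenosis to a final value above 50% (the population filter for
#' stent-trial use), with small noise that never breaks monotonicity.
#' This is an explicit synthetic stand-in for the outputs of a mechanistic
#' plaque-growth simulation, not a model of one.
#'
#' @param patient_ids Character vector of patient ids.
#' @param time_points Numeric vector of years (non-empty, increasing).
#' @param seed Integer seed.
#' @return data.frame with columns `patient_id`, `geometry_id`,
#'   `time_point_years`, `stenosis_pct`, `vessel_label`,
#'   `plaque_burden_pct`.
#' @export
make_geometry_table <- function(patient_ids, time_points, seed = 1L) {
  if (!length(patient_ids)) stop("patient_ids must be non-empty",
                                 call. = FALSE)
  if (!length(time_points)) stop("time_points must be non-empty",
                                 call. = FALSE)
  time_points <- sort(as.numeric(time_points))
  tmax <- max(time_points)
  with_seed(seed, {
    rows <- lapply(patient_ids, function(pid) {
      final <- stats::runif(1, 51, 95)
      base <- stats::runif(1, 10, min(40, final - 5))
      tau <- stats::runif(1, 1.5, 4)
      frac <- (1 - exp(-time_points / tau)) / (1 - exp(-tmax / tau))
      s <- base + (final - base) * frac
      noise <- stats::rnorm(length(s), 0, 0.8)
      noise[length(s)] <- 0                     # final value stays > 50
      s <- pmin(pmax(cummax(s + noise), base), final)
      vessel <- sample(c("LAD", "LCX", "RCA"), 1)
      data.frame(patient_id = pid,
                 geometry_id = sprintf("%s-T%02d", pid,
                                       seq_along(time_points)),
                 time_point_years = time_points,
                 stenosis_pct = s,
                 vessel_label = vessel,
                 plaque_burden_pct = pmax(0.6 * s +
                                            stats::rnorm(length(s), 0, 2), 1),
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}
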