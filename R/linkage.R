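#' Define a compared field for record linkage
#'
#' @param field Column name present in both tables being compared.
#' @param comparator `"exact"` (categorical equality) or `"numeric"`
#'   (agreement when `|a - c| <= tolerance`).
#' @param agreement_weight Weight added when the field agrees (must exceed
#'   `disagreement_weight`).
#' @param disagreement_weight Weight added when the field disagrees.
#' @param tolerance Numeric tolerance (numeric comparator only, >= 0).
#' @return A `vp_field` list.
#' @export
vp_field <- function(field, comparator = c("exact", "numeric"),
                     agreement_weight = 1, disagreement_weight = -1,
                     tolerance = 0) {
  comparator <- match.arg(comparator)
  if (agreement_weight <= disagreement_weight)
    stop("agreement_weight must exceed disagreement_weight for '", field,
         "'", call. = FALSE)
  if (tolerance < 0) stop("tolerance must be >= 0", call. = FALSE)
  structure(list(field = field, comparator = comparator,
                 agreement_weight = agreement_weight,
                 disagreement_weight = disagreement_weight,
                 tolerance = tolerance), class = "vp_field")
}

#' Linkage configuration
#'
#' Holds the matching thresholds and the compared-field lists for linking
#' the clinical-only dataset A and the geometry-only dataset B to the bridge
#' dataset C, which carries both kinds of features. Candidate pairs are
#' those whose additive matching weight is strictly above the threshold.
#'
#' @param threshold_AC,threshold_BC Matching-weight thresholds.
#' @param fields_AC,fields_BC Lists of [vp_field()] entries.
#' @return A `vp_linkage_config`.
#' @export
vp_linkage_config <- function(threshold_AC, threshold_BC,
                              fields_AC, fields_BC) {
  check <- function(fs, nm) {
    if (!length(fs)) stop("empty compared-field list ", nm, call. = FALSE)
    ok <- vapply(fs, inherits, logical(1), "vp_field")
    if (!all(ok)) stop(nm, " must be a list of vp_field entries",
                       call. = FALSE)
    fs
  }
  structure(list(threshold_AC = threshold_AC, threshold_BC = threshold_BC,
                 fields_AC = check(fields_AC, "fields_AC"),
                 fields_BC = check(fields_BC, "fields_BC")),
            class = "vp_linkage_config")
}

#' Read a linkage configuration from JSON
#'
#' Expects `{"threshold_AC":..., "threshold_BC":..., "fields_AC":[{"field":
#' ..., "comparator":..., "agreement_weight":..., "disagreement_weight":...,
#' "tolerance":...}, ...], "fields_BC":[...]}`.
#'
#' @param path Path to the JSON file.
#' @return A `vp_linkage_config`.
#' @export
read_linkage_config <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  parse_fields <- function(fs) lapply(fs, function(f)
    vp_field(f$field, f$comparator %||% "exact",
             agreement_weight = f$agreement_weight %||% 1,
             disagreement_weight = f$disagreement_weight %||% -1,
             tolerance = f$tolerance %||% 0))
  vp_linkage_config(raw$threshold_AC, raw$threshold_BC,
                    parse_fields(raw$fields_AC), parse_fields(raw$fields_BC))
}

#' Additive matching weight between two records
#'
#' Sums, over the compared fields, the agreement weight when the comparator
#' says the records agree and the disagreement weight otherwise. A field
#' missing (`NA`) in either record contributes 0. This is the
#' Fellegi-Sunter-style scalar weight the candidate thresholds act on.
#'
#' @param record_a,record_c Named lists or one-row data.frames.
#' @param fields List of [vp_field()] entries.
#' @return Scalar weight.
#' @export
matching_weight <- function(record_a, record_c, fields) {
  w <- 0
  for (f in fields) {
    a <- record_a[[f$field]]
    c_ <- record_c[[f$field]]
    if (is.null(a) || is.null(c_) || is.na(a) || is.na(c_)) next
    agree <- if (f$comparator == "numeric")
      abs(as.numeric(a) - as.numeric(c_)) <= f$tolerance
    else a == c_
    w <- w + if (agree) f$agreement_weight else f$disagreement_weight
  }
  w
}

#' Derive agreement/disagreement weights from labeled match statistics
#'
#' Given the probability `m` that a field agrees among true matches and `u`
#' that it agrees among non-matches, the classical log2 composite weights are
#' `log2(m/u)` for agreement and `log2((1-m)/(1-u))` for disagreement.
#'
#' @param m,u Agreement probabilities among matches / non-matches, in (0,1).
#' @return Named vector `c(agreement, disagreement)`.
#' @export
fs_weights <- function(m, u) {
  stopifnot(m > 0, m < 1, u > 0, u < 1)
  c(agreement = log2(m / u), disagreement = log2((1 - m) / (1 - u)))
}

weight_matrix <- function(X, C, fields) {
  nx <- nrow(X); nc <- nrow(C)
  for (f in fields)
    if (!f$field %in% names(X) || !f$field %in% names(C))
      stop("compared field '", f$field, "' absent from a table",
           call. = FALSE)
  w <- matrix(0, nx, nc)
  for (f in fields) {
    a <- X[[f$field]]
    b <- C[[f$field]]
    if (f$comparator == "numeric") {
      agree <- abs(outer(as.numeric(a), as.numeric(b), `-`)) <= f$tolerance
    } else {
      agree <- outer(as.character(a), as.character(b), `==`)
    }
    contrib <- ifelse(agree, f$agreement_weight, f$disagreement_weight)
    contrib[is.na(contrib)] <- 0
    w <- w + contrib
  }
  w
}

#' Build per-bridge-record candidate sets
#'
#' For every bridge record `c_k`, computes the weight of each A record and
#' each B record against it and keeps those strictly above the respective
#' threshold: `V_AC^k = {i : w_AC[i,k] > threshold_AC}` and likewise
#' `V_BC^k`. Ties at the threshold are excluded.
#'
#' @param A Clinical table (data.frame or `vp_cohort`).
#' @param B Geometry table (data.frame).
#' @param C Bridge table (data.frame carrying both kinds of fields).
#' @param config A `vp_linkage_config`.
#' @return A `vp_candidates` with weight matrices `w_AC` (|A| x |C|), `w_BC`
#'   (|B| x |C|) and index lists `V_AC`, `V_BC` (one integer vector per
#'   bridge record).
#' @export
build_candidate_sets <- function(A, B, C, config) {
  if (inherits(A, "vp_cohort")) A <- cohort_frame(A)
  stopifnot(is.data.frame(A), is.data.frame(B), is.data.frame(C),
            inherits(config, "vp_linkage_config"))
  w_AC <- weight_matrix(A, C, config$fields_AC)
  w_BC <- weight_matrix(B, C, config$fields_BC)
  V_AC <- lapply(seq_len(nrow(C)), function(k)
    which(w_AC[, k] > config$threshold_AC))
  V_BC <- lapply(seq_len(nrow(C)), function(k)
    which(w_BC[, k] > config$threshold_BC))
  structure(list(w_AC = w_AC, w_BC = w_BC, V_AC = V_AC, V_BC = V_BC),
            class = "vp_candidates")
}

cohort_frame <- function(cohort) {
  df <- cohort$data
  for (v in cohort$schema)
    if (v$kind == "categorical")
      df[[v$name]] <- v$categories[df[[v$name]]]
  cbind(patient_id = cohort$ids, df, stringsAsFactors = FALSE)
}

#' Assemble the final virtual population
#'
#' The population consists of the de-identified bridge records themselves
#' (provenance `"bridge"`) plus, for every bridge record `c_k`, all
#' combinations of its clinical candidates and geometry candidates — the
#' Cartesian product `V_AC^k x V_BC^k` — as new linked patients (provenance
#' `"linked"`). Its size is therefore
#' `|C| + sum_k |V_AC^k| * |V_BC^k|`. A record of A (or B) belonging to
#' several candidate sets appears in several combined records.
#'
#' @param A Clinical table (data.frame or `vp_cohort`).
#' @param B Geometry table.
#' @param C Bridge table.
#' @param config A `vp_linkage_config`.
#' @return A `vp_population`: list with `records` (data.frame of combined
#'   entries: re-keyed id, provenance, source indices, clinical fields from
#'   A or C, geometry fields from B or C), `counts` (per provenance) and
#'   the `candidates` object.
#' @export
vp_link <- function(A, B, C, config) {
  if (inherits(A, "vp_cohort")) A <- cohort_frame(A)
  cand <- build_candidate_sets(A, B, C, config)
  clin_cols <- names(A)
  geom_cols <- names(B)

  rec_bridge <- data.frame(vp_id = sprintf("VP-B%05d", seq_len(nrow(C))),
                           provenance = "bridge",
                           a_index = NA_integer_, b_index = NA_integer_,
                           c_index = seq_len(nrow(C)),
                           stringsAsFactors = FALSE)
  pairs <- do.call(rbind, lapply(seq_len(nrow(C)), function(k) {
    va <- cand$V_AC[[k]]; vb <- cand$V_BC[[k]]
    if (!length(va) || !length(vb)) return(NULL)
    expand.grid(a_index = va, b_index = vb, c_index = k,
                KEEP.OUT.ATTRS = FALSE)
  }))
  if (is.null(pairs))
    pairs <- data.frame(a_index = integer(0), b_index = integer(0),
                        c_index = integer(0))
  rec_linked <- data.frame(
    vp_id = sprintf("VP-L%06d", seq_len(nrow(pairs))),
    provenance = rep("linked", nrow(pairs)),
    pairs, stringsAsFactors = FALSE)

  meta <- rbind(rec_bridge, rec_linked)
  # bridge rows carry their own C payload; linked rows take clinical fields
  # unchanged from A and geometry fields unchanged from B
  clin_payload <- rbind(
    pad_frame(C[rec_bridge$c_index, , drop = FALSE], clin_cols),
    pad_frame(A[rec_linked$a_index, , drop = FALSE], clin_cols))
  geom_payload <- rbind(
    pad_frame(C[rec_bridge$c_index, , drop = FALSE], geom_cols),
    pad_frame(B[rec_linked$b_index, , drop = FALSE], geom_cols))
  names(clin_payload) <- paste0("clin_", clin_cols)
  names(geom_payload) <- paste0("geom_", geom_cols)
  records <- cbind(meta, clin_payload, geom_payload)
  rownames(records) <- NULL

  structure(list(records = records,
                 counts = c(bridge = nrow(C), linked = nrow(pairs)),
                 candidates = cand, config = config),
            class = "vp_population")
}

pad_frame <- function(df, cols) {
  out <- df[intersect(cols, names(df))]
  for (m in setdiff(cols, names(df))) out[[m]] <- NA
  out[cols]
}

#' @export
print.vp_population <- function(x, ...) {
  cat("Virtual population:", nrow(x$records), "records\n")
  cat("  bridge (pass-through C):", x$counts[["bridge"]], "\n")
  cat("  linked (V_AC x V_BC)   :", x$counts[["linked"]], "\n")
  invisible(x)
}
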