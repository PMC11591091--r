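#' Three-class HbA1c-change label
#'
#' Compares the second examination's HbA1c with the first: `|delta| <=
#' epsilon` is class 0 (no change), `delta > epsilon` class 1 (increased),
#' `delta < -epsilon` class 2 (decreased), with `delta = exam2 - exam1` in
#' percentage points. The default `epsilon = 0` treats only exact ties as
#' "no change"; a clinical tolerance can be supplied.
#'
#' @param hba1c_exam1,hba1c_exam2 HbA1c values (%), both `> 0`; vectorized.
#' @param epsilon no-change tolerance in percentage points (default 0).
#' @return list with `class` (integer 0/1/2) and `delta`.
#' @export
label_change <- function(hba1c_exam1, hba1c_exam2, epsilon = 0) {
  if (anyNA(hba1c_exam1) || anyNA(hba1c_exam2) ||
      any(hba1c_exam1 <= 0) || any(hba1c_exam2 <= 0))
    dk_stop("dk_input_error", "HbA1c measurements must be positive and non-missing")
  if (epsilon < 0) dk_stop("dk_input_error", "epsilon must be >= 0")
  delta <- hba1c_exam2 - hba1c_exam1
  cls <- ifelse(abs(delta) <= epsilon, 0L, ifelse(delta > epsilon, 1L, 2L))
  list(class = cls, delta = delta)
}

#' Assemble the predictor matrix and labels from a cohort
#'
#' Selects the 111 predictor features by schema category tag — 6 personal,
#' 10 lifestyle, 79 nutrient and the 16 first-examination medical features,
#' in that column order — and derives the three-class HbA1c-change target
#' from the two exam columns. The entire second-examination block is dropped
#' (selection is driven by tags, never by column positions). Categorical
#' answers are integer-encoded by their declared codebook level order. If the
#' cohort carries a precomputed `hba1c_change` column it takes precedence
#' over recomputation.
#'
#' @param cohort cohort data frame with a `schema` attribute (see
#'   [load_cohort()] / [simulate_cohort()]).
#' @param epsilon no-change tolerance passed to [label_change()].
#' @return list with `X` (samples x 111 numeric matrix), `y` (factor with
#'   levels 0/1/2), `features` (schema rows used, in column order).
#' @export
assemble_predictors <- function(cohort, epsilon = 0) {
  schema <- attr(cohort, "schema") %||% diabmini_schema()
  audit_schema(schema)
  if (!all(c("hba1c_exam1", "hba1c_exam2") %in% names(cohort)))
    dk_stop("dk_schema_error", "cohort must contain hba1c_exam1 and hba1c_exam2")
  miss <- is.na(cohort$hba1c_exam1) | is.na(cohort$hba1c_exam2)
  if (any(miss)) {
    ids <- if ("sample_id" %in% names(cohort)) cohort$sample_id[miss] else which(miss)
    dk_stop("dk_input_error", "missing HbA1c in sample(s): %s",
            paste(ids, collapse = ", "))
  }
  order_cats <- c("personal", "lifestyle", "nutrient", "medical_exam1")
  feat <- do.call(rbind, lapply(order_cats, function(cc)
    schema[schema$category == cc, , drop = FALSE]))
  stopifnot(nrow(feat) == 111)
  cb <- dk_codebooks()
  X <- matrix(NA_real_, nrow(cohort), nrow(feat),
              dimnames = list(NULL, feat$name))
  for (i in seq_len(nrow(feat))) {
    v <- cohort[[feat$name[i]]]
    if (feat$type[i] == "categorical" && !is.numeric(v)) {
      levels <- cb[[feat$name[i]]]
      code <- match(v, levels)
      if (any(is.na(code) & !is.na(v)))
        dk_stop("dk_input_error", "feature '%s': answer outside the codebook",
                feat$name[i])
      v <- code
    }
    X[, i] <- as.numeric(v)
  }
  if ("hba1c_change" %in% names(cohort)) {
    y <- as.integer(cohort$hba1c_change)
  } else {
    y <- label_change(cohort$hba1c_exam1, cohort$hba1c_exam2, epsilon)$class
  }
  list(X = X, y = factor(y, levels = 0:2), features = feat)
}

# median (numeric) imputer fitted on training rows only; categorical columns
# are already integer codes, imputed with the mode
fit_imputer <- function(X) {
  vals <- apply(X, 2, function(v) {
    v <- v[!is.na(v)]
    if (length(v) == 0) return(0)
    stats::median(v)
  })
  list(values = vals)
}

apply_imputer <- function(imp, X) {
  for (j in seq_len(ncol(X))) {
    nas <- is.na(X[, j])
    if (any(nas)) X[nas, j] <- imp$values[j]
  }
  X
}
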