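#' Cohort simulation specification
#'
#' Defines the synthetic cohort's size, class mix and planted feature
#' effects. Defaults emulate the study conditions: 88 participants with the
#' 21:15:52 class imbalance (no change : increased : decreased HbA1c) and
#' moderate planted effects on the features the attribution analysis
#' highlights (age, selenium intake, baseline HDL, baseline HbA1c, baseline
#' triglycerides, waist-to-hip ratio).
#'
#' @param n cohort size (default 88).
#' @param proportions three class counts or weights for classes 0/1/2
#'   (default `c(21, 15, 52)`); scaled to `n` by largest remainder if they do
#'   not already sum to `n`.
#' @param effects data frame with columns `feature`, `class` (0/1/2) and
#'   `size` (shift in within-cohort sd units applied to samples of that
#'   class; sign carries direction), or `NULL` for the default effect list.
#'   Numeric features only.
#' @param seed integer seed.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n = 88, proportions = c(21, 15, 52), effects = NULL,
                        seed = 1) {
  if (length(proportions) != 3 || any(proportions < 0) || sum(proportions) <= 0)
    dk_stop("dk_spec_error", "proportions must be three non-negative weights")
  counts <- if (sum(proportions) == n) as.integer(proportions)
            else largest_remainder(proportions, n)
  if (sum(counts) != n || any(counts < 0))
    dk_stop("dk_spec_error", "infeasible class proportions for n = %d", n)
  if (is.null(effects)) effects <- default_effects()
  schema <- diabmini_schema()
  bad <- setdiff(effects$feature, schema$name)
  if (length(bad) > 0)
    dk_stop("dk_spec_error", "planted feature(s) not in the schema: %s",
            paste(bad, collapse = ", "))
  structure(list(n = n, counts = counts, effects = effects, seed = seed),
            class = "cohort_spec")
}

largest_remainder <- function(w, n) {
  q <- w / sum(w) * n
  base <- floor(q)
  extra <- order(q - base, decreasing = TRUE)[seq_len(n - sum(base))]
  base[extra] <- base[extra] + 1
  as.integer(base)
}

# default planted effects: directions follow the attribution findings
# (older age -> stable; lower Se and lower baseline HbA1c -> increase;
# higher baseline HDL -> increase; higher baseline TG -> decrease;
# lower WHR -> stable)
default_effects <- function() {
  data.frame(feature = c("age", "whr_exam1", "se", "hba1c_exam1",
                         "hdl_exam1", "tg_exam1"),
             class = c(0, 0, 1, 1, 1, 2),
             size = c(0.8, -0.8, -0.8, -0.8, 0.8, 0.8))
}

#' Simulate a DiabMini-schema cohort
#'
#' Generates a 127-column cohort: personal and baseline medical features from
#' plausible clinical marginals, second-exam medical values as first-exam
#' values plus class-dependent drift and noise (HbA1c deltas are constructed
#' so that [label_change()] with `epsilon = 0` reproduces the specified class
#' counts exactly), lifestyle categoricals allocated by fixed codebook
#' proportions (69/88 of samples answer "Never or rarely" for weekly
#' drinking), and a 79-nutrient block drawn from a log-normal family with a
#' low-rank (food-group factor) correlation structure. Planted effects shift
#' the named numeric features by the stated size in sd units within the
#' driven class. Deterministic given the spec's seed.
#'
#' @param spec a [cohort_spec()].
#' @return data frame of `n` rows and 128 columns (`sample_id` + 127
#'   features) with attribute `schema`; lifestyle and gender columns are
#'   character levels from [dk_codebooks()].
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n
  schema <- diabmini_schema()
  set.seed(dk_child_seed(spec$seed, "cohort"))
  y <- sample(rep(0:2, spec$counts))

  cb <- dk_codebooks()
  out <- data.frame(sample_id = sprintf("S%03d", seq_len(n)))

  # personal
  gender <- alloc_levels(cb$gender, c(0.55, 0.45), n)
  age <- round(pmin(pmax(stats::rnorm(n, 56, 10), 28), 82))
  height <- round(stats::rnorm(n, ifelse(gender == "Male", 171, 160), 6), 1)
  weight <- round(stats::rnorm(n, ifelse(gender == "Male", 74, 63), 9), 1)
  bmi <- round(weight / (height / 100)^2, 1)
  bfp <- round(pmin(pmax(stats::rnorm(n, ifelse(gender == "Male", 24, 31), 5), 8), 45), 1)
  out$gender <- gender; out$age <- age; out$height <- height
  out$weight <- weight; out$bmi <- bmi; out$bfp <- bfp

  # medical exam 1
  med1 <- list(
    hba1c = round(pmin(pmax(stats::rnorm(n, 7.6, 1.2), 5.6), 12), 1),
    fbg = round(pmin(pmax(stats::rnorm(n, 8.2, 1.8), 4.5), 15), 1),
    tc = round(stats::rnorm(n, 4.9, 0.9), 2),
    tg = round(pmax(stats::rlnorm(n, log(1.7), 0.4), 0.4), 2),
    hdl = round(pmax(stats::rnorm(n, 1.2, 0.25), 0.5), 2),
    ldl = round(pmax(stats::rnorm(n, 2.9, 0.7), 0.8), 2),
    whr = round(pmin(pmax(stats::rnorm(n, 0.92, 0.06), 0.7), 1.15), 2),
    sbp = round(stats::rnorm(n, 132, 14)),
    dbp = round(stats::rnorm(n, 82, 9)),
    alt = round(pmax(stats::rlnorm(n, log(24), 0.4), 5)),
    ast = round(pmax(stats::rlnorm(n, log(22), 0.35), 5)),
    creatinine = round(stats::rnorm(n, 70, 14)),
    uric_acid = round(stats::rnorm(n, 340, 70)),
    hemoglobin = round(stats::rnorm(n, 142, 13)),
    wbc = round(pmax(stats::rnorm(n, 6.4, 1.4), 2.5), 1),
    body_fat_mass = round(pmax(weight * bfp / 100 + stats::rnorm(n, 0, 1), 4), 1))

  # HbA1c deltas constructed per class so epsilon = 0 labels are exact
  delta <- numeric(n)
  delta[y == 1] <- round(stats::runif(sum(y == 1), 0.3, 1.3), 1)
  delta[y == 2] <- -round(stats::runif(sum(y == 2), 0.3, 1.3), 1)
  delta[y == 1] <- pmax(delta[y == 1], 0.1)
  delta[y == 2] <- pmin(delta[y == 2], -0.1)

  for (m in names(med1)) out[[paste0(m, "_exam1")]] <- med1[[m]]
  for (m in names(med1)) {
    if (m == "hba1c") {
      e2 <- med1$hba1c
      ch <- y != 0
      e2[ch] <- round(med1$hba1c[ch] + delta[ch], 1)
      out$hba1c_exam2 <- e2
    } else {
      drift <- stats::rnorm(n, 0, stats::sd(med1[[m]]) * 0.12)
      out[[paste0(m, "_exam2")]] <- round(med1[[m]] + drift, 2)
    }
  }

  # lifestyle: deterministic level counts (shuffled assignment)
  props <- list(
    exercise_weekly = c(0.35, 0.30, 0.25, 0.10),
    drinking_weekly = c(69 / 88, 0.10, 0.07, 0.05),
    smoking = c(0.6, 0.2, 0.2),
    sleep_duration = c(0.25, 0.6, 0.15),
    staying_up_late = c(0.5, 0.35, 0.15),
    diet_regularity = c(0.7, 0.3),
    food_selection = c(0.4, 0.3, 0.3),
    stress_level = c(0.35, 0.45, 0.2),
    snack_freq = c(0.45, 0.4, 0.15),
    sedentary_hours = c(0.3, 0.5, 0.2))
  for (f in names(props)) out[[f]] <- alloc_levels(cb[[f]], props[[f]], n)

  # nutrient block: log-normal with low-rank food-group factor structure
  nn <- nutrient_names()
  p_nut <- length(nn)
  q <- 6
  set.seed(dk_child_seed(spec$seed, "loadings"))
  L <- matrix(stats::runif(p_nut * q, -0.1, 0.1), p_nut, q)
  grp <- (seq_len(p_nut) - 1) %% q + 1
  L[cbind(seq_len(p_nut), grp)] <- 0.6      # each nutrient loads on one group
  h2 <- rowSums(L^2)
  set.seed(dk_child_seed(spec$seed, "nutrients"))
  f <- matrix(stats::rnorm(n * q), n, q)
  eps <- matrix(stats::rnorm(n * p_nut), n, p_nut)
  z <- f %*% t(L) + eps %*% diag(sqrt(pmax(1 - h2, 0.05)))
  mu_log <- log(nutrient_scale())
  for (j in seq_len(p_nut)) {
    zj <- z[, j]
    ef <- spec$effects[spec$effects$feature == nn[j], , drop = FALSE]
    for (r in seq_len(nrow(ef)))
      zj[y == ef$class[r]] <- zj[y == ef$class[r]] + ef$size[r]
    out[[nn[j]]] <- round(exp(mu_log[j] + 0.25 * zj), 3)
  }

  # planted effects on numeric personal/medical features
  non_nut <- spec$effects[!(spec$effects$feature %in% nn), , drop = FALSE]
  for (r in seq_len(nrow(non_nut))) {
    f_name <- non_nut$feature[r]
    if (!is.numeric(out[[f_name]]))
      dk_stop("dk_spec_error", "planted effects require numeric features: %s", f_name)
    out[[f_name]][y == non_nut$class[r]] <-
      out[[f_name]][y == non_nut$class[r]] +
      non_nut$size[r] * stats::sd(out[[f_name]])
  }

  out <- out[, c("sample_id", schema$name)]
  attr(out, "schema") <- schema
  attr(out, "classes") <- y
  out
}

# typical daily-intake scale per nutrient (unit-consistent with the schema)
nutrient_scale <- function() {
  nm <- nutrient_names()
  s <- rep(5, length(nm))
  big <- c(energy = 1900, protein = 75, fat = 65, carbohydrate = 250,
           dietary_fiber = 15, water = 1200, cholesterol = 300, ash = 15,
           sugar = 40, starch = 180, fructose = 10, glucose = 10,
           sucrose = 20, lactose = 5, maltose = 2, galactose = 0.5,
           insoluble_fiber = 8, trans_fat = 0.5, vitamin_c = 90,
           ca = 600, p = 950, k_mineral = 1900, na = 3500, mg = 300,
           fe = 20, zn = 11, se = 45, cu = 1.8, mn = 4.5, iodine = 110,
           cr = 30, mo = 90, vitamin_a = 450, carotene = 2500, retinol = 300,
           folate = 250, choline = 350, biotin = 28, pantothenic_acid = 4.5)
  s[match(names(big), nm)] <- unname(big)
  stats::setNames(s, nm)
}

# deterministic level allocation: exact largest-remainder counts, shuffled
alloc_levels <- function(levels, prop, n) {
  counts <- largest_remainder(prop, n)
  sample(rep(levels, counts))
}

#' Write a cohort fixture (CSV + schema sidecar)
#'
#' Emits `cohort.csv` and `schema.yaml` consumable by [load_cohort()]
#' unchanged. The sidecar lists every feature's name, category tag, unit,
#' type and (for categoricals) codebook levels.
#'
#' @param cohort output of [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @return invisibly the two file paths.
#' @export
write_cohort_fixture <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  csv <- file.path(dir, "cohort.csv")
  yml <- file.path(dir, "schema.yaml")
  utils::write.csv(cohort, csv, row.names = FALSE)
  schema <- attr(cohort, "schema") %||% diabmini_schema()
  cb <- dk_codebooks()
  entries <- lapply(seq_len(nrow(schema)), function(i) {
    e <- list(name = schema$name[i], category = schema$category[i],
              type = schema$type[i], unit = schema$unit[i])
    if (schema$type[i] == "categorical")
      e$codebook <- cb[[schema$name[i]]]
    e
  })
  yaml::write_yaml(list(features = entries), yml)
  invisible(c(cohort = csv, schema = yml))
}

#' Load a cohort CSV with its schema sidecar
#'
#' @param csv cohort CSV path (must contain every schema feature).
#' @param schema_yaml schema sidecar path.
#' @return cohort data frame with attribute `schema`; audited by
#'   [audit_schema()].
#' @export
load_cohort <- function(csv, schema_yaml) {
  if (!file.exists(csv)) dk_stop("dk_io_error", "cohort file not found: %s", csv)
  if (!file.exists(schema_yaml)) dk_stop("dk_io_error", "schema file not found: %s", schema_yaml)
  sc <- yaml::read_yaml(schema_yaml)$features
  schema <- data.frame(name = vapply(sc, `[[`, "", "name"),
                       category = vapply(sc, `[[`, "", "category"),
                       type = vapply(sc, `[[`, "", "type"),
                       unit = vapply(sc, `[[`, "", "unit"))
  audit_schema(schema)
  cohort <- utils::read.csv(csv, stringsAsFactors = FALSE)
  missing <- setdiff(schema$name, names(cohort))
  if (length(missing) > 0)
    dk_stop("dk_schema_error", "cohort is missing feature(s): %s",
            paste(missing, collapse = ", "))
  attr(cohort, "schema") <- schema
  cohort
}

#' Structural checks against the deposited-cohort counts
#'
#' Verifies the published structural facts of the deposited dataset on any
#' cohort in the DiabMini schema: 88 samples, 127 features, label split
#' 21:15:52 (with `epsilon = 0`), and 69 samples answering "Never or rarely"
#' for weekly drinking. Designed to run identically on a local copy of the
#' deposited data or on the synthetic default cohort.
#'
#' @param cohort a cohort data frame with a `schema` attribute.
#' @param epsilon no-change tolerance for [label_change()].
#' @return named list of logical checks plus the observed values.
#' @export
check_diabmini <- function(cohort, epsilon = 0) {
  schema <- attr(cohort, "schema") %||% diabmini_schema()
  labs <- label_change(cohort$hba1c_exam1, cohort$hba1c_exam2, epsilon)$class
  counts <- as.integer(table(factor(labs, levels = 0:2)))
  drinking <- sum(cohort$drinking_weekly == "Never or rarely")
  list(n_samples = nrow(cohort), n_features = nrow(schema),
       label_counts = counts, drinking_never = drinking,
       ok_samples = nrow(cohort) == 88L,
       ok_features = nrow(schema) == 127L,
       ok_labels = identical(counts, c(21L, 15L, 52L)),
       ok_drinking = drinking == 69L)
}
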