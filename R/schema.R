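#' DiabMini-style cohort schema
#'
#' The 127-feature schema of the diabetes cohort: 6 personal features, 16
#' medical indicators recorded at each of two examinations (32 columns), 10
#' lifestyle questionnaire answers, and 79 nutrient-intake features (14-day
#' daily means). Lifestyle answers and gender are categorical with declared
#' codebooks; everything else is numeric.
#'
#' @return data frame with columns `name`, `category` (one of `personal`,
#'   `lifestyle`, `nutrient`, `medical_exam1`, `medical_exam2`), `type`
#'   (`numeric`/`categorical`) and `unit`.
#' @export
diabmini_schema <- function() {
  personal <- data.frame(
    name = c("gender", "age", "height", "weight", "bmi", "bfp"),
    category = "personal",
    type = c("categorical", rep("numeric", 5)),
    unit = c("code", "years", "cm", "kg", "kg/m2", "%"))
  med <- c(hba1c = "%", fbg = "mmol/L", tc = "mmol/L", tg = "mmol/L",
           hdl = "mmol/L", ldl = "mmol/L", whr = "ratio", sbp = "mmHg",
           dbp = "mmHg", alt = "U/L", ast = "U/L", creatinine = "umol/L",
           uric_acid = "umol/L", hemoglobin = "g/L", wbc = "1e9/L",
           body_fat_mass = "kg")
  med1 <- data.frame(name = paste0(names(med), "_exam1"),
                     category = "medical_exam1", type = "numeric",
                     unit = unname(med))
  med2 <- data.frame(name = paste0(names(med), "_exam2"),
                     category = "medical_exam2", type = "numeric",
                     unit = unname(med))
  lifestyle <- data.frame(
    name = c("exercise_weekly", "drinking_weekly", "smoking", "sleep_duration",
             "staying_up_late", "diet_regularity", "food_selection",
             "stress_level", "snack_freq", "sedentary_hours"),
    category = "lifestyle", type = "categorical", unit = "code")
  nutrient <- data.frame(name = nutrient_names(), category = "nutrient",
                         type = "numeric", unit = nutrient_units())
  out <- rbind(personal, med1, med2, lifestyle, nutrient)
  rownames(out) <- NULL
  out
}

# 79 nutrient feature names (daily mean intake)
nutrient_names <- function() {
  c(# macronutrients & proximates (10)
    "energy", "protein", "fat", "carbohydrate", "dietary_fiber", "water",
    "cholesterol", "ash", "sugar", "starch",
    # sugars & fibre detail (8)
    "fructose", "glucose", "sucrose", "lactose", "maltose", "galactose",
    "insoluble_fiber", "trans_fat",
    # vitamins (16)
    "vitamin_a", "carotene", "retinol", "vitamin_b1", "vitamin_b2", "niacin",
    "vitamin_b6", "vitamin_b12", "vitamin_c", "vitamin_d", "vitamin_e",
    "vitamin_k", "folate", "pantothenic_acid", "biotin", "choline",
    # minerals (13)
    "ca", "p", "k_mineral", "na", "mg", "fe", "zn", "se", "cu", "mn",
    "iodine", "cr", "mo",
    # amino acids (18)
    "isoleucine", "leucine", "lysine", "methionine", "cystine",
    "phenylalanine", "tyrosine", "threonine", "tryptophan", "valine",
    "histidine", "arginine", "alanine", "aspartic_acid", "glutamic_acid",
    "glycine", "proline", "serine",
    # fatty acids (14)
    "sfa", "mufa", "pufa", "c14_0", "c16_0", "c18_0", "c18_1_n9",
    "c18_2_n6", "c18_3_n3", "c20_1_n11", "c20_2_n6", "c20_4_n6",
    "c20_5_n3", "c22_6_n3")
}

nutrient_units <- function() {
  nm <- nutrient_names()
  u <- rep("g/day", length(nm))
  u[nm == "energy"] <- "kcal/day"
  u[nm %in% c("cholesterol", "vitamin_b1", "vitamin_b2", "niacin",
              "vitamin_b6", "vitamin_c", "vitamin_e", "vitamin_k", "ca", "p",
              "k_mineral", "na", "mg", "fe", "zn", "cu", "mn")] <- "mg/day"
  u[nm %in% c("vitamin_a", "carotene", "retinol", "vitamin_b12", "vitamin_d",
              "folate", "pantothenic_acid", "biotin", "choline", "se",
              "iodine", "cr", "mo")] <- "ug/day"
  u
}

#' Lifestyle and gender codebooks
#'
#' Declared answer levels for each categorical feature; integer encoding in
#' [assemble_predictors()] follows the level order given here (first level
#' encodes as 1).
#'
#' @return named list of character level vectors.
#' @export
dk_codebooks <- function() {
  freq4 <- c("Never or rarely", "1-2 times", "3-5 times", "Daily")
  list(gender = c("Male", "Female"),
       exercise_weekly = freq4,
       drinking_weekly = freq4,
       smoking = c("Never", "Former", "Current"),
       sleep_duration = c("<6h", "6-8h", ">8h"),
       staying_up_late = c("Rarely", "Sometimes", "Often"),
       diet_regularity = c("Regular", "Irregular"),
       food_selection = c("By preference", "By nutrition", "By health condition"),
       stress_level = c("Low", "Medium", "High"),
       snack_freq = c("Rarely", "Sometimes", "Often"),
       sedentary_hours = c("<4h", "4-8h", ">8h"))
}

#' Audit a cohort's schema
#'
#' Checks the category counts (6 personal, 16+16 medical, 10 lifestyle, 79
#' nutrient = 127) and the presence of HbA1c in both exam blocks.
#'
#' @param schema a schema data frame (see [diabmini_schema()]).
#' @return invisibly `TRUE`; errors otherwise.
#' @export
audit_schema <- function(schema) {
  counts <- table(schema$category)
  want <- c(personal = 6, medical_exam1 = 16, medical_exam2 = 16,
            lifestyle = 10, nutrient = 79)
  for (cat in names(want))
    if (is.na(counts[cat]) || counts[cat] != want[cat])
      dk_stop("dk_schema_error", "schema: expected %d %s features, found %d",
              want[cat], cat, ifelse(is.na(counts[cat]), 0L, counts[cat]))
  if (!all(c("hba1c_exam1", "hba1c_exam2") %in% schema$name))
    dk_stop("dk_schema_error", "schema: HbA1c must be present in both exam blocks")
  invisible(TRUE)
}
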