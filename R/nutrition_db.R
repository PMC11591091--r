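#' Food--nutrition database
#'
#' Loads the three-kind food composition store: ingredients with full
#' per-100 g nutrient vectors, packaged foods restricted to the five core
#' nutrients (energy, fat, carbohydrate, protein, Na), and dishes described
#' as (ingredient, amount g) composition lists. All nutrient amounts are
#' stored per 100 g. A `-` cell in the source tables marks a nutrient as
#' absent for that food; absence is modelled as `NA` and is never silently
#' treated as zero.
#'
#' @param ingredient_file CSV with a `name` column and one numeric column per
#'   nutrient; `-` marks an absent nutrient.
#' @param packaged_file CSV with `name` plus the five core nutrient columns.
#' @param dish_file CSV in either dialect: long format with columns
#'   `name,ingredient,amount_g`, or wide format with repeated
#'   `ingredient<i>,amount<i>` column pairs.
#' @param units_file required units manifest CSV with columns
#'   `nutrient,unit`; every nutrient column in the ingredient and packaged
#'   tables must appear here (mg vs g is resolved by the manifest, never
#'   guessed from magnitude).
#' @return an object of class `nutrition_db` with elements `ingredients`,
#'   `packaged` (data frames, `NA` = absent), `dishes` (list of composition
#'   data frames) and `units` (named character vector).
#' @export
load_nutrition_db <- function(ingredient_file, packaged_file, dish_file, units_file) {
  units <- read_units_manifest(units_file)
  ing <- read_nutrient_table(ingredient_file, units)
  pkg <- read_nutrient_table(packaged_file, units)
  core <- c("energy", "fat", "carbohydrate", "protein", "na")
  extra <- setdiff(setdiff(names(pkg), "name"), core)
  if (length(extra) > 0)
    dk_stop("dk_parse_error",
            "%s: packaged foods carry only the five core nutrients; unexpected column(s): %s",
            packaged_file, paste(extra, collapse = ", "))
  dishes <- read_dish_table(dish_file)
  db <- structure(list(ingredients = ing, packaged = pkg, dishes = dishes,
                       units = units), class = "nutrition_db")
  db$index <- build_name_index(db)
  db
}

read_units_manifest <- function(path) {
  if (!file.exists(path)) dk_stop("dk_io_error", "units manifest not found: %s", path)
  u <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("nutrient", "unit") %in% names(u)))
    dk_stop("dk_parse_error", "%s: units manifest needs columns nutrient,unit", path)
  stats::setNames(u$unit, normalize_name(u$nutrient))
}

read_nutrient_table <- function(path, units) {
  if (!file.exists(path)) dk_stop("dk_io_error", "file not found: %s", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character",
                         check.names = FALSE)
  if (!"name" %in% names(raw)) dk_stop("dk_parse_error", "%s: missing 'name' column", path)
  nutr_cols <- setdiff(names(raw), "name")
  names(raw)[-match("name", names(raw))] <- normalize_name(nutr_cols)
  nutr_cols <- setdiff(names(raw), "name")
  missing_units <- setdiff(nutr_cols, names(units))
  if (length(missing_units) > 0)
    dk_stop("dk_parse_error", "%s: nutrient(s) not in units manifest: %s",
            path, paste(missing_units, collapse = ", "))
  norm <- normalize_name(raw$name)
  dup <- norm[duplicated(norm)]
  if (length(dup) > 0)
    dk_stop("dk_conflict_error", "%s: duplicate name(s) after normalization: %s",
            path, paste(unique(dup), collapse = ", "))
  out <- data.frame(name = raw$name, stringsAsFactors = FALSE)
  for (cl in nutr_cols) {
    v <- trimws(raw[[cl]])
    is_absent <- v == "-" | v == ""
    num <- suppressWarnings(as.numeric(v))
    bad <- which(!is_absent & is.na(num))
    if (length(bad) > 0)
      dk_stop("dk_parse_error", "%s: line %d: cannot parse '%s' in column '%s'",
              path, bad[1] + 1L, v[bad[1]], cl)
    neg <- which(!is_absent & num < 0)
    if (length(neg) > 0)
      dk_stop("dk_parse_error", "%s: line %d: negative amount in column '%s'",
              path, neg[1] + 1L, cl)
    num[is_absent] <- NA_real_
    out[[cl]] <- num
  }
  rownames(out) <- norm
  out
}

read_dish_table <- function(path) {
  if (!file.exists(path)) dk_stop("dk_io_error", "file not found: %s", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  nm <- names(raw)
  if (all(c("name", "ingredient", "amount_g") %in% nm)) {
    comps <- split(raw[c("ingredient", "amount_g")], normalize_name(raw$name))
    display <- raw$name[!duplicated(normalize_name(raw$name))]
    names(display) <- normalize_name(display)
  } else if ("name" %in% nm && any(grepl("^ingredient", nm))) {
    ing_cols <- grep("^ingredient", nm, value = TRUE)
    amt_cols <- grep("^amount", nm, value = TRUE)
    if (length(ing_cols) != length(amt_cols))
      dk_stop("dk_parse_error", "%s: unpaired ingredient/amount columns", path)
    norm <- normalize_name(raw$name)
    if (anyDuplicated(norm))
      dk_stop("dk_conflict_error", "%s: duplicate dish name(s)", path)
    comps <- lapply(seq_len(nrow(raw)), function(i) {
      ingr <- as.character(unlist(raw[i, ing_cols]))
      amt <- suppressWarnings(as.numeric(unlist(raw[i, amt_cols])))
      keep <- !is.na(ingr) & nzchar(trimws(ingr))
      data.frame(ingredient = ingr[keep], amount_g = amt[keep],
                 stringsAsFactors = FALSE)
    })
    names(comps) <- norm
    display <- stats::setNames(raw$name, norm)
  } else {
    dk_stop("dk_parse_error",
            "%s: dish file must be long (name,ingredient,amount_g) or wide (ingredient<i>,amount<i>)",
            path)
  }
  for (nmz in names(comps)) {
    cc <- comps[[nmz]]
    if (any(is.na(cc$amount_g)))
      dk_stop("dk_parse_error", "%s: dish '%s': non-numeric amount", path, nmz)
    if (any(cc$amount_g <= 0))
      dk_stop("dk_parse_error", "%s: dish '%s': amounts must be > 0", path, nmz)
  }
  lapply(stats::setNames(names(comps), names(comps)), function(k)
    list(name = unname(display[k]), composition = comps[[k]]))
}

build_name_index <- function(db) {
  data.frame(
    norm = c(rownames(db$ingredients), rownames(db$packaged), names(db$dishes)),
    name = c(db$ingredients$name, db$packaged$name,
             vapply(db$dishes, function(d) d$name, character(1))),
    table = rep(c("ingredient", "packaged", "dish"),
                c(nrow(db$ingredients), nrow(db$packaged), length(db$dishes))),
    stringsAsFactors = FALSE)
}

#' @export
print.nutrition_db <- function(x, ...) {
  cat(sprintf("<nutrition_db> %d ingredients, %d packaged foods, %d dishes, %d nutrients\n",
              nrow(x$ingredients), nrow(x$packaged), length(x$dishes),
              length(x$units)))
  invisible(x)
}

#' Match a food name against the database
#'
#' Exact normalized matches score 1.0 and rank first; otherwise similarity is
#' `1 - editdist/max(nchar)` (generalized Levenshtein). Results are sorted by
#' descending score with lexicographic tie-break on the normalized name.
#'
#' @param query non-empty food name.
#' @param db a `nutrition_db`.
#' @param min_score score floor; candidates below it are dropped (default 0.5).
#' @return data frame with columns `name`, `table`, `score` (possibly 0 rows).
#' @export
match_food <- function(query, db, min_score = 0.5) {
  stopifnot(inherits(db, "nutrition_db"))
  if (length(query) != 1 || is.na(query) || !nzchar(trimws(query)))
    dk_stop("dk_input_error", "match_food: query must be a non-empty string")
  q <- normalize_name(query)
  idx <- db$index
  d <- as.integer(utils::adist(q, idx$norm))
  score <- ifelse(idx$norm == q, 1.0,
                  1 - d / pmax(nchar(q), nchar(idx$norm)))
  keep <- score >= min_score
  out <- idx[keep, c("name", "table"), drop = FALSE]
  out$score <- score[keep]
  ord <- order(-out$score, idx$norm[keep])
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# exact-tier resolution of a food name to a per-100 g nutrient vector
resolve_food <- function(name, db) {
  q <- normalize_name(name)
  if (q %in% rownames(db$ingredients)) {
    v <- as.numeric(db$ingredients[q, -1])
    return(stats::setNames(v, names(db$ingredients)[-1]))
  }
  if (q %in% rownames(db$packaged)) {
    v <- as.numeric(db$packaged[q, -1])
    return(stats::setNames(v, names(db$packaged)[-1]))
  }
  if (q %in% names(db$dishes)) {
    dn <- dish_nutrients(db$dishes[[q]], db)
    return(dn$per_100g)
  }
  NULL
}

#' Aggregate a dish's nutrition from its ingredient composition
#'
#' Per-nutrient whole-dish total is `sum(amount_i * nutrient_i / 100)` over
#' the composition; ingredients whose value for a nutrient is absent are
#' skipped and that output nutrient is flagged partially known. The per-100 g
#' vector rescales the total by `100 / sum(amounts)`.
#'
#' @param dish a dish name present in `db`, or a list with elements `name`
#'   and `composition` (data frame `ingredient`, `amount_g`).
#' @param db a `nutrition_db`.
#' @return list with `total`, `per_100g` (named numeric vectors),
#'   `partial` (named logical: nutrient computed from an incomplete
#'   ingredient set) and `dish_weight_g`.
#' @export
dish_nutrients <- function(dish, db) {
  stopifnot(inherits(db, "nutrition_db"))
  if (is.character(dish)) {
    q <- normalize_name(dish)
    if (!q %in% names(db$dishes))
      dk_stop("dk_lookup_error", "dish not found: %s", dish)
    dish <- db$dishes[[q]]
  }
  comp <- dish$composition
  if (any(comp$amount_g <= 0))
    dk_stop("dk_input_error", "dish composition amounts must be > 0")
  nutr <- setdiff(names(db$ingredients), "name")
  total <- stats::setNames(numeric(length(nutr)), nutr)
  partial <- stats::setNames(logical(length(nutr)), nutr)
  seen <- stats::setNames(logical(length(nutr)), nutr)
  for (i in seq_len(nrow(comp))) {
    q <- normalize_name(comp$ingredient[i])
    if (!q %in% rownames(db$ingredients))
      dk_stop("dk_lookup_error", "ingredient not found: %s", comp$ingredient[i])
    v <- as.numeric(db$ingredients[q, nutr])
    absent <- is.na(v)
    partial[absent] <- TRUE
    total[!absent] <- total[!absent] + comp$amount_g[i] * v[!absent] / 100
    seen[!absent] <- TRUE
  }
  # a nutrient absent in every ingredient stays absent, not zero
  total[!seen] <- NA_real_
  w <- sum(comp$amount_g)
  list(total = total, per_100g = total * 100 / w,
       partial = partial, dish_weight_g = w)
}

#' Convert diet records to per-day nutrient totals
#'
#' Each record contributes `weight_g * per-100 g value / 100` to its day's
#' totals. Days inside the requested range with no records appear as explicit
#' zero rows. Nutrients absent for a consumed food are skipped and flagged in
#' the `partial` attribute (never coerced to zero contributions silently: the
#' flag travels with the series).
#'
#' @param records data frame with columns `date` (ISO-8601), `food_name`,
#'   `weight_g` (> 0).
#' @param db a `nutrition_db`.
#' @param from,to optional date range bounds (default: the records' range).
#' @return data frame with a `date` column and one column per nutrient;
#'   attribute `partial` is a logical matrix of the same shape marking
#'   partially known totals.
#' @export
intake_series <- function(records, db, from = NULL, to = NULL) {
  stopifnot(inherits(db, "nutrition_db"))
  nutr <- setdiff(names(db$ingredients), "name")
  if (nrow(records) == 0 && is.null(from)) {
    out <- data.frame(date = as.Date(character(0)))
    for (cl in nutr) out[[cl]] <- numeric(0)
    attr(out, "partial") <- matrix(FALSE, 0, length(nutr),
                                   dimnames = list(NULL, nutr))
    return(out)
  }
  if (nrow(records) > 0) {
    stopifnot(all(c("date", "food_name", "weight_g") %in% names(records)))
    if (any(records$weight_g <= 0))
      dk_stop("dk_input_error", "diet record weights must be > 0")
    rd <- as.Date(records$date)
    if (anyNA(rd)) dk_stop("dk_parse_error", "unparseable date in diet records")
  } else rd <- as.Date(character(0))
  from <- as.Date(from %||% min(rd))
  to <- as.Date(to %||% max(rd))
  days <- seq(from, to, by = "day")
  m <- matrix(0, length(days), length(nutr), dimnames = list(NULL, nutr))
  part <- matrix(FALSE, length(days), length(nutr), dimnames = list(NULL, nutr))
  unresolved <- character(0)
  for (i in seq_len(nrow(records))) {
    v <- resolve_food(records$food_name[i], db)
    if (is.null(v)) { unresolved <- c(unresolved, records$food_name[i]); next }
    di <- match(rd[i], days)
    if (is.na(di)) next   # record outside the requested range
    vv <- v[nutr]
    absent <- is.na(vv)
    part[di, absent] <- TRUE
    m[di, !absent] <- m[di, !absent] + records$weight_g[i] * vv[!absent] / 100
  }
  if (length(unresolved) > 0)
    dk_stop("dk_lookup_error", "unresolved food name(s): %s",
            paste(unique(unresolved), collapse = ", "))
  out <- data.frame(date = days)
  for (j in seq_along(nutr)) out[[nutr[j]]] <- m[, j]
  attr(out, "partial") <- part
  out
}

#' Mean daily nutrient intake over a window
#'
#' Arithmetic mean per nutrient over the window's days, zero days included.
#'
#' @param series output of [intake_series()].
#' @param from first day of the window (default: series start).
#' @param days window length in days (default 14).
#' @return named numeric vector of daily means.
#' @export
mean_intake <- function(series, from = NULL, days = 14) {
  from <- as.Date(from %||% min(series$date))
  window <- seq(from, by = "day", length.out = days)
  if (!all(window %in% series$date))
    dk_stop("dk_input_error", "window not covered by the series' date range")
  sub <- series[series$date %in% window, setdiff(names(series), "date"), drop = FALSE]
  colMeans(as.matrix(sub))
}
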