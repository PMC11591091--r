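test_that("database loads with correct counts, units and absent markers", {
  db <- fixture_db()
  expect_equal(nrow(db$ingredients), 6)
  expect_equal(nrow(db$packaged), 5)
  expect_length(db$dishes, 5)
  # per-100 g values survive parsing
  expect_equal(db$ingredients["rice", "energy"], 116)
  expect_equal(db$ingredients["potato", "energy"], 77)
  # "-" becomes an absent marker, not 0
  expect_true(is.na(db$ingredients["pork", "dietary fiber"]))
  expect_false(isTRUE(db$ingredients["pork", "dietary fiber"] == 0))
})

test_that("malformed and conflicting tables are rejected with located errors", {
  ed <- system.file("extdata", package = "diabkit")
  units <- file.path(ed, "units.csv")
  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("name,energy", "A,12", "B,oops"), bad)
  expect_error(diabkit:::read_nutrient_table(bad, diabkit:::read_units_manifest(units)),
               "line 3", class = "dk_parse_error")
  dup <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("name,energy", "Rice,1", "rice ,2"), dup)
  expect_error(diabkit:::read_nutrient_table(dup, diabkit:::read_units_manifest(units)),
               class = "dk_conflict_error")
  nomanifest <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("name,mystery_nutrient", "A,1"), nomanifest)
  expect_error(diabkit:::read_nutrient_table(nomanifest, diabkit:::read_units_manifest(units)),
               "units manifest", class = "dk_parse_error")
})

test_that("both dish-file dialects parse to the same composition", {
  db <- fixture_db()
  wide <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("name,ingredient1,amount1,ingredient2,amount2",
               "Roast Chicken,Rice,250,Chicken,200"), wide)
  dishes <- diabkit:::read_dish_table(wide)
  expect_equal(dishes[["roast chicken"]]$composition$amount_g,
               db$dishes[["roast chicken"]]$composition$amount_g)
  expect_equal(normalize_name(dishes[["roast chicken"]]$composition$ingredient),
               normalize_name(db$dishes[["roast chicken"]]$composition$ingredient))
})

test_that("match_food scores exact matches 1.0 and ranks by edit-distance similarity", {
  db <- fixture_db()
  exact <- match_food("Potato", db)
  expect_equal(exact$name[1], "Potato")
  expect_equal(exact$score[1], 1.0)
  near <- match_food("Potatoo", db)
  expect_equal(near$name[1], "Potato")
  expect_lt(near$score[1], 1.0)
  expect_equal(nrow(match_food("zzzz", db)), 0)
  expect_error(match_food("", db), class = "dk_input_error")
  # normalization invariance
  expect_equal(match_food("  POTATO ", db)$score[1], 1.0)
})

test_that("match_food ranking agrees with an exhaustive DP edit-distance scan", {
  db <- fixture_db()
  names_all <- db$index$norm
  for (q in c("potatoo", "chiken", "rost chicken", "biskit")) {
    got <- match_food(q, db, min_score = 0)
    sim <- sapply(names_all, function(nm)
      if (nm == q) 1 else 1 - dp_edit_distance(q, nm) / max(nchar(q), nchar(nm)))
    ord <- order(-sim, names_all)
    expect_equal(got$score, unname(sim[ord]), tolerance = 1e-12)
    expect_equal(normalize_name(got$name), names_all[ord])
  }
})

test_that("dish aggregation is linear, scales per-100g values, and flags absences", {
  db <- fixture_db()
  rice200 <- dish_nutrients(list(name = "r", composition = data.frame(
    ingredient = "Rice", amount_g = 200)), db)
  expect_equal(unname(rice200$total["energy"]), 232)  # 2 x 116 kcal
  expect_equal(unname(rice200$per_100g["energy"]), 116)
  two <- dish_nutrients(list(name = "xy", composition = data.frame(
    ingredient = c("Rice", "Potato"), amount_g = c(50, 100))), db)
  expect_equal(unname(two$total["energy"]), 50 * 116 / 100 + 100 * 77 / 100)
  # doubling all amounts doubles totals, keeps per-100g fixed
  dbl <- dish_nutrients(list(name = "xy2", composition = data.frame(
    ingredient = c("Rice", "Potato"), amount_g = c(100, 200))), db)
  expect_equal(dbl$total, 2 * two$total)
  expect_equal(dbl$per_100g, two$per_100g)
  # pork has absent fiber: flag propagates, other nutrients computed
  pfr <- dish_nutrients("Pork Fried Rice", db)
  expect_true(pfr$partial[["dietary fiber"]])
  expect_false(pfr$partial[["energy"]])
  expect_equal(unname(pfr$total["energy"]), 200 * 116 / 100 + 80 * 395 / 100)
  expect_error(dish_nutrients(list(name = "bad", composition = data.frame(
    ingredient = "Unobtainium", amount_g = 10)), db),
    "Unobtainium", class = "dk_lookup_error")
})

test_that("intake series is additive, order-invariant, and zero-fills empty days", {
  db <- fixture_db()
  one <- data.frame(date = "2024-01-01", food_name = "Rice", weight_g = 150)
  s1 <- intake_series(one, db)
  expect_equal(unname(s1$energy), 174)  # 1.5 x 116
  # two half-records equal one whole record
  halves <- data.frame(date = "2024-01-01", food_name = "Rice",
                       weight_g = c(50, 50))
  whole <- data.frame(date = "2024-01-01", food_name = "Rice", weight_g = 100)
  expect_equal(intake_series(halves, db)$energy, intake_series(whole, db)$energy)
  # permutation invariance
  rec <- data.frame(date = c("2024-01-02", "2024-01-01", "2024-01-02"),
                    food_name = c("Rice", "Potato", "Chicken"),
                    weight_g = c(100, 200, 50))
  s_fwd <- intake_series(rec, db)
  s_rev <- intake_series(rec[3:1, ], db)
  expect_equal(s_fwd, s_rev)
  # zero row for a gap day inside the range
  gap <- intake_series(data.frame(date = c("2024-01-01", "2024-01-03"),
                                  food_name = "Rice", weight_g = 100), db)
  expect_equal(nrow(gap), 3)
  expect_equal(unname(gap$energy[2]), 0)
  # empty records over empty range -> empty series
  expect_equal(nrow(intake_series(data.frame(date = character(0),
                                             food_name = character(0),
                                             weight_g = numeric(0)), db)), 0)
  expect_error(intake_series(data.frame(date = "2024-01-01",
                                        food_name = "NotAFood",
                                        weight_g = 10), db),
               "NotAFood", class = "dk_lookup_error")
})

test_that("mean intake averages over the window including zero days", {
  db <- fixture_db()
  days <- seq(as.Date("2024-01-01"), by = "day", length.out = 14)
  const <- data.frame(date = days, food_name = "Rice", weight_g = 150)
  expect_equal(unname(mean_intake(intake_series(const, db), days = 14)["energy"]), 174)
  # alternating 100/200 kcal -> 150
  alt <- data.frame(date = days,
                    food_name = "Rice",
                    weight_g = rep(c(100 / 116 * 100, 200 / 116 * 100), 7))
  expect_equal(unname(mean_intake(intake_series(alt, db), days = 14)["energy"]), 150)
  # random fixture equals brute-force sum/14 (zero days included)
  set.seed(42)
  rnd <- data.frame(date = sample(days, 20, replace = TRUE),
                    food_name = sample(c("Rice", "Potato", "Oatmeal"), 20, TRUE),
                    weight_g = round(runif(20, 20, 300)))
  series <- intake_series(rnd, db, from = days[1], to = days[14])
  mi <- mean_intake(series, from = days[1], days = 14)
  brute <- colSums(as.matrix(series[, -1])) / 14
  expect_equal(mi, brute)
  expect_error(mean_intake(series, from = days[5], days = 14),
               class = "dk_input_error")
})
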