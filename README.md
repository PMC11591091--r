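# diabkit

Tools for the computational core of mobile diabetes management: converting
diet records into nutrient intake over a food composition database,
estimating food weight from a single tilted-phone photograph, classifying
the between-examination change of glycated hemoglobin (HbA1c) with a
stacked ensemble, and attributing that classification to individual risk
factors.

It is written for researchers who study diabetes progression from the kind
of data a diet-tracking phone application collects — personal
characteristics, two medical examinations, lifestyle questionnaires, and
14-day mean nutrient intake — and who need every stage testable without
access to the original deposited data: synthetic scene and cohort
simulators with known ground truth are first-class components.

## What it computes

**Nutrient accounting.** A three-kind food database (ingredients with full
per-100 g nutrient vectors, packaged foods with five core nutrients, dishes
as ingredient–amount lists), edit-distance name matching, dish aggregation
`total = Σ amountᵢ · nutrientᵢ / 100`, per-day intake series and 14-day
means. Absent nutrients (`-` cells) are flags, never zeros.

**Photo geometry.** With the phone leaning at tilt α (gyroscope), camera at
`A = (p·cos α, p·sin α)`, field-offset angle β, and the food at fractional
image height `k = a/b`, the shooting distance is the intersection of the
camera ray through the virtual-image point
`D = d·(cos α, −sin α)`, `d = 2pk·sin α·cos β / sin(α+β)`, with the table:

```
l_OC = x_A − y_A·(x_D − x_A)/(y_D − y_A) = 2·p·d·cos α / (d + p)
```

validated to machine precision against an independent numerical ray-cast.
Projected food area is `S = (mask pixels)·pitch²`.

**Weight regression.** LASSO of weight on food type, α, l_OC and S
(optional S×type interactions), standardized features, CV-chosen penalty,
zero-clamped predictions, MAE evaluation against the simulator's analytic
noise floor.

**HbA1c-change classification.** Three classes (0 no change / 1 increased /
2 decreased) from the two examinations' HbA1c; 111 predictors (6 personal,
10 lifestyle, 79 nutrient, 16 first-exam medical; the second exam never
leaks in). The classifier stacks XGBoost, an RBF SVC and Extra Trees, with
a k-NN meta learner on out-of-fold base probabilities; SMOTE runs inside
training folds only, with an index-provenance leakage audit; evaluation is
stratified K-fold with accuracy, macro-precision/recall/F1, pooled
confusion matrix and macro one-vs-rest ROC/AUC.

**Attribution.** A model-agnostic permutation-sampling Shapley estimator on
the stack's class probabilities, with exact per-sample additivity, global
and per-class rankings, and sign summaries.

## Worked example

```r
library(diabkit)

ed <- system.file("extdata", package = "diabkit")
db <- load_nutrition_db(file.path(ed, "ingredients.csv"),
                        file.path(ed, "packaged.csv"),
                        file.path(ed, "dishes.csv"),
                        file.path(ed, "units.csv"))
db
#> <nutrition_db> 6 ingredients, 5 packaged foods, 5 dishes, 10 nutrients

round(dish_nutrients("Pork Fried Rice", db)$total[
  c("energy", "fat", "protein", "carbohydrate")], 1)
#>       energy          fat      protein carbohydrate
#>        548.0         30.2         15.8         53.7
```

548 kcal is 200 g rice (116 kcal/100 g) plus 80 g pork (395 kcal/100 g).
Geometry: a 15 cm phone tilted 60°, food halfway up the frame:

```r
spec <- phone_spec(p = 0.15, beta = pi/6)
shot_distance(spec, alpha = 60*pi/180, k = 0.5)   # closed form
#> [1] 0.06428571
raycast_distance(spec, alpha = 60*pi/180, k = 0.5) # independent ray-cast
#> [1] 0.06428571
```

A synthetic cohort with five strong planted effects, classified and
explained end to end:

```r
eff <- data.frame(feature = c("age","whr_exam1","se","hba1c_exam1","tg_exam1"),
                  class   = c(0, 0, 1, 1, 2),
                  size    = 1.75 * c(1, -1, -1, -1, 1))
co <- simulate_cohort(cohort_spec(effects = eff, seed = 42))
ap <- assemble_predictors(co)          # 88 x 111, labels 21/15/52
evaluate_stacked(ap$X, ap$y, seed = 42)
#> <stack_eval> K = 5 folds
#>   accuracy         0.9105 +/- 0.0839
#>   macro_precision  0.9281 +/- 0.1012
#>   macro_recall     0.8878 +/- 0.0776
#>   macro_f1         0.9065 +/- 0.0843
#>   auc              0.9619 +/- 0.0321
#>   pooled macro AUC  0.9613
#>   SMOTE leakage audit: clean

model <- fit_stacked(ap$X, ap$y, seed = 42)
rep <- attribute_stacked(model, ap$X, background_size = 20, nsim = 16, seed = 42)
head(summarize_attribution(rep, top_n = 5)$global, 5)
#>       feature   mean_abs
#> 1         age 0.09500631
#> 2    tg_exam1 0.07426926
#> 3 hba1c_exam1 0.06868292
#> 4   whr_exam1 0.06552320
#> 5          se 0.04472301
```

All five planted risk factors head the global attribution ranking; the
cross-validated accuracy (91%) and macro metrics come from held-out folds
with oversampling confined to training data.

A command-line wrapper over the same functions ships in `inst/cli/diabkit`
(subcommands `nutridb`, `geometry`, `simulate`, `weight`, `labels`,
`train`, `explain`; every artifact-producing run writes a manifest).

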