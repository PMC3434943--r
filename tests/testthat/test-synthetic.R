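test_that("the default configuration encodes the study design", {
  cfg <- experiment_config(seed = 1)
  # carbohydrate-rich diet C has C:P ratio 8 (the printed 1:8 P:C)
  expect_equal(cfg$diets$cp_ratio[cfg$diets$diet == "C"], 8.00,
               tolerance = 0.001)
  expect_equal(cfg$diets$cp_ratio[cfg$diets$diet == "P"], 1)
  # both diets hold 84% protein + carbohydrate
  expect_equal(round(cfg$diets$protein_pct + cfg$diets$carb_pct), c(84, 84))
  expect_equal(sum(cfg$sample_sizes$n), 575)
  expect_equal(cfg$schedule$first, 4)
  expect_equal(cfg$schedule$interval, 5)
})

test_that("invalid configurations are rejected with field paths", {
  expect_error(experiment_config(), "seed")
  di <- default_diet_compositions(); di$carb_pct[1] <- 60
  expect_error(experiment_config(diets = di, seed = 1), "diets")
  ss <- default_sample_sizes(); ss$n[1] <- -5
  expect_error(experiment_config(sample_sizes = ss, seed = 1),
               "sample_sizes")
  ss2 <- default_sample_sizes(); ss2$sex[1] <- "other"
  expect_error(experiment_config(sample_sizes = ss2, seed = 1), "sex")
  gp <- default_gompertz_params(); gp$alpha[2] <- -0.01
  expect_error(experiment_config(gompertz = gp, seed = 1), "gompertz")
  sc <- list(first = 4, interval = 0)
  expect_error(experiment_config(schedule = sc, seed = 1), "interval")
  expect_error(experiment_config(calling = list(
    coefficients = default_calling_coefficients(), sigma_u = -1,
    sigma_e = 3000), seed = 1), "sigma_u")
})

test_that("generated cohorts have the exact configured group sizes", {
  e <- generate_experiment(experiment_config(seed = 2))
  expect_equal(nrow(e$cohort), 575)
  expect_equal(sum(e$cohort$sex == "male"), 300)
  expect_equal(sum(e$cohort$sex == "female"), 275)
  counts <- table(e$cohort$sex, e$cohort$diet, e$cohort$mating)
  expect_equal(counts["male", "C", "virgin"], 82)
  expect_equal(counts["male", "C", "mated"], 76)
  expect_equal(counts["male", "P", "virgin"], 72)
  expect_equal(counts["male", "P", "mated"], 70)
  expect_equal(counts["female", "C", "virgin"], 71)
  expect_equal(counts["female", "P", "virgin"], 61)
  expect_true(all(e$cohort$lifespan_days > 0))
  expect_equal(anyDuplicated(e$cohort$id), 0L)
})

test_that("the calling schedule truncates at death", {
  expect_equal(calling_schedule(12), c(4, 9))
  expect_equal(calling_schedule(4), numeric(0))
  expect_equal(calling_schedule(4.5), 4)
  expect_equal(calling_schedule(30, first = 4, interval = 5),
               c(4, 9, 14, 19, 24, 29))
  e <- generate_experiment(experiment_config(seed = 3))
  j <- join_calling(e$cohort, e$calling)
  expect_true(all(j$age_days < j$lifespan_days))
  expect_true(all(j$age_days >= 4))
  expect_true(all(j$sex == "male"))
  # every male surviving past the first recording age appears
  males <- e$cohort[e$cohort$sex == "male" & e$cohort$lifespan_days > 4, ]
  expect_setequal(unique(e$calling$id), males$id)
})

test_that("identical seeds give byte-identical outputs, streams independent", {
  cfg <- experiment_config(seed = 5)
  e1 <- generate_experiment(cfg)
  e2 <- generate_experiment(cfg)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_cohort(e1$cohort, f1); write_cohort(e2$cohort, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(e1$calling, e2$calling)
  e3 <- generate_experiment(cfg, seed = 6)
  expect_false(identical(e1$cohort$lifespan_days, e3$cohort$lifespan_days))
  # toggling the calling stream leaves the death-time stream untouched
  cfg2 <- experiment_config(calling = list(
    coefficients = default_calling_coefficients(), sigma_u = 10,
    sigma_e = 10), seed = 5)
  e4 <- generate_experiment(cfg2)
  expect_identical(e1$cohort$lifespan_days, e4$cohort$lifespan_days)
  expect_false(identical(e1$calling$calling_s, e4$calling$calling_s))
})

test_that("daily rounding and calling clipping behave as flagged", {
  er <- generate_experiment(experiment_config(daily_rounding = TRUE,
                                              seed = 7))
  t <- er$cohort$lifespan_days
  expect_true(all(t == round(t) & t >= 1))
  ec <- generate_experiment(experiment_config(clip_calling = TRUE, seed = 7))
  expect_true(all(ec$calling$calling_s >= 0 &
                    ec$calling$calling_s <= 54000))
})

test_that("per-cell survival of generated cohorts matches the generator", {
  # one cell inflated to n = 1e5: empirical vs generating survival (KS)
  ss <- default_sample_sizes()[1, ]; ss$n <- 1e5
  gp <- default_gompertz_params()[1, ]
  e <- generate_experiment(experiment_config(sample_sizes = ss,
                                             gompertz = gp, seed = 8))
  sp <- hazard_spec("gompertz", alpha = gp$alpha, beta = gp$beta)
  ks <- suppressWarnings(
    ks.test(e$cohort$lifespan_days, function(q) 1 - survival(sp, q)))
  expect_gt(ks$p.value, 0.001)
})

test_that("the full pipeline runs end to end and is reproducible", {
  cfg <- experiment_config(seed = 9)
  rep1 <- run_experiment(cfg, bootstrap_reps = 200, control = fast_ctrl)
  expect_s3_class(rep1, "mortsen_report")
  expect_named(rep1$battery, c("female", "male"))
  expect_equal(nrow(rep1$battery$male$table), 26)
  expect_equal(rep1$sex_lrt$df, 8)
  expect_equal(nrow(rep1$lifespan), 8)
  expect_equal(nrow(rep1$calling$table), 3)
  rep2 <- run_experiment(cfg, bootstrap_reps = 200, control = fast_ctrl)
  # AIC tables are bit-identical across runs at a fixed seed
  expect_identical(rep1$battery$male$table, rep2$battery$male$table)
  expect_identical(rep1$lifespan, rep2$lifespan)
  js <- report_json(rep1)
  expect_equal(js$provenance$seed, 9)
})

test_that("battery outcomes echo the study design across many seeds", {
  interaction_in_top_set <- 0; null_ok <- 0; const_best <- 0
  gp_null <- default_gompertz_params()
  gp_null$alpha <- 0.008; gp_null$beta <- 0.035
  gp_const <- default_gompertz_params()
  gp_const$alpha <- 0.02; gp_const$beta <- 1e-12
  for (s in 1:20) {
    # default Table-1-style generator: diet x mating signal on male beta
    e <- generate_experiment(experiment_config(seed = s))
    m <- e$cohort[e$cohort$sex == "male", ]
    b <- run_battery(m, control = fast_ctrl)
    top <- b$table$label[b$table$delta_aic <= 2]
    if (any(grepl("b~.*diet:mating", top)))
      interaction_in_top_set <- interaction_in_top_set + 1
    # homogeneous generator: the no-effect structure stays competitive
    e2 <- generate_experiment(experiment_config(gompertz = gp_null,
                                                seed = s))
    b2 <- run_battery(e2$cohort[e2$cohort$sex == "male", ],
                      control = fast_ctrl)
    if (b2$table$delta_aic[b2$table$label == "gompertz: a~1, b~1"] <= 2)
      null_ok <- null_ok + 1
    # age-independent generator: "no senescence" wins
    e3 <- generate_experiment(experiment_config(gompertz = gp_const,
                                                seed = s))
    b3 <- run_battery(e3$cohort[e3$cohort$sex == "male", ],
                      control = fast_ctrl)
    if (b3$best$structure$family == "constant") const_best <- const_best + 1
  }
  expect_gte(interaction_in_top_set, 11)  # majority of 20 seeds
  expect_gte(null_ok, 16)                 # >= 80% of 20 seeds
  expect_gte(const_best, 11)              # majority of 20 seeds
})
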