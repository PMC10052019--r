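test_that("stratified splits partition rows with per-class rounding", {
  tb <- small_table(n = 10, p = 3, k = 0, seed = 2, fractions = c(0.5, 0.5))
  sp <- stratified_split(tb, 0.8, seed = 1)
  y <- ft_labels(tb)
  expect_equal(sum(y[sp$train] == 0), 4)
  expect_equal(sum(y[sp$train] == 1), 4)
  expect_equal(length(sp$test), 2)
  expect_setequal(c(sp$train, sp$test), 1:10)
  expect_length(intersect(sp$train, sp$test), 0)
})

test_that("77-row cohort splits keep class proportions within one sample", {
  tb <- generate_feature_table(table_spec(n_samples = 77, n_features = 5))
  for (s in 1:5) {
    sp <- stratified_split(tb, 0.8, seed = s)
    y <- ft_labels(tb)
    expect_equal(sum(y[sp$train] == 0), 24)  # round(30 * 0.8)
    expect_equal(sum(y[sp$train] == 1), 38)  # round(47 * 0.8)
    expect_equal(length(sp$train), 62)
    prop_train <- mean(y[sp$train])
    expect_lt(abs(prop_train - 47 / 77), 1 / length(sp$train) + 1e-9)
  }
  expect_error(stratified_split(tb, 0.99), "empty")
})

small_eval_setup <- function(n = 24, p = 6, k = 1, effect = 4, seed = 5) {
  list(table = small_table(n = n, p = p, k = k, effect = effect, seed = seed,
                           fractions = c(0.5, 0.5)),
       ga = ga_config(population_size = 8, generations = 4),
       split = split_config(n_repeats = 4, master_seed = 9))
}

test_that("a perfect separator yields AUC 1 in every repeat of both procedures", {
  tb <- perfect_table(n = 24, p = 4)
  ga <- ga_config(population_size = 10, generations = 6)
  sc <- split_config(n_repeats = 4, master_seed = 3)
  for (proc in c("A", "B")) {
    res <- run_procedure(tb, ga, sc, proc)
    aucs <- vapply(res$per_repeat, `[[`, numeric(1), "test_auc")
    expect_equal(aucs, rep(1, 4))
  }
})

test_that("procedure results are reproducible and internally consistent", {
  s <- small_eval_setup()
  r1 <- run_procedure(s$table, s$ga, s$split, "B")
  r2 <- run_procedure(s$table, s$ga, s$split, "B")
  expect_identical(r1$per_repeat, r2$per_repeat)
  aucs <- vapply(r1$per_repeat, `[[`, numeric(1), "test_auc")
  expect_equal(r1$mean_auc, mean(aucs), tolerance = 1e-12)
  expect_equal(r1$sd_auc, sd(aucs), tolerance = 1e-12)
  expect_length(r1$per_repeat, s$split$n_repeats)
})

test_that("n_repeats = 1 reproduces a manual GA + split + fit composition", {
  s <- small_eval_setup()
  sc1 <- split_config(n_repeats = 1, master_seed = 9)
  res <- run_procedure(s$table, s$ga, sc1, "A")
  # manual recomposition with the same derived seeds
  split_seed <- derive_seed(9, 1, "split")
  ga_seed <- derive_seed(9, 1, "ga")
  cfg <- s$ga; cfg$seed <- ga_seed
  sel <- selection_mask(evolve(s$table, cfg))
  sp <- stratified_split(s$table, 0.8, split_seed)
  expect_identical(res$per_repeat[[1]]$selected_names, sel)
  expect_equal(res$per_repeat[[1]]$test_auc,
               zotga:::final_test_auc(s$table, sp, sel))
})

test_that("procedures A and B face identical split sequences", {
  s <- small_eval_setup()
  a <- run_procedure(s$table, s$ga, s$split, "A")
  b <- run_procedure(s$table, s$ga, s$split, "B")
  expect_identical(vapply(a$per_repeat, `[[`, integer(1), "split_seed"),
                   vapply(b$per_repeat, `[[`, integer(1), "split_seed"))
})

test_that("test rows are isolated from selection in procedure B", {
  s <- small_eval_setup(n = 30, p = 8)
  for (ms in c(9, 10)) {
    sc1 <- split_config(n_repeats = 1, master_seed = ms)
    b1 <- run_procedure(s$table, s$ga, sc1, "B")
    # scramble the test rows' feature values for this repeat's split
    sp <- stratified_split(s$table, 0.8, derive_seed(ms, 1, "split"))
    tb2 <- as.data.frame(s$table)
    for (j in 3:ncol(tb2))
      tb2[sp$test, j] <- rev(tb2[sp$test, j]) + 100
    tb2 <- new_feature_table(tb2, provenance = list())
    b2 <- run_procedure(tb2, s$ga, sc1, "B")
    expect_identical(b1$per_repeat[[1]]$selected_names,
                     b2$per_repeat[[1]]$selected_names)
  }
})

test_that("leakage gap arithmetic and provenance checks", {
  s <- small_eval_setup()
  a <- run_procedure(s$table, s$ga, s$split, "A")
  b <- run_procedure(s$table, s$ga, s$split, "B")
  expect_equal(leakage_gap(a, a), 0)
  auc_a <- mean(vapply(a$per_repeat, `[[`, numeric(1), "test_auc"))
  auc_b <- mean(vapply(b$per_repeat, `[[`, numeric(1), "test_auc"))
  expect_equal(leakage_gap(a, b), auc_a - auc_b, tolerance = 1e-12)
  other <- small_table(n = 24, p = 6, k = 0, seed = 99,
                       fractions = c(0.5, 0.5))
  a2 <- run_procedure(other, s$ga, s$split, "A")
  expect_error(leakage_gap(a2, b), "different tables")
})

test_that("selection rates count repeats exactly and rank deterministically", {
  s <- small_eval_setup()
  b <- run_procedure(s$table, s$ga, s$split, "B")
  rep_sets <- lapply(b$per_repeat, `[[`, "selected_names")
  sr <- selection_rates(b, top_k = 3)
  for (i in seq_len(nrow(sr$rates))) {
    f <- sr$rates$feature[i]
    manual <- 100 * mean(vapply(rep_sets, function(s) f %in% s, logical(1)))
    expect_equal(sr$rates$selection_rate_percent[i], manual)
  }
  expect_equal(nrow(sr$top_k), 3)
  r <- sr$rates$selection_rate_percent
  expect_true(all(diff(r) <= 0))
  # ties broken lexicographically (C collation)
  ties <- split(sr$rates$feature, sr$rates$selection_rate_percent)
  for (grp in ties)
    expect_identical(grp, sort(grp, method = "radix"))
  expect_true(all(sr$rates$region_tag %in% c("TUMOR", "ZOT")))
})

test_that("AUC summaries recompute and densities normalize", {
  s <- small_eval_setup(k = 1, effect = 2)
  b <- run_procedure(s$table, s$ga, s$split, "B")
  sm <- summarize_aucs(b)
  aucs <- vapply(b$per_repeat, `[[`, numeric(1), "test_auc")
  expect_equal(sm$mean, mean(aucs))
  expect_equal(sm$sd, sd(aucs))
  if (sd(aucs) > 0) {
    dx <- diff(sm$density$x)
    integral <- sum((sm$density$y[-1] + sm$density$y[-length(sm$density$y)]) /
                      2 * dx)
    expect_lt(abs(integral - 1), 1e-6)
  }
  # constant AUCs give sd 0
  tbp <- perfect_table(n = 24, p = 4)
  bp <- run_procedure(tbp, s$ga, split_config(n_repeats = 3, master_seed = 2))
  expect_equal(summarize_aucs(bp)$sd, 0)
})

test_that("procedure results serialize to JSON with recomputable summaries", {
  s <- small_eval_setup()
  b <- run_procedure(s$table, s$ga, s$split, "B")
  path <- withr::local_tempfile(fileext = ".json")
  write_procedure_result(b, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$mean_auc, b$mean_auc)
  expect_equal(mean(back$per_repeat$test_auc), b$mean_auc, tolerance = 1e-12)
})
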