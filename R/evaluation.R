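#' Repeated-split evaluation configuration
#'
#' Defaults reproduce the reference setup: stratified 80/20 train/test
#' splits repeated 100 times with fresh shuffles.
#'
#' @param train_fraction Fraction of each class assigned to training.
#' @param n_repeats Number of split repetitions.
#' @param master_seed Integer master seed; per-repeat seeds are derived with
#'   [derive_seed()] so the two procedures see identical split sequences.
#' @return A `split_config`.
#' @export
split_config <- function(train_fraction = 0.8, n_repeats = 100L,
                         master_seed = 1L) {
  stopifnot(train_fraction > 0, train_fraction < 1, n_repeats >= 1)
  structure(list(train_fraction = train_fraction,
                 n_repeats = as.integer(n_repeats),
                 master_seed = as.integer(master_seed)),
            class = "split_config")
}

#' Stratified train/test split
#'
#' Rows are partitioned per class: each class contributes
#' `round(n_class * train_fraction)` training rows (chosen by a seeded
#' shuffle) and the rest to the test set, keeping class proportions within
#' one sample of the cohort's on both sides.
#'
#' @param table A `feature_table` with both classes present.
#' @param train_fraction Training fraction in (0, 1).
#' @param seed Integer seed.
#' @return List with integer row indices `train` and `test` (disjoint,
#'   exhaustive).
#' @export
stratified_split <- function(table, train_fraction = 0.8, seed = 1L) {
  stopifnot(inherits(table, "feature_table"),
            train_fraction > 0, train_fraction < 1)
  y <- ft_labels(table)
  if (length(unique(y)) < 2L) stop("both classes must be present")
  train <- integer(0)
  with_seed(seed, {
    for (cls in c(0L, 1L)) {
      idx <- which(y == cls)
      n_tr <- as.integer(round(length(idx) * train_fraction))
      if (n_tr >= length(idx) || n_tr < 1L)
        stop("class ", cls, " would have an empty train or test share")
      train <- c(train, sample(idx)[seq_len(n_tr)])
    }
  })
  train <- sort(train)
  list(train = train, test = setdiff(seq_along(y), train))
}

# Fit the final decision tree on the training rows restricted to the
# selected features and return the test ROC AUC. An empty selection yields
# constant scores, hence AUC 0.5 by the tie convention.
final_test_auc <- function(table, split, selected) {
  X <- ft_features(table)
  y <- ft_labels(table)
  sel <- match(selected, colnames(X))
  if (anyNA(sel)) stop("selected features missing from table")
  if (length(sel) == 0L) return(0.5)
  scores <- cart_tree_predict(X[split$train, sel, drop = FALSE],
                              y[split$train],
                              X[split$test, sel, drop = FALSE])
  roc_auc(scores, y[split$test])
}

#' Run one evaluation procedure over repeated stratified splits
#'
#' Two pipeline variants differ only in where feature selection sits:
#' * **Procedure A** (`run_procedure_a()`): the GA selects features on the
#'   *whole* table, then the data are split 80/20, a decision tree is fit on
#'   the training rows restricted to the selected features, and ROC AUC is
#'   measured on the test rows. Selection has seen the test data — this is
#'   the leakage-prone design.
#' * **Procedure B** (`run_procedure_b()`): the split comes first and the GA
#'   sees only the training rows (a guard asserts no test row reaches the
#'   selection stage), so the test set stays untouched until scoring.
#'
#' Per-repeat seeds are derived from the master seed and the repeat index,
#' with the split-stage seeds shared between procedures: on the same table
#' and configs, A and B face the identical sequence of splits, isolating
#' selection placement as the only difference.
#'
#' @param table A `feature_table`.
#' @param ga_config A [ga_config()]; its `seed` field is overridden per
#'   repeat.
#' @param split_cfg A [split_config()].
#' @param procedure `"A"` or `"B"`.
#' @return A `procedure_result`: list with `procedure`, `per_repeat` (list
#'   of `test_auc`, `selected_names`, `split_seed`, `empty_selection`
#'   entries), `mean_auc`, `sd_auc`, `feature_names`, `n_repeats`,
#'   `provenance`.
#' @export
run_procedure <- function(table, ga_config = ga_config(),
                          split_cfg = split_config(),
                          procedure = c("A", "B")) {
  procedure <- match.arg(procedure)
  stopifnot(inherits(table, "feature_table"),
            inherits(split_cfg, "split_config"))
  per_repeat <- vector("list", split_cfg$n_repeats)
  for (r in seq_len(split_cfg$n_repeats)) {
    split_seed <- derive_seed(split_cfg$master_seed, r, "split")
    ga_seed <- derive_seed(split_cfg$master_seed, r, "ga")
    cfg_r <- ga_config
    cfg_r$seed <- ga_seed
    split <- stratified_split(table, split_cfg$train_fraction, split_seed)
    if (procedure == "A") {
      sel_res <- evolve(table, cfg_r)
    } else {
      train_tbl <- ft_restrict(table, split$train, role = "train")
      sel_res <- evolve(train_tbl, cfg_r,
                        forbidden_ids = table$patient_id[split$test])
    }
    selected <- selection_mask(sel_res)
    per_repeat[[r]] <- list(
      test_auc = final_test_auc(table, split, selected),
      selected_names = selected,
      split_seed = split_seed,
      empty_selection = length(selected) == 0L)
  }
  aucs <- vapply(per_repeat, `[[`, numeric(1), "test_auc")
  structure(list(procedure = procedure,
                 per_repeat = per_repeat,
                 mean_auc = mean(aucs),
                 sd_auc = sd(aucs),
                 feature_names = colnames(ft_features(table)),
                 n_repeats = split_cfg$n_repeats,
                 provenance = list(table_hash = ft_provenance(table)$hash,
                                   ga_config = unclass(ga_config),
                                   split_config = unclass(split_cfg))),
            class = "procedure_result")
}

#' @rdname run_procedure
#' @export
run_procedure_a <- function(table, ga_config = ga_config(),
                            split_cfg = split_config()) {
  run_procedure(table, ga_config, split_cfg, "A")
}

#' @rdname run_procedure
#' @export
run_procedure_b <- function(table, ga_config = ga_config(),
                            split_cfg = split_config()) {
  run_procedure(table, ga_config, split_cfg, "B")
}

#' @export
print.procedure_result <- function(x, ...) {
  cat("<procedure_result ", x$procedure, "> ", x$n_repeats,
      " repeats | mean test AUC ", sprintf("%.3f", x$mean_auc),
      " (sd ", sprintf("%.3f", x$sd_auc), ")\n", sep = "")
  invisible(x)
}

procedure_aucs <- function(result) {
  vapply(result$per_repeat, `[[`, numeric(1), "test_auc")
}

#' Leakage gap between the two procedures
#'
#' The mean test AUC of Procedure A (selection before split) minus that of
#' Procedure B (selection after split) on the same table: the optimism
#' attributable to feature-selection leakage. Both results must come from
#' the same table and repeat count.
#'
#' @param result_a,result_b `procedure_result`s for procedures A and B.
#' @return A single number, `mean_auc(A) - mean_auc(B)`.
#' @export
leakage_gap <- function(result_a, result_b) {
  stopifnot(inherits(result_a, "procedure_result"),
            inherits(result_b, "procedure_result"))
  if (!identical(result_a$provenance$table_hash,
                 result_b$provenance$table_hash) ||
      result_a$n_repeats != result_b$n_repeats)
    stop("results come from different tables or repeat counts")
  result_a$mean_auc - result_b$mean_auc
}

#' Per-feature selection rates across repetitions
#'
#' For every feature column, the percentage of repetitions whose best genome
#' selected it — the pipeline's feature-importance measure. The top-k
#' listing annotates each feature with its region (tumor vs ZOT) and filter
#' (wavelet/Laplacian) tags; rate ties are broken lexicographically by
#' rendered name.
#'
#' @param result A `procedure_result`.
#' @param top_k Number of features in the ranked listing.
#' @return A `selection_rate_report`: list with `rates` (data frame over all
#'   features: `feature`, `selection_rate_percent`, `region_tag`,
#'   `filter_tag`) and `top_k` (head of the ranking).
#' @export
selection_rates <- function(result, top_k = 10L) {
  stopifnot(inherits(result, "procedure_result"),
            length(result$per_repeat) > 0)
  counts <- integer(length(result$feature_names))
  names(counts) <- result$feature_names
  for (rep in result$per_repeat) {
    hit <- match(rep$selected_names, result$feature_names)
    counts[hit] <- counts[hit] + 1L
  }
  rates <- data.frame(
    feature = result$feature_names,
    selection_rate_percent = 100 * counts / result$n_repeats,
    region_tag = feature_region_tags(result$feature_names),
    filter_tag = feature_filter_tags(result$feature_names),
    row.names = NULL)
  ord <- order(-rates$selection_rate_percent, rates$feature,
               method = "radix")
  rates <- rates[ord, ]
  rownames(rates) <- NULL
  structure(list(rates = rates,
                 top_k = head(rates, top_k),
                 n_repeats = result$n_repeats,
                 procedure = result$procedure),
            class = "selection_rate_report")
}

#' @export
print.selection_rate_report <- function(x, ...) {
  cat("<selection_rate_report> procedure", x$procedure, "over", x$n_repeats,
      "repeats; top features:\n")
  print(x$top_k, row.names = FALSE)
  invisible(x)
}

#' Summarize a procedure's AUC distribution
#'
#' Mean, standard deviation, histogram and kernel-density series of the
#' per-repeat test AUCs, ready for probability-density plotting or JSON
#' export. The density is renormalized to integrate to 1 over its support.
#'
#' @param result A `procedure_result`.
#' @param bins Number of histogram bins.
#' @return List with `mean`, `sd`, `n`, `histogram` (`mids`, `density`),
#'   `density` (`x`, `y`).
#' @export
summarize_aucs <- function(result, bins = 20L) {
  stopifnot(inherits(result, "procedure_result"),
            length(result$per_repeat) > 0)
  aucs <- procedure_aucs(result)
  h <- graphics::hist(aucs, breaks = bins, plot = FALSE)
  if (sd(aucs) > 0) {
    d <- density(aucs)
    dx <- diff(d$x)
    norm <- sum((d$y[-1] + d$y[-length(d$y)]) / 2 * dx)
    dens <- list(x = d$x, y = d$y / norm)
  } else {
    dens <- list(x = aucs[1], y = Inf)
  }
  list(mean = mean(aucs), sd = sd(aucs), n = length(aucs),
       histogram = list(mids = h$mids, density = h$density),
       density = dens)
}

#' Serialize a procedure result to JSON
#'
#' @param result A `procedure_result`.
#' @param path JSON file path.
#' @export
write_procedure_result <- function(result, path) {
  stopifnot(inherits(result, "procedure_result"))
  obj <- list(procedure = result$procedure,
              n_repeats = result$n_repeats,
              mean_auc = result$mean_auc,
              sd_auc = result$sd_auc,
              per_repeat = lapply(result$per_repeat, function(r)
                list(test_auc = r$test_auc, split_seed = r$split_seed,
                     selected_names = I(r$selected_names))))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Density plot of the two procedures' AUC distributions
#'
#' Convenience \pkg{ggplot2} figure comparing the test-AUC probability
#' densities of procedures A and B with dashed mean lines. Requires
#' \pkg{ggplot2} (Suggests).
#'
#' @param result_a,result_b `procedure_result`s.
#' @return A ggplot object.
#' @export
plot_auc_distributions <- function(result_a, result_b) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  df <- rbind(
    data.frame(procedure = result_a$procedure, auc = procedure_aucs(result_a)),
    data.frame(procedure = result_b$procedure, auc = procedure_aucs(result_b)))
  means <- aggregate(auc ~ procedure, df, mean)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$auc, fill = .data$procedure)) +
    ggplot2::geom_density(alpha = 0.4) +
    ggplot2::geom_vline(data = means,
                        ggplot2::aes(xintercept = .data$auc,
                                     color = .data$procedure),
                        linetype = "dashed") +
    ggplot2::labs(x = "test ROC AUC", y = "density") +
    ggplot2::theme_minimal()
}
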