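#' GA configuration for wrapper feature selection
#'
#' Defaults follow the reference analysis: 150 genomes evolved for 100
#' generations, fitness = mean ROC AUC of a decision tree over stratified
#' five-fold cross-validation. Operators (not dictated by the analysis) are
#' standard robust choices: tournament selection of size 3, uniform
#' crossover at rate 0.9, per-gene bit-flip mutation at 1/L, elitism of 1.
#'
#' @param population_size Number of genomes per generation (>= 2).
#' @param generations Number of generations.
#' @param cv_folds Cross-validation folds for the fitness.
#' @param tournament_size Tournament size for parent selection.
#' @param crossover_rate Probability a child is produced by uniform
#'   crossover (otherwise a clone of the first parent).
#' @param per_gene_mutation_rate Bit-flip probability per gene; `NULL` means
#'   `1/L` where `L` is the number of feature columns.
#' @param elitism_count Number of best genomes copied unchanged into the
#'   next generation.
#' @param seed Integer seed; the whole run is a pure function of
#'   `(table, config)`.
#' @return A `ga_config` object.
#' @export
ga_config <- function(population_size = 150L, generations = 100L,
                      cv_folds = 5L, tournament_size = 3L,
                      crossover_rate = 0.9, per_gene_mutation_rate = NULL,
                      elitism_count = 1L, seed = 1L) {
  stopifnot(population_size >= 2, generations >= 1, cv_folds >= 2,
            tournament_size >= 1, crossover_rate >= 0, crossover_rate <= 1,
            elitism_count >= 0, elitism_count < population_size)
  structure(list(population_size = as.integer(population_size),
                 generations = as.integer(generations),
                 cv_folds = as.integer(cv_folds),
                 tournament_size = as.integer(tournament_size),
                 crossover_rate = crossover_rate,
                 per_gene_mutation_rate = per_gene_mutation_rate,
                 elitism_count = as.integer(elitism_count),
                 seed = as.integer(seed)),
            class = "ga_config")
}

# Stratified fold assignment: shuffles within class, then deals rows to
# folds round-robin so every fold holds both classes when each class has at
# least `k` members.
stratified_folds <- function(y, k, seed) {
  y <- as_binary_labels(y)
  if (min(table(y)) < k)
    stop("each class needs at least ", k, " members for ", k, "-fold CV")
  fold <- integer(length(y))
  with_seed(seed, {
    for (cls in c(0L, 1L)) {
      idx <- sample(which(y == cls))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

# Mean decision-tree ROC AUC over precomputed CV folds for the columns
# selected by `bits`. All-zero genomes score 0.5 (chance) by convention.
dtc_cv_auc <- function(X, y, bits, fold) {
  sel <- which(bits == 1L)
  if (length(sel) == 0L) return(0.5)
  Xs <- X[, sel, drop = FALSE]
  k <- max(fold)
  aucs <- vapply(seq_len(k), function(f) {
    tr <- fold != f
    scores <- cart_tree_predict(Xs[tr, , drop = FALSE], y[tr],
                                Xs[!tr, , drop = FALSE])
    roc_auc(scores, y[!tr])
  }, numeric(1))
  mean(aucs)
}

#' Fitness of one genome: cross-validated decision-tree ROC AUC
#'
#' Features at 1-bits are kept, features at 0-bits are excluded; a decision
#' tree is fit on the selected columns of the training folds of a seeded
#' stratified k-fold partition and scored by ROC AUC (from leaf class
#' fractions, ties at 1/2) on each held-out fold. Returns the fold mean.
#'
#' @param genome Binary 0/1 vector of length `ncol(features)`.
#' @param table A `feature_table` with at least `cv_folds` members per class.
#' @param cv_folds Number of folds (default 5).
#' @param seed Seed for the fold partition.
#' @return Fitness in `[0, 1]`; exactly 0.5 for the all-zero genome.
#' @export
genome_fitness <- function(genome, table, cv_folds = 5L, seed = 1L) {
  X <- ft_features(table)
  y <- ft_labels(table)
  bits <- as.integer(genome)
  if (length(bits) != ncol(X))
    stop("genome length must match the number of feature columns")
  if (!all(bits %in% c(0L, 1L))) stop("genome bits must be 0/1")
  fold <- stratified_folds(y, cv_folds, seed)
  dtc_cv_auc(X, y, bits, fold)
}

#' Evolve a feature-selection genome population
#'
#' Binary genomes over the table's feature columns are initialized uniformly
#' at random and evolved by tournament selection, uniform crossover,
#' per-gene bit-flip mutation and elitism, with fitness
#' `genome_fitness()`-style cross-validated decision-tree ROC AUC (the fold
#' partition is drawn once per run so fitness is a pure function of the
#' bits, enabling caching). Returns the best genome ever evaluated.
#'
#' @param table A `feature_table`.
#' @param config A [ga_config()].
#' @param forbidden_ids Optional character vector of patient ids that must
#'   NOT be present in `table`; the run aborts if any is found. Used by the
#'   leakage-safe evaluation pipeline to assert that feature selection never
#'   sees test rows.
#' @return A `selection_result`: list with `best_genome` (list `bits`,
#'   `fitness`), `fitness_history` (best fitness per generation,
#'   non-decreasing when `elitism_count >= 1`), `selected_names`, and
#'   `n_evaluations` (unique genomes evaluated).
#' @export
evolve <- function(table, config = ga_config(), forbidden_ids = NULL) {
  stopifnot(inherits(table, "feature_table"), inherits(config, "ga_config"))
  if (!is.null(forbidden_ids) && any(table$patient_id %in% forbidden_ids))
    stop("leakage guard tripped: feature selection was handed rows ",
         "reserved for testing")
  X <- ft_features(table)
  y <- ft_labels(table)
  L <- ncol(X)
  mu <- if (is.null(config$per_gene_mutation_rate)) 1 / L
        else config$per_gene_mutation_rate
  pop_n <- config$population_size

  fold <- stratified_folds(y, config$cv_folds,
                           derive_seed(config$seed, 0L, "cvfolds"))
  cache <- new.env(parent = emptyenv())
  n_eval <- 0L
  fitness_of <- function(bits) {
    key <- rawToChar(as.raw(bits + 48L))
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    f <- dtc_cv_auc(X, y, bits, fold)
    n_eval <<- n_eval + 1L
    cache[[key]] <- f
    f
  }

  with_seed(derive_seed(config$seed, 0L, "evolve"), {
    pop <- matrix(as.integer(runif(pop_n * L) < 0.5), nrow = pop_n)
    best_bits <- NULL
    best_fit <- -Inf
    history <- numeric(config$generations)
    for (gen in seq_len(config$generations)) {
      fit <- apply(pop, 1L, fitness_of)
      gb <- which.max(fit)
      if (fit[gb] > best_fit) {
        best_fit <- fit[gb]
        best_bits <- pop[gb, ]
      }
      history[gen] <- best_fit
      if (gen == config$generations) break
      ord <- order(fit, decreasing = TRUE)
      nxt <- matrix(0L, pop_n, L)
      n_elite <- config$elitism_count
      if (n_elite > 0) nxt[seq_len(n_elite), ] <- pop[ord[seq_len(n_elite)], ]
      for (i in seq(n_elite + 1L, pop_n)) {
        p1 <- pop[tournament_pick(fit, config$tournament_size), ]
        child <- if (runif(1) < config$crossover_rate) {
          p2 <- pop[tournament_pick(fit, config$tournament_size), ]
          take <- runif(L) < 0.5
          ifelse(take, p1, p2)
        } else p1
        nflip <- rbinom(1L, L, mu)
        if (nflip > 0) {
          at <- sample.int(L, nflip)
          child[at] <- 1L - child[at]
        }
        nxt[i, ] <- child
      }
      pop <- nxt
    }
  })

  sel <- which(best_bits == 1L)
  structure(list(
    best_genome = list(bits = best_bits, fitness = best_fit),
    fitness_history = history,
    selected_names = colnames(X)[sel],
    n_evaluations = n_eval,
    provenance = list(table_hash = ft_provenance(table)$hash,
                      config = unclass(config))),
    class = "selection_result")
}

tournament_pick <- function(fit, size) {
  cand <- sample.int(length(fit), min(size, length(fit)))
  cand[which.max(fit[cand])]
}

#' Selected feature names of a selection result
#'
#' @param result A `selection_result` from [evolve()].
#' @return Character vector of feature names at 1-bits, in stable (column)
#'   order.
#' @export
selection_mask <- function(result) {
  stopifnot(inherits(result, "selection_result"))
  result$selected_names
}

#' @export
print.selection_result <- function(x, ...) {
  cat("<selection_result> best fitness", format(x$best_genome$fitness),
      "|", length(x$selected_names), "features selected |",
      length(x$fitness_history), "generations\n")
  invisible(x)
}

#' Serialize / deserialize a selection result as JSON
#'
#' Bits are stored as a compact 0/1 string, the fitness history as an array.
#'
#' @param result A `selection_result`.
#' @param path JSON file path.
#' @export
write_selection_result <- function(result, path) {
  stopifnot(inherits(result, "selection_result"))
  obj <- list(bits = paste(result$best_genome$bits, collapse = ""),
              fitness = result$best_genome$fitness,
              fitness_history = result$fitness_history,
              selected_names = result$selected_names,
              n_evaluations = result$n_evaluations)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_selection_result
#' @export
read_selection_result <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(
    best_genome = list(
      bits = as.integer(strsplit(obj$bits, "")[[1]]),
      fitness = obj$fitness),
    fitness_history = obj$fitness_history,
    selected_names = as.character(obj$selected_names),
    n_evaluations = obj$n_evaluations,
    provenance = NULL), class = "selection_result")
}
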