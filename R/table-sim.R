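#' Specification of a simulated radiomic feature table
#'
#' Emulates the statistical shape of a radiomic cohort table: `n_samples`
#' patients, two classes in fixed proportions, `n_features` iid standard
#' normal feature columns of which `k_informative` are shifted by
#' `effect_size` (standardized mean difference) in class-1 rows.
#' `k_informative = 0` is the null regime: labels carry no information about
#' any feature. The defaults mirror a 77-patient cohort split 39%/61%
#' between benign (RO, label 0) and malignant (ccRCC, label 1) histotypes.
#'
#' @param n_samples Positive integer number of rows.
#' @param n_features Positive integer number of feature columns.
#' @param class_fractions Numeric pair summing to 1: fractions of class 0 and
#'   class 1. Class counts are `round(n_samples * fraction)` for class 0 and
#'   the remainder for class 1.
#' @param k_informative Number of signal-bearing columns, `<= n_features`.
#' @param effect_size Standardized mean shift applied to informative columns
#'   in class-1 rows (>= 0).
#' @param seed Integer seed.
#' @return A validated `table_spec` object.
#' @examples
#' table_spec(n_samples = 77)  # cohort-emulation defaults: classes 30/47
#' @export
table_spec <- function(n_samples = 77L, n_features = 2436L,
                       class_fractions = c(0.39, 0.61),
                       k_informative = 0L, effect_size = 0,
                       seed = 1L) {
  stopifnot(n_samples >= 2, n_features >= 1,
            length(class_fractions) == 2L, all(class_fractions > 0),
            abs(sum(class_fractions) - 1) < 1e-8,
            k_informative >= 0, effect_size >= 0)
  if (k_informative > n_features)
    stop("k_informative must not exceed n_features")
  structure(list(n_samples = as.integer(n_samples),
                 n_features = as.integer(n_features),
                 class_fractions = as.numeric(class_fractions),
                 k_informative = as.integer(k_informative),
                 effect_size = effect_size, seed = as.integer(seed)),
            class = "table_spec")
}

#' Simulate a radiomic feature table
#'
#' Columns are iid standard normal; the first `k_informative` columns (in a
#' random position set recorded in provenance) get a mean shift of
#' `effect_size` in class-1 rows. Labels are assigned by exact counts
#' (rounded from `class_fractions`) and shuffled, so class proportions are
#' deterministic while row order is random. Column names follow the rendered
#' radiomic naming convention so name-parsing code downstream sees realistic
#' input; half the columns are tagged as ZOT-region features.
#'
#' @param spec A [table_spec()].
#' @return A `feature_table`: data frame with `patient_id`, `label`, then
#'   feature columns; attribute `provenance` records the spec, the informative
#'   column names and a content hash.
#' @export
generate_feature_table <- function(spec) {
  stopifnot(inherits(spec, "table_spec"))
  n <- spec$n_samples; p <- spec$n_features
  n0 <- as.integer(round(n * spec$class_fractions[1]))
  n1 <- n - n0
  if (n0 < 1 || n1 < 1) stop("each class needs at least one sample")
  with_seed(spec$seed, {
    labels <- sample(rep(c(0L, 1L), c(n0, n1)))
    X <- matrix(rnorm(n * p), n, p)
    informative <- if (spec$k_informative > 0)
      sort(sample.int(p, spec$k_informative)) else integer(0)
    if (length(informative))
      X[labels == 1L, informative] <- X[labels == 1L, informative] +
        spec$effect_size
  })
  colnames(X) <- simulated_feature_names(p)
  tbl <- data.frame(patient_id = sprintf("P%03d", seq_len(n)),
                    label = labels, check.names = FALSE)
  tbl <- cbind(tbl, as.data.frame(X, check.names = FALSE))
  new_feature_table(tbl, provenance = list(
    source = "simulated", spec = unclass(spec),
    informative = colnames(X)[informative]))
}

# Deterministic rendered feature names for simulated tables: cycles through
# filter tags and marks the second half as ZOT-region columns.
simulated_feature_names <- function(p) {
  filters <- c("", "W-LLL_", "W-HHH_", "L-2.0_")
  vapply(seq_len(p), function(j) {
    nm <- paste0(filters[(j - 1L) %% length(filters) + 1L],
                 sprintf("firstorder_Sim%04d", j))
    if (j > p / 2) nm <- paste0(nm, "(ZOT)")
    nm
  }, character(1))
}
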