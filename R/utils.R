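#' @useDynLib zotga, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats aggregate density median quantile rbinom rnorm runif sd var
#' @importFrom utils head write.csv read.csv
NULL

#' Derive a reproducible child seed from a master seed
#'
#' Deterministic integer hashing of `(master_seed, index, tag)` onto
#' `[1, 2^31 - 2]`, used throughout the package to give every repetition and
#' pipeline stage its own independent seed without sharing RNG state. The hash
#' is a fixed Lehmer-style polynomial over the tag characters, the master seed
#' and the index, so derived seeds are order-independent: item 57 of a cohort
#' has the same seed whether or not items 1..56 were generated.
#'
#' @param master_seed Integer master seed.
#' @param index Non-negative integer (repetition or item index).
#' @param tag Short character tag naming the stage (e.g. `"split"`, `"ga"`).
#' @return A single integer in `[1, 2^31 - 2]`.
#' @examples
#' derive_seed(42, 1, "split")
#' derive_seed(42, 1, "split") == derive_seed(42L, 1L, "split")
#' @export
derive_seed <- function(master_seed, index = 0L, tag = "") {
  stopifnot(length(master_seed) == 1L, is.finite(master_seed),
            length(index) == 1L, index >= 0)
  m <- 2147483647  # 2^31 - 1, Mersenne prime; all arithmetic stays < 2^53
  a <- 69621       # Lehmer multiplier, keeps a * h below 2^48
  h <- 17
  for (code in utf8ToInt(tag)) h <- (a * h + code) %% m
  h <- (a * h + (as.double(master_seed) %% m)) %% m
  h <- (a * h + (as.double(index) %% m)) %% m
  as.integer(h %% (m - 2) + 1)
}

# Evaluate `expr` under a local RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

#' Area under the ROC curve from scores
#'
#' Mann-Whitney (midrank) estimator: the probability that a random positive
#' scores above a random negative, with tied score pairs counted 1/2. This is
#' the convention needed for the piecewise-constant scores a decision tree
#' produces (leaf class fractions generate many ties).
#'
#' @param scores Numeric vector of classifier scores (higher = more positive).
#' @param labels Binary vector (0/1, logical, or two-level factor with the
#'   second level as positive).
#' @return AUC in `[0, 1]`.
#' @examples
#' roc_auc(c(0.9, 0.8, 0.3, 0.1), c(1, 1, 0, 0))  # 1
#' roc_auc(c(0.5, 0.5, 0.5, 0.5), c(1, 1, 0, 0))  # 0.5 by tie convention
#' @export
roc_auc <- function(scores, labels) {
  y <- as_binary_labels(labels)
  stopifnot(length(scores) == length(y))
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  if (n1 == 0L || n0 == 0L) stop("roc_auc() needs both classes present")
  r <- rank(scores, ties.method = "average")
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Coerce labels to integer 0/1.
as_binary_labels <- function(labels) {
  if (is.factor(labels)) labels <- as.integer(labels) - 1L
  if (is.logical(labels)) labels <- as.integer(labels)
  u <- unique(labels)
  if (!all(u %in% c(0L, 1L))) stop("labels must be binary (0/1)")
  as.integer(labels)
}

# Content hash used for provenance stamps (md5 of the serialized object).
content_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f), add = TRUE)
  saveRDS(x, f, version = 2, compress = FALSE)
  unname(tools::md5sum(f))
}
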