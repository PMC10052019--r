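#' Radiomic feature naming convention
#'
#' Rendered names encode three fields: an optional filter tag prefixed to the
#' base name (`W-<subband>_` for wavelet subbands, `L-<sigma>_` for
#' Laplacian-of-Gaussian responses), the base feature name
#' (`<class>_<Descriptor>`, e.g. `firstorder_Mean`, `shape_VoxelCount`), and
#' an optional region suffix `(ZOT)` marking features computed on the
#' zone-of-transition shell rather than the tumor. Examples:
#' `firstorder_Mean`, `W-LLH_firstorder_Entropy(ZOT)`,
#' `L-2.0_firstorder_P50`.
#'
#' @param base_name Base feature name string.
#' @param filter_tag `""` (unfiltered), `"W-<subband>"`, or `"L-<sigma>"`.
#' @param region_tag `""` (unset), `"TUMOR"`, or `"ZOT"`.
#' @return `feature_name()`: a `feature_name` record (list).
#'   `render_feature_name()`: a string. `parse_feature_name()`: a
#'   `feature_name` record; round-trips with rendering.
#' @examples
#' render_feature_name(feature_name("firstorder_Mean", "W-LLH", "ZOT"))
#' parse_feature_name("L-2.0_shape_VoxelCount")
#' @export
feature_name <- function(base_name, filter_tag = "", region_tag = "") {
  stopifnot(is.character(base_name), nchar(base_name) > 0)
  if (!(filter_tag == "" || grepl("^[WL]-", filter_tag)))
    stop("filter_tag must be '', 'W-<subband>' or 'L-<sigma>'")
  if (!region_tag %in% c("", "TUMOR", "ZOT"))
    stop("region_tag must be '', 'TUMOR' or 'ZOT'")
  structure(list(base_name = base_name, filter_tag = filter_tag,
                 region_tag = region_tag), class = "feature_name")
}

#' @rdname feature_name
#' @param fn A `feature_name`.
#' @export
render_feature_name <- function(fn) {
  stopifnot(inherits(fn, "feature_name"))
  out <- fn$base_name
  if (fn$filter_tag != "") out <- paste0(fn$filter_tag, "_", out)
  if (fn$region_tag == "ZOT") out <- paste0(out, "(ZOT)")
  out
}

#' @rdname feature_name
#' @param name Rendered feature-name string.
#' @export
parse_feature_name <- function(name) {
  stopifnot(is.character(name), length(name) == 1L)
  region <- ""
  if (grepl("\\(ZOT\\)$", name)) {
    region <- "ZOT"
    name <- sub("\\(ZOT\\)$", "", name)
  }
  filter <- ""
  m <- regmatches(name, regexpr("^[WL]-[^_]+", name))
  if (length(m) == 1L && grepl(paste0("^", gsub("([.-])", "\\\\\\1", m), "_"),
                               name)) {
    filter <- m
    name <- sub("^[WL]-[^_]+_", "", name)
  }
  feature_name(name, filter, region)
}

# Vectorized tag helpers for reports.
feature_region_tags <- function(names) {
  ifelse(grepl("\\(ZOT\\)$", names), "ZOT", "TUMOR")
}

feature_filter_tags <- function(names) {
  m <- regmatches(names, regexpr("^[WL]-[^_]+(?=_)", names, perl = TRUE))
  out <- character(length(names))
  has <- grepl("^[WL]-[^_]+_", names)
  out[has] <- regmatches(names[has],
                         regexpr("^[WL]-[^_]+", names[has]))
  out
}
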