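# Internal helpers shared across modules.

#' @importFrom rlang .data abort warn inform
#' @importFrom tibble tibble as_tibble
NULL

DEG2RAD <- pi / 180

# Derive a reproducible child seed from (seed, index); stays below 2^31.
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + as.double(index) * 16807) %% 2147483587)
}

# Wrap angles (degrees) into [low, low + span) per dimension.
wrap_angles <- function(angles, ranges) {
  low <- ranges$low
  span <- ranges$high - ranges$low
  wrapped <- low + ((angles - low) %% span)
  # %% can return span itself through floating point; fold back
  wrapped[wrapped >= ranges$high] <- low[wrapped >= ranges$high]
  wrapped
}

# Per-dimension circular or absolute angular difference in degrees.
# `ranges` is a tibble with columns low, high, periodic.
angle_diff <- function(a, b, ranges) {
  d <- abs(a - b)
  span <- ranges$high - ranges$low
  per <- ranges$periodic
  d[per] <- pmin(d[per] %% span[per], span[per] - (d[per] %% span[per]))
  d
}

# Canonical ranges tibble: full 360-degree periodic dims.
full_ranges <- function(D) {
  tibble(low = rep(0, D), high = rep(360, D), periodic = rep(TRUE, D))
}

as_ranges <- function(ranges, D = NULL) {
  if (is.null(ranges)) {
    if (is.null(D)) abort("either `ranges` or a dimension is required")
    return(full_ranges(D))
  }
  ranges <- as_tibble(ranges)
  if (!all(c("low", "high") %in% names(ranges))) {
    abort("`ranges` needs columns low and high")
  }
  if (is.null(ranges[["periodic"]])) ranges$periodic <- TRUE
  ranges
}

angle_cols <- function(D) paste0("angle_", seq_len(D))

pool_angles <- function(pool) {
  as.matrix(dplyr::select(pool, dplyr::starts_with("angle_")))
}
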