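#' Read an XYZ file
#'
#' Standard XYZ: atom-count line, comment line, then `element x y z` rows.
#' Multi-frame files concatenate such blocks.
#'
#' @param path File path.
#' @return A list of frames; each frame is a tibble with columns `element`,
#'   `x`, `y`, `z` and attribute `comment`.  For single-frame files the list
#'   has length one.
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  frames <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n)) abort(paste0("malformed XYZ count line at line ", i))
    comment <- if (i + 1L <= length(lines)) lines[i + 1L] else ""
    block <- lines[(i + 2L):(i + 1L + n)]
    parts <- strsplit(trimws(block), "\\s+")
    frame <- tibble(
      element = vapply(parts, `[`, "", 1L),
      x = as.numeric(vapply(parts, `[`, "", 2L)),
      y = as.numeric(vapply(parts, `[`, "", 3L)),
      z = as.numeric(vapply(parts, `[`, "", 4L))
    )
    attr(frame, "comment") <- comment
    frames[[length(frames) + 1L]] <- frame
    i <- i + 2L + n
  }
  frames
}

#' Write one or more structures to an XYZ file
#'
#' @param frames A single frame (tibble with `element`, `x`, `y`, `z`, or a
#'   `conformation` with coordinates plus a `molecule_spec` for elements) or
#'   a list of frames.
#' @param path Output path.
#' @param comments Character vector of per-frame comment lines.
#' @param spec Optional [molecule_spec()] supplying element symbols when
#'   frames are `conformation` objects or bare coordinate matrices.
#' @export
write_xyz <- function(frames, path, comments = NULL, spec = NULL) {
  if (inherits(frames, "conformation") || is.matrix(frames) ||
      (is.data.frame(frames))) {
    frames <- list(frames)
  }
  out <- character(0)
  for (k in seq_along(frames)) {
    f <- frames[[k]]
    if (inherits(f, "conformation")) f <- f$coords
    if (is.matrix(f)) {
      if (is.null(spec)) abort("element symbols required: pass `spec`")
      f <- tibble(element = spec$atoms$element,
                  x = f[, 1], y = f[, 2], z = f[, 3])
    }
    cm <- if (!is.null(comments)) comments[[k]] else
      (attr(f, "comment") %||% "")
    out <- c(out, nrow(f), cm,
             sprintf("%-3s %18.10f %18.10f %18.10f", f$element, f$x, f$y, f$z))
  }
  writeLines(out, path)
  invisible(path)
}
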