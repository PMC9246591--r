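#' Write an image grid as a plain-text grid
#'
#' One header line `# pixel_size=<value>` followed by n rows of n
#' whitespace-separated reals (full double precision); losslessly
#' round-trips through [read_image_txt()].
#'
#' @param grid An [image_grid()].
#' @param path Output file path.
#' @export
write_image_txt <- function(grid, path) {
  stopifnot(inherits(grid, "image_grid"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# pixel_size=%.17g", grid$pixel_size), con)
  utils::write.table(format(grid$values, digits = 17, trim = TRUE,
                            scientific = TRUE),
                     con, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read a plain-text image grid
#'
#' @param path File written by [write_image_txt()].
#' @return An [image_grid()].
#' @export
read_image_txt <- function(path) {
  lines <- readLines(path)
  if (!length(lines) || !grepl("^# pixel_size=", lines[1]))
    stop("line 1: expected header '# pixel_size=<value>' in ", path)
  ps <- as.numeric(sub("^# pixel_size=", "", lines[1]))
  body <- lines[-1]
  body <- body[nzchar(trimws(body))]
  rows <- lapply(seq_along(body), function(r) {
    tok <- strsplit(trimws(body[r]), "\\s+")[[1]]
    v <- suppressWarnings(as.numeric(tok))
    if (anyNA(v))
      stop("parse error at row ", r, ", column ", which(is.na(v))[1],
           ": non-numeric token '", tok[which(is.na(v))[1]], "'")
    v
  })
  nc <- lengths(rows)
  if (length(unique(nc)) != 1)
    stop("ragged rows: row ", which(nc != nc[1])[1], " has ",
         nc[which(nc != nc[1])[1]], " values, expected ", nc[1])
  image_grid(do.call(rbind, rows), ps)
}

#' Write an image grid as a plain (P2) PGM
#'
#' Values are affinely mapped from `[min, max]` (the grid's range unless
#' given) to `0..maxval` and rounded; the scaling is recorded in a comment
#' sidecar header line so the mapping is recoverable. Integer-valued grids
#' already inside `[0, maxval]` round-trip exactly when `lo = 0` and
#' `hi = maxval`.
#'
#' @param grid An [image_grid()].
#' @param path Output path.
#' @param maxval PGM maximum gray value (255 for 8-bit, up to 65535).
#' @param lo,hi Intensity range mapped to `0..maxval`; defaults to the
#'   grid's own range.
#' @export
write_pgm <- function(grid, path, maxval = 255, lo = NULL, hi = NULL) {
  stopifnot(inherits(grid, "image_grid"))
  if (maxval < 1 || maxval > 65535) stop("'maxval' must be in 1..65535")
  v <- grid$values
  if (is.null(lo)) lo <- min(v)
  if (is.null(hi)) hi <- max(v)
  if (hi <= lo) hi <- lo + 1
  scaled <- round((v - lo) / (hi - lo) * maxval)
  scaled <- pmin(pmax(scaled, 0), maxval)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2",
               sprintf("# min=%.17g max=%.17g pixel_size=%.17g", lo, hi,
                       grid$pixel_size),
               paste(grid$n, grid$n), as.character(maxval)), con)
  utils::write.table(scaled, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a plain (P2) PGM written by [write_pgm()]
#'
#' @param path PGM path.
#' @param rescale If `TRUE` (default) map gray levels back to the intensity
#'   range recorded in the sidecar comment; otherwise return raw levels.
#' @return An [image_grid()].
#' @export
read_pgm <- function(path, rescale = TRUE) {
  lines <- readLines(path)
  if (lines[1] != "P2") stop("line 1: expected plain PGM magic 'P2' in ", path)
  meta <- list(min = 0, max = 1, pixel_size = 1)
  body <- lines[-1]
  cm <- grepl("^#", body)
  for (cl in body[cm]) {
    for (kv in strsplit(sub("^#\\s*", "", cl), "\\s+")[[1]]) {
      p <- strsplit(kv, "=")[[1]]
      if (length(p) == 2) meta[[p[1]]] <- as.numeric(p[2])
    }
  }
  toks <- as.numeric(unlist(strsplit(trimws(body[!cm]), "\\s+")))
  toks <- toks[!is.na(toks)]
  w <- toks[1]; h <- toks[2]; maxval <- toks[3]
  px <- toks[-(1:3)]
  if (length(px) != w * h)
    stop("PGM payload has ", length(px), " samples, header promises ", w * h)
  m <- matrix(px, nrow = h, ncol = w, byrow = TRUE)
  if (rescale) m <- m / maxval * (meta$max - meta$min) + meta$min
  image_grid(m, meta$pixel_size)
}

#' Write a sinogram
#'
#' Text mode: header lines `# D=`, `# n_views=`, `# n_bins=`,
#' `# bin_spacing=` followed by one whitespace-separated row per view.
#' Binary mode: little-endian doubles in `path` plus the same text header in
#' a `.hdr` sidecar.
#'
#' @param sino A [sinogram()].
#' @param path Output path.
#' @param format `"text"` (default) or `"binary"`.
#' @export
write_sinogram <- function(sino, path, format = c("text", "binary")) {
  stopifnot(inherits(sino, "sinogram"))
  format <- match.arg(format)
  g <- sino$geometry
  hdr <- c(sprintf("# D=%.17g", g$D),
           sprintf("# n_views=%d", g$n_views),
           sprintf("# n_bins=%d", g$n_bins),
           sprintf("# bin_spacing=%.17g", g$bin_spacing))
  if (format == "text") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(hdr, con)
    utils::write.table(format(sino$values, digits = 17, trim = TRUE,
                              scientific = TRUE),
                       con, row.names = FALSE, col.names = FALSE,
                       quote = FALSE)
  } else {
    writeLines(hdr, paste0(path, ".hdr"))
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(as.vector(t(sino$values)), con, size = 8, endian = "little")
  }
  invisible(path)
}

#' Read a sinogram written by [write_sinogram()]
#'
#' @param path Input path.
#' @param format `"text"` or `"binary"`.
#' @return A [sinogram()].
#' @export
read_sinogram <- function(path, format = c("text", "binary")) {
  format <- match.arg(format)
  hdr_lines <- if (format == "text") readLines(path) else
    readLines(paste0(path, ".hdr"))
  meta <- list()
  for (cl in hdr_lines[grepl("^#", hdr_lines)]) {
    p <- strsplit(sub("^#\\s*", "", cl), "=")[[1]]
    if (length(p) == 2) meta[[p[1]]] <- as.numeric(p[2])
  }
  need <- c("D", "n_views", "n_bins", "bin_spacing")
  if (!all(need %in% names(meta)))
    stop("sinogram header missing field(s): ",
         paste(setdiff(need, names(meta)), collapse = ", "))
  geom <- fan_geometry(meta$D, meta$n_views, meta$n_bins, meta$bin_spacing)
  if (format == "text") {
    body <- hdr_lines[!grepl("^#", hdr_lines)]
    body <- body[nzchar(trimws(body))]
    rows <- lapply(body, function(l) as.numeric(strsplit(trimws(l), "\\s+")[[1]]))
    vals <- do.call(rbind, rows)
  } else {
    con <- file(path, "rb")
    on.exit(close(con))
    raw <- readBin(con, "double", n = meta$n_views * meta$n_bins + 1,
                   size = 8, endian = "little")
    if (length(raw) != meta$n_views * meta$n_bins)
      stop("binary payload length ", length(raw),
           " does not match header shape ", meta$n_views, "x", meta$n_bins)
    vals <- matrix(raw, meta$n_views, meta$n_bins, byrow = TRUE)
  }
  sinogram(vals, geom)   # the constructor enforces header/shape consistency
}

#' Write a phantom specification as YAML
#'
#' @param spec A [phantom_spec()].
#' @param path Output path.
#' @export
write_phantom_spec <- function(spec, path) {
  stopifnot(inherits(spec, "phantom_spec"))
  yaml::write_yaml(list(
    bounding_radius = spec$bounding_radius,
    ellipses = lapply(spec$ellipses, function(e)
      list(cx = e$cx, cy = e$cy, a = e$a, b = e$b,
           theta_deg = e$theta_deg, value = e$value))), path)
  invisible(path)
}

#' Read a phantom specification from YAML
#'
#' @param path YAML file with `bounding_radius` and a list of `ellipses`
#'   records (`cx, cy, a, b, theta_deg, value`).
#' @return A [phantom_spec()].
#' @export
read_phantom_spec <- function(path) {
  if (!file.exists(path)) stop("phantom spec file not found: ", path)
  y <- yaml::read_yaml(path)
  if (is.null(y$bounding_radius) || is.null(y$ellipses))
    stop("phantom spec must contain 'bounding_radius' and 'ellipses'")
  phantom_spec(lapply(y$ellipses, function(e)
    ellipse(e$cx, e$cy, e$a, e$b,
            if (is.null(e$theta_deg)) 0 else e$theta_deg,
            if (is.null(e$value)) 1 else e$value)),
    y$bounding_radius)
}
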