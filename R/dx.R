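# OpenDX scalar-grid reader/writer (the APBS dialect: regular grid, data
# listed with z varying fastest, three values per line).

#' Create a potential grid object
#'
#' @param origin Numeric length-3, grid origin in Angstrom.
#' @param spacing Numeric length-3, grid spacing per axis in Angstrom (> 0).
#' @param counts Integer length-3, number of nodes per axis.
#' @param values Numeric vector of `prod(counts)` node values in kT/e,
#'   ordered with z fastest (APBS/OpenDX convention).
#' @return A `potential_grid` object.
#' @export
potential_grid <- function(origin, spacing, counts, values) {
  origin <- as.numeric(origin)
  spacing <- as.numeric(spacing)
  counts <- as.integer(counts)
  stopifnot(
    length(origin) == 3L, length(spacing) == 3L, length(counts) == 3L,
    all(spacing > 0), all(counts >= 2L)
  )
  if (length(values) != prod(counts)) {
    stop(
      "grid value count ", length(values), " does not match counts ",
      paste(counts, collapse = "x"), " = ", prod(counts),
      call. = FALSE
    )
  }
  structure(
    list(origin = origin, spacing = spacing, counts = counts,
         values = as.numeric(values)),
    class = "potential_grid"
  )
}

#' @export
print.potential_grid <- function(x, ...) {
  cat(
    "<potential_grid> ", paste(x$counts, collapse = " x "), " nodes, origin (",
    paste(format(x$origin), collapse = ", "), ") A, spacing (",
    paste(format(x$spacing), collapse = ", "), ") A, values in kT/e\n",
    sep = ""
  )
  invisible(x)
}

#' Read an APBS OpenDX scalar grid
#'
#' Supports the subset of OpenDX emitted by APBS: `object 1 class
#' gridpositions counts nx ny nz`, `origin`, three `delta` records (assumed
#' axis-aligned), and a rank-0 data array with z varying fastest.
#'
#' @param source Path to a .dx file, or a character vector of its lines.
#' @return A [potential_grid()].
#' @export
read_dx <- function(source) {
  lines <- read_text_source(source)
  lines <- lines[!startsWith(trimws(lines), "#")]

  grab <- function(pattern) {
    hit <- grep(pattern, lines, value = TRUE)
    if (!length(hit)) stop("DX parse error: missing ", sQuote(pattern), call. = FALSE)
    hit[1]
  }
  nums <- function(s) as.numeric(strsplit(trimws(s), "\\s+")[[1]])

  counts_line <- grab("^object 1 class gridpositions counts")
  counts <- as.integer(nums(sub(".*counts", "", counts_line)))
  origin <- nums(sub("^origin", "", grab("^origin")))
  deltas <- grep("^delta", lines, value = TRUE)
  if (length(deltas) != 3L) stop("DX parse error: expected 3 delta records", call. = FALSE)
  dmat <- t(vapply(deltas, function(d) nums(sub("^delta", "", d)), numeric(3)))
  if (any(abs(dmat[upper.tri(dmat) | lower.tri(dmat)]) > 1e-12)) {
    stop("DX parse error: non-axis-aligned grid not supported", call. = FALSE)
  }
  spacing <- diag(dmat)

  data_at <- grep("^object 3 class array", lines)
  if (!length(data_at)) stop("DX parse error: missing data array object", call. = FALSE)
  body <- lines[(data_at[1] + 1L):length(lines)]
  stop_at <- grep("^(attribute|object|component|end)", body)
  if (length(stop_at)) body <- body[seq_len(stop_at[1] - 1L)]
  values <- as.numeric(unlist(strsplit(trimws(body[nzchar(trimws(body))]), "\\s+")))
  if (anyNA(values)) stop("DX parse error: non-numeric grid data", call. = FALSE)

  potential_grid(origin, spacing, counts, values)
}

#' Write a potential grid as APBS-style OpenDX text
#'
#' @param grid A [potential_grid()].
#' @param path Output path; when `NULL` the lines are returned invisibly
#'   without writing.
#' @param comment Optional comment line placed in the header.
#' @return Invisibly, the character vector of file lines.
#' @export
write_dx <- function(grid, path = NULL, comment = "scalar potential (kT/e)") {
  stopifnot(inherits(grid, "potential_grid"))
  n <- grid$counts
  header <- c(
    paste0("# ", comment),
    sprintf("object 1 class gridpositions counts %d %d %d", n[1], n[2], n[3]),
    sprintf("origin %.6e %.6e %.6e", grid$origin[1], grid$origin[2], grid$origin[3]),
    sprintf("delta %.6e %.6e %.6e", grid$spacing[1], 0, 0),
    sprintf("delta %.6e %.6e %.6e", 0, grid$spacing[2], 0),
    sprintf("delta %.6e %.6e %.6e", 0, 0, grid$spacing[3]),
    sprintf("object 2 class gridconnections counts %d %d %d", n[1], n[2], n[3]),
    sprintf(
      "object 3 class array type double rank 0 items %d data follows",
      prod(n)
    )
  )
  v <- sprintf("%.16e", grid$values)
  pad <- (3L - length(v) %% 3L) %% 3L
  if (pad) v <- c(v, rep("", pad))
  body <- apply(matrix(v, ncol = 3L, byrow = TRUE), 1L, paste, collapse = " ")
  body <- trimws(body)
  footer <- c(
    'attribute "dep" string "positions"',
    'object "regular positions regular connections" class field',
    'component "positions" value 1',
    'component "connections" value 2',
    'component "data" value 3'
  )
  out <- c(header, body, footer)
  if (!is.null(path)) writeLines(out, path)
  invisible(out)
}

#' Trilinear interpolation of a potential grid
#'
#' Evaluates the grid at arbitrary points by trilinear interpolation of the
#' eight surrounding nodes. Points outside the grid bounding box raise an
#' error — no extrapolation is attempted. The upper boundary faces belong to
#' the box (closed box; the cell index is clamped).
#'
#' @param grid A [potential_grid()].
#' @param points Numeric matrix (n x 3) or length-3 vector of coordinates in
#'   Angstrom.
#' @return Numeric vector of interpolated potentials in kT/e.
#' @export
interpolate_grid <- function(grid, points) {
  stopifnot(inherits(grid, "potential_grid"))
  p <- as_points(points)
  n <- grid$counts
  # fractional node coordinates per axis
  t_ <- sweep(sweep(p, 2L, grid$origin), 2L, grid$spacing, `/`)
  eps <- 1e-9
  lo <- t_ < -eps
  hi <- sweep(t_, 2L, n - 1L) > eps
  if (any(lo | hi)) {
    bad <- which(apply(lo | hi, 1L, any))[1]
    stop(
      sprintf(
        "point (%.3f, %.3f, %.3f) outside grid bounding box",
        p[bad, 1], p[bad, 2], p[bad, 3]
      ),
      call. = FALSE
    )
  }
  t_ <- pmin(pmax(t_, 0), matrix(n - 1L, nrow(t_), 3L, byrow = TRUE))
  i0 <- pmin(floor(t_), matrix(n - 2L, nrow(t_), 3L, byrow = TRUE))
  f <- t_ - i0

  val <- function(ix, iy, iz) {
    grid$values[(ix * n[2] + iy) * n[3] + iz + 1L] # z fastest
  }
  v000 <- val(i0[, 1], i0[, 2], i0[, 3])
  v001 <- val(i0[, 1], i0[, 2], i0[, 3] + 1L)
  v010 <- val(i0[, 1], i0[, 2] + 1L, i0[, 3])
  v011 <- val(i0[, 1], i0[, 2] + 1L, i0[, 3] + 1L)
  v100 <- val(i0[, 1] + 1L, i0[, 2], i0[, 3])
  v101 <- val(i0[, 1] + 1L, i0[, 2], i0[, 3] + 1L)
  v110 <- val(i0[, 1] + 1L, i0[, 2] + 1L, i0[, 3])
  v111 <- val(i0[, 1] + 1L, i0[, 2] + 1L, i0[, 3] + 1L)

  fx <- f[, 1]; fy <- f[, 2]; fz <- f[, 3]
  c00 <- v000 * (1 - fx) + v100 * fx
  c01 <- v001 * (1 - fx) + v101 * fx
  c10 <- v010 * (1 - fx) + v110 * fx
  c11 <- v011 * (1 - fx) + v111 * fx
  c0 <- c00 * (1 - fy) + c10 * fy
  c1 <- c01 * (1 - fy) + c11 * fy
  c0 * (1 - fz) + c1 * fz
}

as_points <- function(points) {
  if (is.null(dim(points))) {
    stopifnot(length(points) == 3L)
    points <- matrix(points, nrow = 1L)
  }
  p <- as.matrix(points)
  storage.mode(p) <- "double"
  stopifnot(ncol(p) == 3L)
  p
}
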