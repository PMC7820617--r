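#' Read and write NRRD volumes (ASCII encoding)
#'
#' Minimal NRRD I/O for scalar voxel volumes and 3-component vector fields
#' (displacement fields, mm). Data are stored with `encoding: ascii`, which
#' keeps every artifact plain text. Vector volumes follow the NRRD convention
#' of a leading non-spatial "vector" axis of size 3. Only axis-aligned LPS
#' space directions are supported; that is the package's fixed coordinate
#' frame.
#'
#' @param values 3D array (scalar) or 4D array `c(shape, 3)` (vector field).
#' @param grid the `template_grid` the values live on.
#' @param path output / input file path (`.nrrd`).
#' @return `write_nrrd` returns `path` invisibly; `read_nrrd` returns a list
#'   with elements `values` (array, vector fields as `c(shape, 3)`) and
#'   `grid`.
#' @export
write_nrrd <- function(values, grid, path) {
  nd <- length(dim(values))
  stopifnot(nd %in% c(3L, 4L))
  is_vec <- nd == 4L
  if (is_vec) {
    stopifnot(dim(values)[4] == 3L)
    # reorder to vector-axis-first for on-disk layout
    values <- aperm(values, c(4, 1, 2, 3))
  }
  sp <- grid$spacing
  dirs <- sprintf("(%g,0,0) (0,%g,0) (0,0,%g)", sp[1], sp[2], sp[3])
  hdr <- c(
    "NRRD0004",
    "# Complete NRRD file format specification at:",
    "# http://teem.sourceforge.net/nrrd/format.html",
    "type: double",
    sprintf("dimension: %d", if (is_vec) 4L else 3L),
    "space: left-posterior-superior",
    sprintf("sizes: %s", paste(dim(values), collapse = " ")),
    if (is_vec) sprintf("space directions: none %s", dirs)
    else sprintf("space directions: %s", dirs),
    sprintf("kinds: %s", if (is_vec) "vector domain domain domain"
            else "domain domain domain"),
    "endian: little",
    "encoding: ascii",
    sprintf("space origin: (%g,%g,%g)", grid$origin[1], grid$origin[2],
            grid$origin[3])
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  writeLines("", con)
  # full double precision so write/read round-trips bit-exactly
  writeLines(paste(format(as.vector(values), digits = 17, trim = TRUE,
                          scientific = TRUE), collapse = " "), con)
  invisible(path)
}

#' @rdname write_nrrd
#' @export
read_nrrd <- function(path) {
  lines <- readLines(path, warn = FALSE)
  blank <- which(lines == "")[1]
  if (is.na(blank)) stop("malformed NRRD: no blank line after header")
  hdr <- lines[seq_len(blank - 1)]
  hdr <- hdr[!startsWith(hdr, "#")][-1]  # drop comments and magic
  fields <- list()
  for (ln in hdr) {
    kv <- regmatches(ln, regexpr(": ", ln), invert = TRUE)[[1]]
    if (length(kv) == 2) fields[[kv[1]]] <- kv[2]
  }
  if (!identical(fields[["encoding"]], "ascii"))
    stop("only ascii-encoded NRRD is supported")
  sizes <- as.integer(strsplit(fields[["sizes"]], " ")[[1]])
  dimn <- as.integer(fields[["dimension"]])
  is_vec <- dimn == 4L
  if (is_vec && sizes[1] != 3L)
    stop("vector NRRD must have a leading axis of size 3")
  dirtxt <- fields[["space directions"]]
  dirs <- regmatches(dirtxt, gregexpr("\\(([^)]*)\\)", dirtxt))[[1]]
  dm <- t(vapply(dirs, function(s)
    as.numeric(strsplit(gsub("[()]", "", s), ",")[[1]]), numeric(3)))
  if (nrow(dm) != 3L) stop("expected 3 spatial space directions")
  if (any(abs(dm - diag(diag(dm))) > 1e-12))
    stop("only axis-aligned space directions are supported")
  spacing <- diag(dm)
  org <- as.numeric(strsplit(gsub("[()]", "",
                                  fields[["space origin"]]), ",")[[1]])
  shape <- if (is_vec) sizes[2:4] else sizes
  vals <- scan(text = paste(lines[(blank + 1):length(lines)], collapse = " "),
               what = double(), quiet = TRUE)
  if (length(vals) != prod(sizes)) stop("NRRD data length mismatch")
  arr <- array(vals, dim = sizes)
  if (is_vec) arr <- aperm(arr, c(2, 3, 4, 1))
  list(values = arr, grid = template_grid(shape, spacing, org))
}
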