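#' Depth-layer labels used throughout the package
#'
#' The survey design samples four fixed depth intervals. Layers are handled
#' as ordered character labels; all layer-aware functions accept any subset
#' of these.
#'
#' @return Character vector of the four depth-layer labels, shallowest first.
#' @export
#' @examples
#' soc_layers()
soc_layers <- function() c("0-10", "10-20", "20-30", "30-40")

#' Regular sampling lattice over a rectangular survey area
#'
#' Builds the closed regular grid of sampling locations: nodes sit at every
#' integer multiple of `spacing` within the closed extents, boundary
#' included. The default reproduces the 5 km x 8 km survey design at 500 m
#' spacing, which has (5000/500 + 1) * (8000/500 + 1) = 11 x 17 = 187 nodes.
#'
#' Coordinates are planar metres with the origin at the southwest corner;
#' `y` increases northward.
#'
#' @param extent_x West-east extent in metres.
#' @param extent_y South-north extent in metres.
#' @param spacing Grid spacing in metres.
#' @return An object of class `location_grid`: a list with `extent_x`,
#'   `extent_y`, `spacing` and `nodes`, a data frame of `location_id`, `x`,
#'   `y` ordered west-to-east within south-to-north rows.
#' @export
#' @examples
#' g <- location_grid()
#' nrow(g$nodes) # 187
location_grid <- function(extent_x = 5000, extent_y = 8000, spacing = 500) {
  stopifnot(extent_x > 0, extent_y > 0, spacing > 0)
  xs <- seq(0, extent_x, by = spacing)
  ys <- seq(0, extent_y, by = spacing)
  nodes <- expand.grid(x = xs, y = ys, KEEP.OUT.ATTRS = FALSE)
  nodes <- data.frame(
    location_id = sprintf("L%03d", seq_len(nrow(nodes))),
    x = nodes$x, y = nodes$y,
    stringsAsFactors = FALSE
  )
  structure(
    list(extent_x = extent_x, extent_y = extent_y, spacing = spacing,
         nodes = nodes),
    class = "location_grid"
  )
}

#' @export
print.location_grid <- function(x, ...) {
  cat(sprintf("Sampling lattice: %g m x %g m at %g m spacing (%d nodes)\n",
              x$extent_x, x$extent_y, x$spacing, nrow(x$nodes)))
  invisible(x)
}

# canonical sample-table columns and which must be numeric
.soc_columns <- c("location_id", "x", "y", "layer", "soc",
                  "stones", "sand", "silt", "clay", "bd")
.soc_numeric <- setdiff(.soc_columns, c("location_id", "layer"))

#' Validate a sample table
#'
#' Checks the physical invariants of a long-format sample table: positive
#' SOC and bulk density, stone and texture fractions within 0--100 with
#' sand + silt + clay not exceeding 100 (plus a rounding tolerance), and,
#' when an extent is supplied, coordinates inside it. Missing values are
#' permitted and skipped (they propagate as absent downstream).
#'
#' @param samples Data frame with the columns of [read_samples()].
#' @param extent Optional numeric vector `c(extent_x, extent_y)` in metres.
#' @param action `"error"` (default) or `"warn"` on violated invariants.
#' @param tol Rounding tolerance for the texture-sum check, in percentage
#'   points.
#' @return The table, invisibly, on success.
#' @export
validate_samples <- function(samples, extent = NULL,
                             action = c("error", "warn"), tol = 0.5) {
  action <- match.arg(action)
  missing_cols <- setdiff(.soc_columns, names(samples))
  if (length(missing_cols) > 0L) {
    stop("sample table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  problems <- character(0)
  chk <- function(bad, what) {
    bad <- which(bad)
    if (length(bad) > 0L) {
      problems <<- c(problems, sprintf("%s (rows %s)", what,
                                       paste(utils::head(bad, 5), collapse = ", ")))
    }
  }
  ok <- function(v) !is.na(v)
  chk(ok(samples$soc) & samples$soc <= 0, "soc must be > 0")
  chk(ok(samples$bd) & samples$bd <= 0, "bd must be > 0")
  chk(ok(samples$stones) & (samples$stones < 0 | samples$stones > 100),
      "stones outside [0, 100]")
  for (v in c("sand", "silt", "clay")) {
    chk(ok(samples[[v]]) & samples[[v]] < 0, paste(v, "must be >= 0"))
  }
  tex <- samples$sand + samples$silt + samples$clay
  chk(ok(tex) & tex > 100 + tol, "sand + silt + clay exceeds 100")
  chk(!(samples$layer %in% soc_layers()) & !is.na(samples$layer),
      "unknown layer label")
  if (!is.null(extent)) {
    chk(ok(samples$x) & (samples$x < 0 | samples$x > extent[1]),
        "x outside area extent")
    chk(ok(samples$y) & (samples$y < 0 | samples$y > extent[2]),
        "y outside area extent")
  }
  if (length(problems) > 0L) {
    msg <- paste("sample validation:", paste(problems, collapse = "; "))
    if (action == "error") stop(msg, call. = FALSE) else warning(msg, call. = FALSE)
  }
  invisible(samples)
}

#' Read a long-format sample table from CSV
#'
#' One row per location x depth layer, comma-separated, `.` decimal, empty
#' cells for missing values. The expected columns are `location_id`, `x`,
#' `y` (metres from the southwest corner), `layer`, `soc` (g/kg), `stones`,
#' `sand`, `silt`, `clay` (%), and `bd` (g/cm^3); a `schema` mapping lets
#' files with other headers be read without rewriting them.
#'
#' @param path Path to a CSV file with a header row.
#' @param schema Optional named character vector mapping canonical column
#'   names to the file's column names, e.g. `c(soc = "OC_gkg")`. Unmapped
#'   canonical names are looked up verbatim.
#' @param validate Run [validate_samples()] on the result (default `TRUE`).
#' @param validate_action Passed to [validate_samples()] as `action`.
#' @return Data frame of samples, row order preserved.
#' @export
read_samples <- function(path, schema = NULL, validate = TRUE,
                         validate_action = "error") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = FALSE)
  file_names <- vapply(.soc_columns, function(nm) {
    if (!is.null(schema) && nm %in% names(schema)) schema[[nm]] else nm
  }, character(1))
  missing_cols <- .soc_columns[!(file_names %in% names(raw))]
  if (length(missing_cols) > 0L) {
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  out <- raw[, file_names, drop = FALSE]
  names(out) <- .soc_columns
  for (nm in .soc_numeric) {
    v <- out[[nm]]
    v[v == ""] <- NA_character_
    num <- suppressWarnings(as.numeric(v))
    bad <- which(!is.na(v) & is.na(num))
    if (length(bad) > 0L) {
      stop(sprintf("non-numeric value in column '%s' at data row %d: \"%s\"",
                   nm, bad[1], v[bad[1]]), call. = FALSE)
    }
    out[[nm]] <- num
  }
  rownames(out) <- NULL
  if (validate) validate_samples(out, action = validate_action)
  out
}

#' Write a sample table to CSV
#'
#' Inverse of [read_samples()]: comma-separated, `.` decimal, missing
#' values as empty cells, so that `read_samples(write_samples(x))` restores
#' the table within print precision.
#'
#' @param samples Sample data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_samples <- function(samples, path) {
  utils::write.csv(samples, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Write a grid of values as an ESRI ASCII raster
#'
#' The matrix is interpreted with row 1 as the southernmost row and column 1
#' as the westernmost column (the same frame as the sample coordinates);
#' rows are flipped to the north-to-south order the `.asc` format requires.
#'
#' @param values Numeric matrix, complete rectangular grid (no ragged rows).
#' @param cell_size Cell size in metres.
#' @param origin Numeric `c(x, y)` of the lower-left corner (metres).
#' @param path Output path.
#' @param nodata No-data sentinel written for `NA` cells.
#' @param digits Significant digits to print.
#' @return `path`, invisibly.
#' @export
write_asc <- function(values, cell_size, origin = c(0, 0), path,
                      nodata = -9999, digits = 8) {
  if (!is.matrix(values) || nrow(values) == 0L || ncol(values) == 0L) {
    stop("values must be a non-empty rectangular matrix", call. = FALSE)
  }
  header <- c(
    sprintf("ncols %d", ncol(values)),
    sprintf("nrows %d", nrow(values)),
    sprintf("xllcorner %.6f", origin[1]),
    sprintf("yllcorner %.6f", origin[2]),
    sprintf("cellsize %.6f", cell_size),
    sprintf("NODATA_value %g", nodata)
  )
  m <- values[rev(seq_len(nrow(values))), , drop = FALSE] # north first
  m[is.na(m)] <- nodata
  body <- apply(m, 1L, function(r) paste(signif(r, digits), collapse = " "))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read an ESRI ASCII raster
#'
#' @param path Path to a `.asc` file.
#' @return List with `values` (matrix, row 1 = south), `cell_size`,
#'   `origin`, `nodata`.
#' @export
read_asc <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1L
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1L
  }
  body <- lines[i:length(lines)]
  vals <- lapply(body, function(l) as.numeric(strsplit(trimws(l), "[[:space:]]+")[[1]]))
  m <- do.call(rbind, vals)
  if (nrow(m) != hdr$nrows || ncol(m) != hdr$ncols) {
    stop("raster body does not match declared dimensions", call. = FALSE)
  }
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  m[m == nodata] <- NA
  list(values = m[rev(seq_len(nrow(m))), , drop = FALSE],
       cell_size = hdr$cellsize,
       origin = c(hdr$xllcorner, hdr$yllcorner),
       nodata = nodata)
}
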