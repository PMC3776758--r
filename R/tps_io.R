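# TPS landmark I/O, outline resampling and side standardization.
#
# TPS files are the de-facto deposit format of 2D landmark studies: records
# of the form
#   LM=<k>
#   <x> <y>        (k coordinate lines)
#   IMAGE=<file>   (optional)
#   ID=<id>        (optional)
#   SCALE=<s>      (optional; multiplies coordinates)
# Coordinates are y-up Cartesian (digitizer convention), not image rows.

#' Read a TPS landmark file
#'
#' Parses 2D landmark records from a TPS-format text file. Each record must
#' start with an `LM=` header followed by that many coordinate lines;
#' optional `ID=`, `IMAGE=` and `SCALE=` lines are honoured (coordinates are
#' multiplied by the scale factor when present). Unknown keys are ignored
#' with a warning. Digitization order is preserved.
#'
#' @param path path to a TPS file.
#' @return An object of class `tps_records`: a list of specimen records,
#'   each a list with elements `id`, `points` (k x 2 matrix), `scale`
#'   (applied factor or `NA`) and `image`.
#' @seealso [write_tps()], [resample_outline()]
#' @export
read_tps <- function(path) {
  if (!file.exists(path)) stop("TPS file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  records <- list()
  i <- 1L
  rec_no <- 0L
  unknown <- character()
  while (i <= length(lines)) {
    rec_no <- rec_no + 1L
    hdr <- lines[i]
    if (!grepl("^LM\\s*=", hdr, ignore.case = TRUE))
      stop("malformed TPS record ", rec_no, ": expected 'LM=' header, got '",
           hdr, "'")
    k <- suppressWarnings(as.integer(sub("^LM\\s*=\\s*", "", hdr,
                                         ignore.case = TRUE)))
    if (is.na(k) || k < 1)
      stop("malformed TPS record ", rec_no, ": bad landmark count in '",
           hdr, "'")
    if (i + k > length(lines))
      stop("TPS record ", rec_no, ": file ends before ", k,
           " coordinate lines")
    coord_lines <- lines[(i + 1L):(i + k)]
    xy <- lapply(seq_along(coord_lines), function(j) {
      v <- suppressWarnings(as.numeric(strsplit(coord_lines[j],
                                                "[,;[:space:]]+")[[1]]))
      if (length(v) != 2 || anyNA(v))
        stop("TPS record ", rec_no, ", coordinate line ", j,
             ": not two numeric values ('", coord_lines[j], "')")
      v
    })
    pts <- do.call(rbind, xy)
    i <- i + k + 1L
    id <- NA_character_; image <- NA_character_; scale <- NA_real_
    while (i <= length(lines) && !grepl("^LM\\s*=", lines[i],
                                        ignore.case = TRUE)) {
      ln <- lines[i]
      if (grepl("^ID\\s*=", ln, ignore.case = TRUE)) {
        id <- sub("^ID\\s*=\\s*", "", ln, ignore.case = TRUE)
      } else if (grepl("^IMAGE\\s*=", ln, ignore.case = TRUE)) {
        image <- sub("^IMAGE\\s*=\\s*", "", ln, ignore.case = TRUE)
      } else if (grepl("^SCALE\\s*=", ln, ignore.case = TRUE)) {
        scale <- suppressWarnings(as.numeric(sub("^SCALE\\s*=\\s*", "", ln,
                                                 ignore.case = TRUE)))
        if (is.na(scale) || scale <= 0)
          stop("TPS record ", rec_no, ": bad SCALE line '", ln, "'")
      } else if (grepl("=", ln, fixed = TRUE)) {
        unknown <- c(unknown, sub("=.*$", "", ln))
        i <- i + 1L
        next
      } else {
        stop("TPS record ", rec_no, ": unexpected line '", ln, "'")
      }
      i <- i + 1L
    }
    if (!is.na(scale)) pts <- pts * scale
    if (is.na(id)) id <- paste0("specimen_", rec_no)
    records[[rec_no]] <- list(id = id, points = pts, scale = scale,
                              image = image)
  }
  if (length(unknown))
    warning("ignored unknown TPS keys: ",
            paste(unique(unknown), collapse = ", "))
  structure(records, class = "tps_records")
}

#' Write landmark records to a TPS file
#'
#' @param records a `tps_records` object or plain list of records as
#'   returned by [read_tps()]; a k x 2 x n array with specimen dimnames is
#'   also accepted.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_tps <- function(records, path) {
  records <- as_tps_records(records)
  if (length(records) == 0) stop("no records to write")
  con <- file(path, "w")
  on.exit(close(con))
  for (r in records) {
    pts <- r$points
    writeLines(sprintf("LM=%d", nrow(pts)), con)
    writeLines(sprintf("%.17g %.17g", pts[, 1], pts[, 2]), con)
    writeLines(sprintf("ID=%s", r$id), con)
  }
  invisible(path)
}

#' Coerce to a list of TPS specimen records
#'
#' @param x a `tps_records` list, a k x 2 x n array (specimen ids taken from
#'   the third dimnames), or a single k x 2 matrix.
#' @return a `tps_records` object.
#' @export
as_tps_records <- function(x) {
  if (inherits(x, "tps_records")) return(x)
  if (is.array(x) && length(dim(x)) == 3) {
    ids <- dimnames(x)[[3]]
    if (is.null(ids)) ids <- paste0("specimen_", seq_len(dim(x)[3]))
    recs <- lapply(seq_len(dim(x)[3]), function(i)
      list(id = ids[i], points = x[, , i], scale = NA_real_,
           image = NA_character_))
    return(structure(recs, class = "tps_records"))
  }
  if (is.matrix(x))
    return(structure(list(list(id = "specimen_1", points = x,
                               scale = NA_real_, image = NA_character_)),
                     class = "tps_records"))
  if (is.list(x) && all(vapply(x, function(r) is.list(r) &&
                                 !is.null(r$points), logical(1))))
    return(structure(x, class = "tps_records"))
  stop("cannot interpret input as TPS records")
}

#' Stack TPS records into a coordinate array
#'
#' @param records records as accepted by [as_tps_records()]; all specimens
#'   must share the landmark count.
#' @return a k x 2 x n array, specimen ids on the third dimension.
#' @export
coords_array <- function(records) {
  records <- as_tps_records(records)
  ks <- vapply(records, function(r) nrow(r$points), integer(1))
  if (length(unique(ks)) != 1)
    stop("specimens differ in landmark count: ",
         paste(unique(ks), collapse = ", "))
  arr <- array(NA_real_, dim = c(ks[1], 2, length(records)),
               dimnames = list(NULL, c("x", "y"),
                               vapply(records, `[[`, character(1), "id")))
  for (i in seq_along(records)) arr[, , i] <- records[[i]]$points
  arr
}

#' @export
print.tps_records <- function(x, ...) {
  ks <- vapply(x, function(r) nrow(r$points), integer(1))
  cat("TPS records:", length(x), "specimen(s),",
      paste(unique(ks), collapse = "/"), "landmarks each\n")
  invisible(x)
}

# signed polygon area (shoelace); negative = clockwise in y-up coordinates
.signed_area <- function(pts) {
  x <- pts[, 1]; y <- pts[, 2]
  j <- c(seq_len(nrow(pts))[-1], 1L)
  sum(x * y[j] - x[j] * y) / 2
}

#' Resample a closed outline to equally spaced semi-landmarks
#'
#' Resamples a densely digitized closed outline to `n_semilandmarks + 1`
#' points equally spaced by cumulative arc length, with point 1 placed
#' exactly at the designated start vertex (the fixed landmark; here the
#' middle of the ulnar articular surface). Output order is clockwise
#' (negative signed area); counter-clockwise inputs are reversed with a
#' warning.
#'
#' @param raw_points dense closed polyline, m x 2 matrix (first point need
#'   not repeat at the end; the curve wraps).
#' @param n_semilandmarks number of semi-landmarks (default 20, giving 21
#'   points with the fixed landmark).
#' @param start row index of the vertex that becomes the fixed landmark.
#' @return a (n_semilandmarks + 1) x 2 matrix with attribute `fixed = 1`.
#' @export
resample_outline <- function(raw_points, n_semilandmarks = 20, start = 1) {
  .check_config(raw_points, "raw_points")
  m <- nrow(raw_points)
  if (m < n_semilandmarks + 1)
    stop("need at least n_semilandmarks + 1 input vertices")
  if (start < 1 || start > m) stop("start index out of range")
  # drop duplicated closing vertex if present
  if (sqrt(sum((raw_points[1, ] - raw_points[m, ])^2)) < 1e-12) {
    raw_points <- raw_points[-m, , drop = FALSE]
    m <- nrow(raw_points)
    if (start > m) start <- 1L
  }
  pts <- raw_points[c(start:m, seq_len(start - 1L)), , drop = FALSE]
  if (.signed_area(pts) > 0) {
    warning("outline is counter-clockwise; reversing to clockwise")
    pts <- pts[c(1L, m:2L), , drop = FALSE]
  }
  closed <- rbind(pts, pts[1, ])
  seg <- sqrt(rowSums(diff(closed)^2))
  total <- sum(seg)
  if (total <= 0) stop("degenerate outline: zero total length")
  cum <- c(0, cumsum(seg))
  k <- n_semilandmarks + 1L
  target <- total * (seq_len(k) - 1) / k
  out <- matrix(NA_real_, k, 2)
  out[1, ] <- pts[1, ]
  for (j in 2:k) {
    i <- findInterval(target[j], cum, rightmost.closed = TRUE)
    f <- (target[j] - cum[i]) / seg[i]
    out[j, ] <- closed[i, ] + f * (closed[i + 1, ] - closed[i, ])
  }
  attr(out, "fixed") <- 1L
  out
}

#' Mirror a landmark configuration about the y axis
#'
#' Applies x -> -x to every landmark, the load-time standardization for
#' right-side specimens so all shapes are analysed in left-equivalent form.
#' Point order and the fixed landmark are unchanged (traversal handedness is
#' thereby reversed).
#'
#' @param points k x 2 coordinate matrix.
#' @return mirrored k x 2 matrix (attributes preserved).
#' @export
mirror_config <- function(points) {
  .check_config(points)
  out <- points
  out[, 1] <- -out[, 1]
  out
}

#' Read a specimen group table
#'
#' Reads a UTF-8 CSV with a header row, requiring a `specimen_id` column;
#' conventional extra columns are `taxon`, `side` and one column per
#' grouping scheme (e.g. an extant scheme and two terrestrial schemes).
#'
#' @param path CSV path.
#' @param scheme optional scheme column name to validate.
#' @return a data.frame.
#' @export
read_group_table <- function(path, scheme = NULL) {
  tab <- read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  if (!"specimen_id" %in% names(tab))
    stop("group table must contain a 'specimen_id' column")
  if (anyDuplicated(tab$specimen_id))
    stop("duplicate specimen_id in group table")
  if (!is.null(scheme) && !scheme %in% names(tab))
    stop("scheme column '", scheme, "' not found in group table")
  tab
}

#' Standardize specimen sides by mirroring right radii
#'
#' Right-side specimens (per the group table's `side` column) are mirrored
#' to left-equivalent form and flagged, so downstream shape analysis never
#' mixes reflections.
#'
#' @param records TPS records.
#' @param groups data.frame with `specimen_id` and `side`
#'   (`"left"`/`"right"`/`"unknown"`).
#' @return `tps_records` with right-side specimens mirrored; each mirrored
#'   record carries `mirrored = TRUE`.
#' @export
standardize_sides <- function(records, groups) {
  records <- as_tps_records(records)
  if (!all(c("specimen_id", "side") %in% names(groups)))
    stop("groups must contain specimen_id and side columns")
  side <- groups$side[match(vapply(records, `[[`, character(1), "id"),
                            groups$specimen_id)]
  for (i in seq_along(records)) {
    if (!is.na(side[i]) && tolower(side[i]) == "right") {
      records[[i]]$points <- mirror_config(records[[i]]$points)
      records[[i]]$mirrored <- TRUE
    }
  }
  records
}
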