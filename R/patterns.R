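#' Rectangular observation window
#'
#' An axis-aligned rectangle in meters, the observation window of all point
#' patterns in the package. The canonical census plot is 600 m x 400 m
#' (24 ha), but any rectangle with positive area is allowed.
#'
#' @param xmin,ymin,xmax,ymax window corners in meters; `xmax > xmin`,
#'   `ymax > ymin`.
#' @return An object of class `"pp_window"` with fields `xmin`, `ymin`,
#'   `xmax`, `ymax`.
#' @examples
#' w <- rect_window(0, 0, 600, 400)
#' window_area(w) # 240000 m^2 = 24 ha
#' @export
rect_window <- function(xmin = 0, ymin = 0, xmax, ymax) {
  stopifnot(is.numeric(xmin), is.numeric(ymin), is.numeric(xmax),
            is.numeric(ymax), length(xmin) == 1, length(xmax) == 1)
  if (!(xmax > xmin && ymax > ymin))
    stop("window must have xmax > xmin and ymax > ymin")
  structure(list(xmin = xmin, ymin = ymin, xmax = xmax, ymax = ymax),
            class = "pp_window")
}

#' @rdname rect_window
#' @param w a `pp_window`.
#' @export
window_area <- function(w) {
  stopifnot(inherits(w, "pp_window"))
  (w$xmax - w$xmin) * (w$ymax - w$ymin)
}

#' @export
print.pp_window <- function(x, ...) {
  cat(sprintf("window: [%g, %g] x [%g, %g] m (area %g m^2)\n",
              x$xmin, x$xmax, x$ymin, x$ymax, window_area(x)))
  invisible(x)
}

in_window <- function(x, y, w) {
  x >= w$xmin & x <= w$xmax & y >= w$ymin & y <= w$ymax
}

#' Planar point pattern
#'
#' Locations of stems of one species and life stage inside a rectangular
#' window. Coordinates are continuous meters with the origin at the plot's
#' lower-left corner; duplicated coordinates (multi-stemmed neighbours) are
#' permitted but reported via a message.
#'
#' @param x,y numeric coordinate vectors of equal length (meters).
#' @param window a [rect_window()].
#' @param check validate containment (closed window) and duplicates.
#' @return Object of class `"point_pattern"` with fields `x`, `y`, `n`,
#'   `window`.
#' @examples
#' p <- point_pattern(c(10, 20), c(10, 30), rect_window(0, 0, 100, 100))
#' intensity_of(p)
#' @export
point_pattern <- function(x, y, window, check = TRUE) {
  stopifnot(inherits(window, "pp_window"), length(x) == length(y))
  x <- as.numeric(x); y <- as.numeric(y)
  if (check && length(x)) {
    out <- !in_window(x, y, window)
    if (any(out))
      stop(sprintf("%d point(s) outside the window (first at index %d)",
                   sum(out), which(out)[1]))
    if (anyDuplicated(cbind(x, y)))
      message("point_pattern: duplicate coordinates present (kept)")
  }
  structure(list(x = x, y = y, n = length(x), window = window),
            class = "point_pattern")
}

#' @rdname point_pattern
#' @param p a `point_pattern`.
#' @return `intensity_of()`: the estimated intensity n / |W| (points per m^2).
#' @export
intensity_of <- function(p) {
  stopifnot(inherits(p, "point_pattern"))
  p$n / window_area(p$window)
}

#' @export
print.point_pattern <- function(x, ...) {
  cat(sprintf("point pattern: %d points, intensity %.4g /m^2\n",
              x$n, intensity_of(x)))
  print(x$window)
  invisible(x)
}

#' Life-stage classification from stem diameter
#'
#' Maps diameter at breast height (dbh, cm) to one of the three life stages
#' (sapling < juvenile < adult), with growth-form specific size classes:
#' canopy trees 1-5 / 5-10 / >=10 cm, under-story trees 1-2.5 / 2.5-5 / >=5,
#' shrubs 1-1.5 / 1.5-2 / >=2. Intervals are lower-closed and upper-open so
#' every dbh >= 1 maps to exactly one stage.
#'
#' @param dbh numeric vector of diameters (cm), all >= 1.
#' @param growth_form character vector (recycled) in
#'   `c("shrub", "understory", "canopy")`.
#' @return Ordered factor with levels `sapling < juvenile < adult`.
#' @examples
#' classify_stage(7, "canopy")       # juvenile
#' classify_stage(5, "understory")   # adult
#' @export
classify_stage <- function(dbh, growth_form) {
  if (any(!is.finite(dbh)) || any(dbh < 1))
    stop("dbh must be finite and >= 1 cm (census floor)")
  growth_form <- rep_len(as.character(growth_form), length(dbh))
  bad <- !growth_form %in% names(stage_cuts)
  if (any(bad))
    stop("unknown growth form: ", paste(unique(growth_form[bad]), collapse = ", "))
  cuts <- do.call(rbind, stage_cuts[growth_form])
  idx <- 1L + (dbh >= cuts[, 1]) + (dbh >= cuts[, 2])
  factor(stage_levels()[idx], levels = stage_levels(), ordered = TRUE)
}

stage_cuts <- list(canopy = c(5, 10), understory = c(2.5, 5),
                   shrub = c(1.5, 2))

#' @rdname classify_stage
#' @return `stage_levels()`: the ordered stage names.
#' @export
stage_levels <- function() c("sapling", "juvenile", "adult")

#' Read and validate a stem table
#'
#' Reads a CSV stem table with columns `species,x,y,dbh,growth_form`
#' (UTF-8, '.' decimal separator), validates every row against the window
#' (closed containment) and the 1 cm dbh census floor, and preserves row
#' order. A `stage` column is appended via [classify_stage()].
#'
#' @param path path to the CSV file.
#' @param window a [rect_window()] the coordinates must fall in.
#' @return `data.frame` with columns `species, x, y, dbh, growth_form, stage`.
#' @export
read_stem_table <- function(path, window) {
  stopifnot(inherits(window, "pp_window"))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("species", "x", "y", "dbh", "growth_form")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("stem table missing column(s): ", paste(miss, collapse = ", "))
  df <- df[need]
  for (col in c("x", "y", "dbh")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(!is.finite(v))
    if (length(bad))
      stop(sprintf("malformed value in column '%s' at row %d", col, bad[1]))
    df[[col]] <- v
  }
  low <- which(df$dbh < 1)
  if (length(low))
    stop(sprintf("dbh below the 1 cm census floor at row %d (dbh = %g)",
                 low[1], df$dbh[low[1]]))
  out <- which(!in_window(df$x, df$y, window))
  if (length(out))
    stop(sprintf("stem outside the window at row %d (x = %g, y = %g)",
                 out[1], df$x[out[1]], df$y[out[1]]))
  df$stage <- classify_stage(df$dbh, df$growth_form)
  ndup <- sum(duplicated(df[c("x", "y")]))
  if (ndup) message(sprintf("read_stem_table: %d duplicate coordinate(s)", ndup))
  df
}

#' Select species with sufficient stems in every life stage
#'
#' Retains species that have at least `min_per_stage` individuals in each of
#' the three life stages (the census analysis floor of 40), sorted by
#' descending total abundance with ties broken by species code. Invariant to
#' row order of the input.
#'
#' @param stems stem table as returned by [read_stem_table()] (needs `stage`).
#' @param min_per_stage minimum count per stage (default 40).
#' @return character vector of species codes.
#' @export
select_species <- function(stems, min_per_stage = 40) {
  if (!nrow(stems)) return(character(0))
  if (is.null(stems$stage)) stems$stage <- classify_stage(stems$dbh, stems$growth_form)
  tab <- table(stems$species, factor(stems$stage, levels = stage_levels()))
  keep <- rownames(tab)[apply(tab, 1, function(z) all(z >= min_per_stage))]
  if (!length(keep)) return(character(0))
  tot <- rowSums(tab)[keep]
  keep[order(-tot, keep)]
}

#' Extract the point pattern of one species and stage
#'
#' @param stems stem table with `stage` column.
#' @param species species code.
#' @param stage one of `"sapling"`, `"juvenile"`, `"adult"`.
#' @param window a [rect_window()].
#' @return A [point_pattern()] (possibly empty) of the matching stems.
#' @export
extract_pattern <- function(stems, species, stage, window) {
  stage <- match.arg(stage, stage_levels())
  if (is.null(stems$stage)) stems$stage <- classify_stage(stems$dbh, stems$growth_form)
  sel <- stems$species == species & as.character(stems$stage) == stage
  point_pattern(stems$x[sel], stems$y[sel], window, check = FALSE)
}
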