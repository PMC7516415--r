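#' Construct an AOI layout
#'
#' An AOI layout partitions the stimulus frame into five named regions --
#' pavement area (PA), right wall (RW), left wall (LW), top wall (TW) and
#' central area (CA) -- given as simple closed polygons in screen pixels,
#' with everything else labelled white space (WS). Coordinates use the
#' dominant eye-tracker convention: origin at the top-left of the frame,
#' x rightward, y downward.
#'
#' Points falling on a shared polygon edge are resolved by `priority`: the
#' first listed region containing the point (boundary included) wins, so
#' every screen point maps to exactly one of the six labels.
#'
#' @param regions Named list of the five polygons; each element is a
#'   two-column numeric matrix (or coercible data frame) of vertices, one
#'   row per vertex, columns x then y. Names must be exactly
#'   `PA, CA, TW, LW, RW` in any order.
#' @param frame_width,frame_height Frame dimensions in pixels.
#' @param priority Character vector ordering the five labels for boundary
#'   tie-breaking. Default puts PA first.
#' @return An object of class `aoi_layout`.
#' @seealso [load_aoi_layout()], [assign_fixation()], [default_aoi_layout()]
#' @export
aoi_layout <- function(regions, frame_width, frame_height,
                       priority = c("PA", "CA", "TW", "LW", "RW")) {
  if (!is.list(regions)) {
    stop("`regions` must be a named list of polygons", call. = FALSE)
  }
  missing <- setdiff(aoi_states, names(regions))
  if (length(missing) > 0) {
    stop("AOI layout is missing region(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  extra <- setdiff(names(regions), aoi_states)
  if (length(extra) > 0) {
    stop("AOI layout declares unknown region(s): ",
         paste(extra, collapse = ", "), call. = FALSE)
  }
  if (!setequal(priority, aoi_states) || length(priority) != 5) {
    stop("`priority` must be a permutation of the five AOI labels",
         call. = FALSE)
  }
  stopifnot(is.numeric(frame_width), frame_width > 0,
            is.numeric(frame_height), frame_height > 0)
  regions <- lapply(regions, function(v) {
    v <- as.matrix(as.data.frame(v))
    storage.mode(v) <- "double"
    if (ncol(v) != 2 || anyNA(v)) {
      stop("each polygon must be a two-column numeric vertex matrix",
           call. = FALSE)
    }
    # drop an explicitly repeated closing vertex
    n <- nrow(v)
    if (n >= 2 && all(v[1, ] == v[n, ])) v <- v[-n, , drop = FALSE]
    v
  })
  for (lab in names(regions)) {
    v <- regions[[lab]]
    if (nrow(v) < 3) {
      stop("polygon for ", lab, " has fewer than 3 vertices", call. = FALSE)
    }
    if (!.is_simple_polygon(v)) {
      stop("polygon for ", lab, " is self-intersecting", call. = FALSE)
    }
  }
  structure(
    list(regions = regions[aoi_states],
         frame_width = as.numeric(frame_width),
         frame_height = as.numeric(frame_height),
         priority = priority),
    class = "aoi_layout"
  )
}

#' @export
print.aoi_layout <- function(x, ...) {
  cat(sprintf("<aoi_layout> %g x %g px frame\n", x$frame_width, x$frame_height))
  for (lab in x$priority) {
    cat(sprintf("  %s: %d vertices\n", lab, nrow(x$regions[[lab]])))
  }
  cat("  tie-break priority:", paste(x$priority, collapse = " > "), "\n")
  invisible(x)
}

#' Read an AOI layout from a JSON or YAML file
#'
#' The file must declare `frame` (with `width` and `height`), a `regions`
#' map from each of the five AOI labels to a vertex list (`[[x, y], ...]`),
#' and may declare a `priority` order for boundary tie-breaking.
#'
#' @param path Path to a `.json`, `.yaml` or `.yml` file.
#' @return An [aoi_layout()] object.
#' @export
load_aoi_layout <- function(path) {
  if (!file.exists(path)) {
    stop("AOI layout file not found: ", path, call. = FALSE)
  }
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    yaml = ,
    yml  = yaml::read_yaml(path),
    stop("unsupported AOI layout format: .", ext,
         " (expected .json, .yaml or .yml)", call. = FALSE)
  )
  if (is.null(raw$frame$width) || is.null(raw$frame$height)) {
    stop("AOI layout file must declare frame width and height", call. = FALSE)
  }
  if (is.null(raw$regions)) {
    stop("AOI layout file must declare a `regions` map", call. = FALSE)
  }
  regions <- lapply(raw$regions, function(v) {
    if (is.list(v)) v <- do.call(rbind, lapply(v, unlist))
    v
  })
  priority <- raw$priority %||% c("PA", "CA", "TW", "LW", "RW")
  aoi_layout(regions, raw$frame$width, raw$frame$height,
             priority = unlist(priority))
}

#' Default AOI layout used by the synthetic cohort
#'
#' A 1920 x 1080 frame divided like a driver's forward view in a tunnel:
#' a top-wall band, left/right wall bands, a central area between them and a
#' pavement band below. The margins (including a bottom dashboard strip)
#' are white space. The polygon coordinates are a package convention: they
#' emulate the shape of a tunnel scene, not any measured apparatus.
#'
#' @return An [aoi_layout()] object.
#' @export
default_aoi_layout <- function() {
  rect <- function(x0, y0, x1, y1) {
    cbind(c(x0, x1, x1, x0), c(y0, y0, y1, y1))
  }
  aoi_layout(
    regions = list(
      TW = rect(120, 140, 1800, 320),
      LW = rect(120, 320, 440, 780),
      CA = rect(440, 320, 1480, 780),
      RW = rect(1480, 320, 1800, 780),
      PA = rect(120, 780, 1800, 1000)
    ),
    frame_width = 1920, frame_height = 1080
  )
}

#' Assign screen points to AOI labels
#'
#' Total function: each point receives exactly one of the six labels. A
#' point inside (or on the boundary of) a region gets that region's label,
#' with boundary ties broken by the layout's priority order; points
#' contained by no region are white space (`WS`).
#'
#' @param x,y Numeric vectors of screen coordinates (pixels, top-left
#'   origin). Recycled to common length.
#' @param layout An [aoi_layout()] object.
#' @return Factor with levels `PA, RW, LW, TW, CA, WS`.
#' @export
assign_fixation <- function(x, y, layout) {
  stopifnot(inherits(layout, "aoi_layout"))
  n <- max(length(x), length(y))
  x <- rep_len(as.numeric(x), n)
  y <- rep_len(as.numeric(y), n)
  lab <- rep("WS", n)
  open <- rep(TRUE, n)
  for (region in layout$priority) {
    if (!any(open)) break
    v <- layout$regions[[region]]
    inside <- pracma::inpolygon(x[open], y[open], v[, 1], v[, 2],
                                boundary = TRUE)
    idx <- which(open)[inside]
    lab[idx] <- region
    open[idx] <- FALSE
  }
  factor(lab, levels = aoi_areas)
}

#' Label a fixation table with AOI assignments
#'
#' Adds an `aoi_label` column to a fixation table via [assign_fixation()].
#'
#' @param fixations Fixation tibble as returned by [read_fixations()].
#' @param layout An [aoi_layout()] object.
#' @return The input tibble with an added `aoi_label` factor column.
#' @export
label_table <- function(fixations, layout) {
  .check_fixation_cols(fixations)
  fixations$aoi_label <- assign_fixation(fixations$pos_x, fixations$pos_y,
                                         layout)
  fixations
}

# simple-polygon check: no two non-adjacent edges may intersect
.is_simple_polygon <- function(v) {
  n <- nrow(v)
  seg <- function(i) rbind(v[i, ], v[i %% n + 1, ])
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      adjacent <- (j == i + 1) || (i == 1 && j == n)
      if (adjacent) next
      if (.segments_intersect(seg(i), seg(j))) return(FALSE)
    }
  }
  TRUE
}

.segments_intersect <- function(s1, s2) {
  d <- function(a, b, c) {
    (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  }
  on_seg <- function(a, b, c) {
    min(a[1], b[1]) <= c[1] && c[1] <= max(a[1], b[1]) &&
      min(a[2], b[2]) <= c[2] && c[2] <= max(a[2], b[2])
  }
  p1 <- s1[1, ]; p2 <- s1[2, ]; p3 <- s2[1, ]; p4 <- s2[2, ]
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
      ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) return(TRUE)
  (d1 == 0 && on_seg(p3, p4, p1)) || (d2 == 0 && on_seg(p3, p4, p2)) ||
    (d3 == 0 && on_seg(p1, p2, p3)) || (d4 == 0 && on_seg(p1, p2, p4))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
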