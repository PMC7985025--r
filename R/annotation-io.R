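#' Slide metadata
#'
#' Describes one scanned slide: identity, the RGB image it was exported to,
#' and the physical scale of the scan. The defaults correspond to a Hamamatsu
#' Nanozoomer 2.0-XR scan at x40 magnification (0.22 um per pixel). All lesion
#' geometry is expressed in level-0 pixel coordinates at the base
#' magnification and converted to physical units through `base_resolution`.
#'
#' @param slide_id Character slide identifier.
#' @param patient_id Character patient identifier.
#' @param image_path Optional path to the exported RGB image (PNG or TIFF).
#' @param base_resolution Microns per pixel at the scan magnification.
#' @param base_magnification Nominal scan magnification (unitless).
#' @return An object of class `slide_meta`.
#' @export
slide_meta <- function(slide_id, patient_id = slide_id, image_path = NA_character_,
                       base_resolution = 0.22, base_magnification = 40) {
  stopifnot(is.character(slide_id), length(slide_id) == 1L)
  if (!is.numeric(base_resolution) || base_resolution <= 0)
    stop("base_resolution must be > 0")
  if (!is.numeric(base_magnification) || base_magnification <= 0)
    stop("base_magnification must be > 0")
  structure(
    list(slide_id = slide_id, patient_id = patient_id,
         image_path = image_path,
         base_resolution = as.numeric(base_resolution),
         base_magnification = as.numeric(base_magnification)),
    class = "slide_meta")
}

#' Lesion annotation (outlined polygon)
#'
#' One outlined DCIS lesion: a simple polygon in 0-based level-0 pixel
#' coordinates. Closure is implicit (the last vertex connects back to the
#' first); a duplicated closing vertex is tolerated and dropped.
#'
#' @param lesion_id Character lesion identifier.
#' @param slide_id Character slide identifier.
#' @param polygon Numeric matrix with two columns (x, y), at least 3 rows.
#' @return An object of class `lesion_annotation`.
#' @export
lesion_annotation <- function(lesion_id, slide_id, polygon) {
  polygon <- as.matrix(polygon)
  if (!is.numeric(polygon) || ncol(polygon) != 2L)
    stop("polygon must be a numeric matrix with columns (x, y)")
  n <- nrow(polygon)
  if (n >= 2L && all(polygon[1L, ] == polygon[n, ])) {
    polygon <- polygon[-n, , drop = FALSE]  # drop duplicated closing vertex
    n <- n - 1L
  }
  if (n < 3L)
    stop(sprintf("lesion '%s': polygon needs at least 3 vertices", lesion_id))
  if (any(polygon < 0))
    stop(sprintf("lesion '%s': negative coordinates", lesion_id))
  if (!polygon_is_simple(polygon))
    stop(sprintf("lesion '%s': polygon is self-intersecting", lesion_id))
  dimnames(polygon) <- list(NULL, c("x", "y"))
  structure(list(lesion_id = lesion_id, slide_id = slide_id, polygon = polygon),
            class = "lesion_annotation")
}

# Simple-polygon test: no two non-adjacent edges intersect.  O(n^2) segment
# pairs, fine for hand-drawn outlines.
polygon_is_simple <- function(p) {
  n <- nrow(p)
  a <- p
  b <- p[c(2:n, 1L), , drop = FALSE]
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      adjacent <- (j == i + 1L) || (i == 1L && j == n)
      if (adjacent) next
      if (segments_intersect(a[i, ], b[i, ], a[j, ], b[j, ])) return(FALSE)
    }
  }
  TRUE
}

segments_intersect <- function(p1, p2, p3, p4) {
  orient <- function(a, b, c)
    sign((b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1]))
  o1 <- orient(p1, p2, p3); o2 <- orient(p1, p2, p4)
  o3 <- orient(p3, p4, p1); o4 <- orient(p3, p4, p2)
  if (o1 != o2 && o3 != o4) return(TRUE)
  on_seg <- function(a, b, c)
    orient(a, b, c) == 0 &&
      min(a[1], b[1]) <= c[1] && c[1] <= max(a[1], b[1]) &&
      min(a[2], b[2]) <= c[2] && c[2] <= max(a[2], b[2])
  on_seg(p1, p2, p3) || on_seg(p1, p2, p4) ||
    on_seg(p3, p4, p1) || on_seg(p3, p4, p2)
}

#' Parse lesion annotations from ASAP XML
#'
#' Reads the annotation dialect written by the Automated Slide Analysis
#' Platform (ASAP): `ASAP_Annotations/Annotations/Annotation` elements of
#' type `Polygon` whose `Coordinates/Coordinate` children carry `Order`, `X`
#' and `Y` attributes. Vertices are sorted by `Order`; the annotation `Name`
#' becomes the lesion id. Non-polygon annotation types (Dot, Spline, ...) are
#' skipped with a warning.
#'
#' @param xml_text XML document as a single string, or a file path.
#' @param slide_id Slide identifier attached to the returned lesions.
#' @return List of [lesion_annotation()] objects.
#' @export
parse_asap_annotations <- function(xml_text, slide_id = NA_character_) {
  doc <- tryCatch(xml2::read_xml(xml_text), error = function(e)
    stop("malformed ASAP XML: ", conditionMessage(e), call. = FALSE))
  anns <- xml2::xml_find_all(doc, "/ASAP_Annotations/Annotations/Annotation")
  out <- list()
  for (ann in anns) {
    name <- xml2::xml_attr(ann, "Name")
    type <- xml2::xml_attr(ann, "Type")
    if (!identical(type, "Polygon")) {
      warning(sprintf("skipping annotation '%s' of non-polygon type '%s'",
                      name, type), call. = FALSE)
      next
    }
    coords <- xml2::xml_find_all(ann, "./Coordinates/Coordinate")
    if (length(coords) < 3L)
      stop(sprintf("annotation '%s': polygon has fewer than 3 coordinates", name),
           call. = FALSE)
    ord <- as.numeric(xml2::xml_attr(coords, "Order"))
    x <- as.numeric(xml2::xml_attr(coords, "X"))
    y <- as.numeric(xml2::xml_attr(coords, "Y"))
    if (anyNA(ord) || anyNA(x) || anyNA(y))
      stop(sprintf("annotation '%s': non-numeric coordinate attributes", name),
           call. = FALSE)
    o <- order(ord)
    out[[length(out) + 1L]] <-
      lesion_annotation(name, slide_id, cbind(x[o], y[o]))
  }
  out
}

#' Write lesion annotations as ASAP XML
#'
#' Inverse of [parse_asap_annotations()]: serializes lesions into the ASAP
#' dialect with full floating-point precision, so that a write-then-parse
#' round trip reproduces the vertex coordinates exactly.
#'
#' @param lesions List of [lesion_annotation()] objects (may be empty).
#' @param path Optional file path; if given the XML is also written there.
#' @return XML document as a single string (invisibly when `path` is given).
#' @export
write_asap_annotations <- function(lesions, path = NULL) {
  body <- vapply(lesions, function(l) {
    p <- l$polygon
    coords <- sprintf(
      '\t\t\t\t<Coordinate Order="%d" X="%.17g" Y="%.17g" />',
      seq_len(nrow(p)) - 1L, p[, 1], p[, 2])
    paste0(
      sprintf('\t\t<Annotation Name="%s" Type="Polygon" PartOfGroup="None" Color="#F4FA58">\n',
              l$lesion_id),
      "\t\t\t<Coordinates>\n",
      paste(coords, collapse = "\n"), "\n",
      "\t\t\t</Coordinates>\n",
      "\t\t</Annotation>")
  }, character(1))
  xml <- paste0(
    '<?xml version="1.0"?>\n<ASAP_Annotations>\n\t<Annotations>\n',
    if (length(body)) paste0(paste(body, collapse = "\n"), "\n") else "",
    "\t</Annotations>\n\t<AnnotationGroups />\n</ASAP_Annotations>\n")
  if (!is.null(path)) {
    writeLines(xml, path, sep = "")
    return(invisible(xml))
  }
  xml
}

#' Read an observer grade table
#'
#' Reads a CSV (or TSV; the delimiter is sniffed from the header line) with
#' columns `lesion_id,observer1,observer2,observer3`, one row per lesion.
#' Every grade must lie in \{1, 2, 3\} and lesion ids must be unique.
#'
#' @param x File path, or the table contents as a single string.
#' @return Data frame with columns `lesion_id`, `observer1..3` (integer).
#' @export
read_grade_table <- function(x) {
  txt <- if (length(x) == 1L && !grepl("\n", x, fixed = TRUE) && file.exists(x))
    readLines(x) else strsplit(x, "\n", fixed = TRUE)[[1]]
  txt <- txt[nzchar(txt)]
  if (!length(txt)) stop("empty grade table")
  sep <- if (grepl("\t", txt[1], fixed = TRUE)) "\t" else ","
  df <- utils::read.table(text = txt, sep = sep, header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("lesion_id", "observer1", "observer2", "observer3")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("grade table is missing column(s): ", paste(missing, collapse = ", "))
  df <- df[need]
  df$lesion_id <- as.character(df$lesion_id)
  if (anyDuplicated(df$lesion_id))
    stop("duplicate lesion_id in grade table: ",
         df$lesion_id[duplicated(df$lesion_id)][1])
  for (col in need[-1]) {
    g <- df[[col]]
    bad <- which(!(g %in% c(1, 2, 3)))
    if (length(bad))
      stop(sprintf("row %d (lesion '%s'): grade %s in column %s is outside {1,2,3}",
                   bad[1], df$lesion_id[bad[1]], g[bad[1]], col))
    df[[col]] <- as.integer(g)
  }
  df
}

#' Write an observer grade table
#'
#' @param grades Data frame as returned by [read_grade_table()].
#' @param path File path to write a CSV to.
#' @export
write_grade_table <- function(grades, path) {
  utils::write.csv(grades, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Lesion area in square millimetres
#'
#' Shoelace area of the annotation polygon in level-0 pixels, converted to
#' physical units by the slide's base resolution. Orientation-invariant.
#'
#' @param lesion A [lesion_annotation()].
#' @param meta A [slide_meta()].
#' @return Area in mm^2 (always > 0).
#' @export
lesion_area_mm2 <- function(lesion, meta) {
  p <- lesion$polygon
  n <- nrow(p)
  j <- c(2:n, 1L)
  area_px <- abs(sum(p[, 1] * p[j, 2] - p[j, 1] * p[, 2])) / 2
  if (area_px <= 0) stop(sprintf("lesion '%s': degenerate zero-area polygon",
                                 lesion$lesion_id))
  area_px * meta$base_resolution^2 / 1e6
}

#' Read an RGB image as an 8-bit array
#'
#' PNG is read through the png package, TIFF through the tiff package.
#' Grayscale images are expanded to three channels; any alpha channel is
#' dropped.
#'
#' @param path Image file path.
#' @return Numeric array height x width x 3 with values in \[0, 255\].
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE))
        stop("reading TIFF requires the 'tiff' package")
      tiff::readTIFF(path)
    },
    stop("unsupported image format: ", ext))
  if (length(dim(img)) == 2L) img <- array(rep(img, 3L), c(dim(img), 3L))
  if (dim(img)[3] > 3L) img <- img[, , 1:3, drop = FALSE]
  img * 255
}

#' Write an 8-bit RGB array as PNG
#'
#' @param pixels Numeric array height x width x 3, values in \[0, 255\].
#' @param path Output path.
#' @export
write_image <- function(pixels, path) {
  png::writePNG(pmin(pmax(pixels / 255, 0), 1), path)
  invisible(path)
}
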