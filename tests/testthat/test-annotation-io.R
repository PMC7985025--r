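test_that("ASAP polygon annotations parse with vertices in Order sequence", {
  xml <- paste0(
    '<?xml version="1.0"?><ASAP_Annotations><Annotations>',
    '<Annotation Name="les1" Type="Polygon" PartOfGroup="None" Color="#F4FA58">',
    '<Coordinates>',
    '<Coordinate Order="2" X="100" Y="100"/>',
    '<Coordinate Order="0" X="0" Y="0"/>',
    '<Coordinate Order="1" X="100" Y="0"/>',
    '<Coordinate Order="3" X="0" Y="100"/>',
    '</Coordinates></Annotation>',
    '</Annotations><AnnotationGroups/></ASAP_Annotations>')
  lesions <- parse_asap_annotations(xml, slide_id = "s1")
  expect_length(lesions, 1L)
  expect_identical(lesions[[1]]$lesion_id, "les1")
  expect_equal(lesions[[1]]$polygon,
               cbind(x = c(0, 100, 100, 0), y = c(0, 0, 100, 100)))
})

test_that("non-polygon annotations are skipped with a warning", {
  xml <- paste0(
    '<ASAP_Annotations><Annotations>',
    '<Annotation Name="p" Type="Polygon"><Coordinates>',
    '<Coordinate Order="0" X="0" Y="0"/>',
    '<Coordinate Order="1" X="10" Y="0"/>',
    '<Coordinate Order="2" X="10" Y="10"/>',
    '</Coordinates></Annotation>',
    '<Annotation Name="d" Type="Dot"><Coordinates>',
    '<Coordinate Order="0" X="5" Y="5"/>',
    '</Coordinates></Annotation>',
    '</Annotations><AnnotationGroups/></ASAP_Annotations>')
  expect_warning(lesions <- parse_asap_annotations(xml), "Dot")
  expect_length(lesions, 1L)
})

test_that("malformed XML and degenerate polygons are rejected with clear errors", {
  expect_error(parse_asap_annotations("<ASAP_Annotations><unclosed"),
               "malformed")
  xml <- paste0(
    '<ASAP_Annotations><Annotations>',
    '<Annotation Name="bad" Type="Polygon"><Coordinates>',
    '<Coordinate Order="0" X="0" Y="0"/>',
    '<Coordinate Order="1" X="10" Y="0"/>',
    '</Coordinates></Annotation>',
    '</Annotations></ASAP_Annotations>')
  expect_error(parse_asap_annotations(xml), "bad")
})

test_that("write-then-parse round trip is the identity on random lesion lists", {
  set.seed(41)
  make_lesion <- function(id) {
    # star-convex polygon: always simple
    k <- sample(5:12, 1)
    ang <- sort(stats::runif(k, 0, 2 * pi))
    r <- stats::runif(k, 50, 400)
    lesion_annotation(id, "s1",
                      cbind(1000 + r * cos(ang), 1000 + r * sin(ang)))
  }
  for (n in c(5, 20)) {
    lesions <- lapply(paste0("L", seq_len(n)), make_lesion)
    back <- parse_asap_annotations(write_asap_annotations(lesions), "s1")
    expect_length(back, n)
    for (i in seq_len(n)) {
      expect_identical(back[[i]]$lesion_id, lesions[[i]]$lesion_id)
      expect_identical(back[[i]]$polygon, lesions[[i]]$polygon)
    }
  }
  # empty list -> valid XML with zero annotations
  expect_length(parse_asap_annotations(write_asap_annotations(list())), 0L)
})

test_that("polygon validation enforces simplicity, vertex count and closure", {
  expect_error(lesion_annotation("x", "s", cbind(c(0, 1), c(0, 1))),
               "3 vertices")
  # bow-tie self-intersection
  expect_error(lesion_annotation("x", "s",
                                 cbind(c(0, 10, 10, 0), c(0, 10, 0, 10))),
               "self-intersect")
  # duplicated closing vertex is dropped
  l <- lesion_annotation("x", "s",
                         cbind(c(0, 10, 10, 0, 0), c(0, 0, 10, 10, 0)))
  expect_identical(nrow(l$polygon), 4L)
})

test_that("grade tables parse, sniff TSV, and reject out-of-range grades", {
  df <- read_grade_table("lesion_id,observer1,observer2,observer3\nL1,1,2,1\nL2,3,3,3\n")
  expect_identical(df$observer2, c(2L, 3L))
  tsv <- read_grade_table("lesion_id\tobserver1\tobserver2\tobserver3\nL1\t1\t2\t1\n")
  expect_identical(tsv$observer1, 1L)
  expect_error(read_grade_table("lesion_id,observer1,observer2,observer3\nL1,4,2,1\n"),
               "outside")
  expect_error(read_grade_table("lesion_id,observer1,observer2\nL1,1,2\n"),
               "missing column")
  expect_error(read_grade_table("lesion_id,observer1,observer2,observer3\nL1,1,2,1\nL1,2,2,2\n"),
               "duplicate")
  # every grade value outside {1,2,3} in 0..9 is rejected
  for (g in c(0, 4:9)) {
    txt <- sprintf("lesion_id,observer1,observer2,observer3\nL1,%d,2,1\n", g)
    expect_error(read_grade_table(txt), "outside")
  }
})

test_that("lesion area matches the closed form and is orientation invariant", {
  meta <- slide_meta("s1", "p1")
  sq <- lesion_annotation("sq", "s1",
                          cbind(c(0, 1000, 1000, 0), c(0, 0, 1000, 1000)))
  expect_equal(lesion_area_mm2(sq, meta), (1000 * 0.22)^2 / 1e6)
  sq_cw <- lesion_annotation("sq", "s1",
                             cbind(c(0, 0, 1000, 1000), c(0, 1000, 1000, 0)))
  expect_equal(lesion_area_mm2(sq_cw, meta), lesion_area_mm2(sq, meta))
  # cyclic re-indexing of vertices leaves the area unchanged
  p <- sq$polygon
  rot <- lesion_annotation("sq", "s1", p[c(3, 4, 1, 2), ])
  expect_equal(lesion_area_mm2(rot, meta), lesion_area_mm2(sq, meta))
})

test_that("lesion area agrees with a Monte-Carlo point-in-polygon estimate", {
  set.seed(7)
  k <- 9
  ang <- sort(stats::runif(k, 0, 2 * pi))
  r <- stats::runif(k, 200, 900)
  px <- 1000 + r * cos(ang); py <- 1000 + r * sin(ang)
  lesion <- lesion_annotation("mc", "s1", cbind(px, py))
  meta <- slide_meta("s1", "p1")
  # MC estimate over the bounding box, 1e6 samples
  n <- 1e6
  xs <- stats::runif(n, min(px), max(px))
  ys <- stats::runif(n, min(py), max(py))
  # ray-casting point-in-polygon, vectorized over test points
  inside <- rep(FALSE, n)
  j <- k
  for (i in seq_len(k)) {
    cross <- ((py[i] > ys) != (py[j] > ys)) &
      (xs < (px[j] - px[i]) * (ys - py[i]) / (py[j] - py[i]) + px[i])
    inside <- xor(inside, cross)
    j <- i
  }
  box_mm2 <- (max(px) - min(px)) * (max(py) - min(py)) * meta$base_resolution^2 / 1e6
  mc <- mean(inside) * box_mm2
  expect_equal(lesion_area_mm2(lesion, meta), mc, tolerance = 0.01)
})

test_that("degenerate zero-area polygons raise an error", {
  collinear <- lesion_annotation("z", "s", cbind(c(0, 5, 10), c(0, 5, 10)))
  expect_error(lesion_area_mm2(collinear, slide_meta("s", "p")), "degenerate")
})

test_that("PNG image IO round-trips 8-bit RGB arrays", {
  set.seed(3)
  img <- array(sample(0:255, 20 * 30 * 3, TRUE), c(20, 30, 3))
  f <- tempfile(fileext = ".png")
  write_image(img, f)
  expect_equal(read_image(f), img)
  unlink(f)
})
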