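#' Construct a case record
#'
#' @param caseId unique case identifier.
#' @param contours list of [NoduleContour-class] (or a single contour).
#' @param label 0 (benign), 1 (malignant) or `NA`.
#' @param tirads TIRADS category text, or `character(0)`.
#' @param image optional image/mask matrix (rows = y, columns = x).
#' @param imageRef optional path or reference to the source image.
#' @param sourceTag `"original"` or `"augmented"`.
#' @param sourceCaseId source case for augmented records.
#' @param opLog list of augmentation operations applied.
#' @return a [CaseRecord-class].
#' @export
CaseRecord <- function(caseId, contours, label = NA_integer_,
                       tirads = character(0), image = NULL,
                       imageRef = character(0), sourceTag = "original",
                       sourceCaseId = character(0), opLog = list()) {
  if (is(contours, "NoduleContour")) contours <- list(contours)
  new("CaseRecord", caseId = as.character(caseId), contours = contours,
      label = as.integer(label), tirads = as.character(tirads),
      image = image, imageRef = as.character(imageRef),
      sourceTag = sourceTag, sourceCaseId = as.character(sourceCaseId),
      opLog = opLog)
}

#' @describeIn CaseRecord label accessor.
#' @param x a `CaseRecord`.
#' @export
caseLabel <- function(x) x@label

#' @describeIn CaseRecord contour list accessor.
#' @export
caseContours <- function(x) x@contours

#' Parse a per-case annotation XML file
#'
#' Reads one case annotation in the coordinate-list dialect used for
#' open-access thyroid ultrasound ground truth: a `<case>` element with an
#' optional `<tirads>` category and one `<mark>` per annotated nodule, each
#' carrying an ordered list of `<point x=".." y=".."/>` pixel coordinates.
#'
#' @param path path to the XML file.
#' @param imageSize optional `(width, height)` recorded on the parsed
#'   contours.
#' @return a [CaseRecord-class]; its `label` is `NA` unless a TIRADS
#'   category is present and `autoLabel` mapping succeeds.
#' @param autoLabel if `TRUE` (default), derive the binary label from the
#'   TIRADS category via [mapTiradsToBinary()]; an absent category then
#'   leaves the label `NA`.
#' @param mapping TIRADS-to-binary mapping passed to [mapTiradsToBinary()].
#' @export
parseAnnotationXML <- function(path, imageSize = integer(0),
                               autoLabel = TRUE,
                               mapping = defaultTiradsMapping()) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e)
                    stop("malformed XML in '", path, "': ",
                         conditionMessage(e)))
  caseId <- xml2::xml_attr(doc, "id")
  if (is.na(caseId)) caseId <- tools::file_path_sans_ext(basename(path))
  tir <- xml2::xml_find_first(doc, ".//tirads")
  tirads <- if (inherits(tir, "xml_missing")) character(0) else
    trimws(xml2::xml_text(tir))
  if (length(tirads) && !nzchar(tirads)) tirads <- character(0)
  marks <- xml2::xml_find_all(doc, ".//mark")
  contours <- list()
  for (mk in marks) {
    pts <- xml2::xml_find_all(mk, ".//point")
    xy <- cbind(as.numeric(xml2::xml_attr(pts, "x")),
                as.numeric(xml2::xml_attr(pts, "y")))
    if (nrow(xy) < 3) {
      warning("skipping a coordinate list with fewer than 3 points in '",
              path, "'")
      next
    }
    contours <- c(contours, NoduleContour(xy, imageSize = imageSize))
  }
  if (length(contours) == 0)
    stop("no usable coordinate list in '", path, "'")
  label <- NA_integer_
  if (autoLabel && length(tirads))
    label <- mapTiradsToBinary(tirads, mapping)
  CaseRecord(caseId, contours, label = label, tirads = tirads,
             imageRef = path)
}

#' Write a case record as annotation XML
#'
#' Inverse of [parseAnnotationXML()]: serializes the contours (full double
#' precision, lossless for integer pixel coordinates) and the TIRADS
#' category, if any.
#'
#' @param case a [CaseRecord-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeAnnotationXML <- function(case, path) {
  doc <- xml2::xml_new_root("case", id = case@caseId)
  if (length(case@tirads))
    xml2::xml_add_child(doc, "tirads", case@tirads)
  fmt <- function(z) formatC(z, format = "g", digits = 17)
  for (ct in case@contours) {
    mk <- xml2::xml_add_child(doc, "mark")
    ptsNode <- xml2::xml_add_child(mk, "points")
    p <- contourPoints(ct)
    for (i in seq_len(nrow(p)))
      xml2::xml_add_child(ptsNode, "point", x = fmt(p[i, 1]),
                          y = fmt(p[i, 2]))
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Default TIRADS-to-binary mapping
#'
#' TIRADS 2 and 3 map to benign (0); 4a, 4b, 4c and 5 map to malignant (1).
#' The mapping is a declared convention (override via the `mapping`
#' argument of [mapTiradsToBinary()]), chosen so that intermediate-risk
#' categories count as positive, which reproduces the heavy malignant
#' majority of the open thyroid cohort.
#'
#' @return named integer vector.
#' @export
defaultTiradsMapping <- function() {
  c("2" = 0L, "3" = 0L, "4a" = 1L, "4b" = 1L, "4c" = 1L, "5" = 1L)
}

#' Map a TIRADS category to a binary label
#'
#' @param category TIRADS category text (vectorized).
#' @param mapping named integer vector of 0/1 values; defaults to
#'   [defaultTiradsMapping()].
#' @return integer vector of 0/1 labels.
#' @export
mapTiradsToBinary <- function(category, mapping = defaultTiradsMapping()) {
  category <- trimws(as.character(category))
  bad <- !category %in% names(mapping)
  if (any(bad))
    stop("unmapped TIRADS category: ",
         paste(unique(category[bad]), collapse = ", "))
  unname(mapping[category])
}

#' Build a labeled feature table from a cohort
#'
#' Extracts the 27-feature vector of every contour of every case and stacks
#' them into a [LabeledFeatureTable-class]: one row per nodule, with
#' provenance columns (`case_id`, `source_tag`), the 28 flattened feature
#' columns and the binary `label`.
#'
#' @param cases list of [CaseRecord-class] with labels assigned.
#' @param ... passed on to [extractFeatures()].
#' @return a [LabeledFeatureTable-class].
#' @export
buildFeatureTable <- function(cases, ...) {
  rows <- vector("list", 0L)
  for (case in cases) {
    if (is.na(case@label))
      stop("case '", case@caseId, "' has no label")
    for (ct in case@contours) {
      fl <- tryCatch(flattenFeatures(extractFeatures(ct, ...)),
                     error = function(e)
                       stop("feature extraction failed for case '",
                            case@caseId, "': ", conditionMessage(e)))
      rows[[length(rows) + 1L]] <-
        data.frame(case_id = case@caseId, source_tag = case@sourceTag,
                   as.list(fl), label = case@label,
                   stringsAsFactors = FALSE)
    }
  }
  new("LabeledFeatureTable", table = do.call(rbind, rows))
}

#' @describeIn buildFeatureTable extract the underlying `data.frame`.
#' @param x a `LabeledFeatureTable`.
#' @export
featureTable <- function(x) {
  stopifnot(is(x, "LabeledFeatureTable"))
  x@table
}

#' Write / read a labeled feature table as CSV
#'
#' Comma-delimited UTF-8 text with a header row, `'.'` decimal separator
#' and full double precision, so that `readFeatureTable(writeFeatureTable(t))`
#' round-trips numerically at 15 significant digits. Reading validates the
#' schema (column names, numeric features, binary label) and fails with a
#' `schema mismatch` error otherwise.
#'
#' @param table a [LabeledFeatureTable-class].
#' @param path CSV file path.
#' @return `writeFeatureTable` returns `path` invisibly;
#'   `readFeatureTable` returns a [LabeledFeatureTable-class].
#' @export
writeFeatureTable <- function(table, path) {
  stopifnot(is(table, "LabeledFeatureTable"))
  tab <- table@table
  num <- flatFeatureNames()
  tab[num] <- lapply(tab[num], function(z) formatC(z, format = "g",
                                                   digits = 17))
  utils::write.csv(tab, path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname writeFeatureTable
#' @export
readFeatureTable <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         fileEncoding = "UTF-8")
  want <- featureTableColumns()
  absent <- setdiff(want, names(tab))
  if (length(absent))
    stop("schema mismatch: missing columns ", paste(absent, collapse = ", "))
  tab <- tab[want]
  if (!all(tab$label %in% c(0L, 1L)))
    stop("schema mismatch: label not binary")
  tab$label <- as.integer(tab$label)
  new("LabeledFeatureTable", table = tab)
}
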