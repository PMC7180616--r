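# Annotation tables use one CSV dialect everywhere:
#   image_id,shape,cx,cy,r,w,h,class_id,confidence,tags
# Circles fill r and leave w,h empty; rectangles the reverse. Ground truth
# leaves confidence empty. Coordinates are 0-based continuous pixels,
# origin at the image top-left.

ann_columns <- c("image_id", "shape", "cx", "cy", "r", "w", "h",
                 "class_id", "confidence", "tags")

#' Read an annotation or detection table
#'
#' Parses the package's annotation CSV dialect (header
#' `image_id,shape,cx,cy,r,w,h,class_id,confidence,tags`) or its JSON-lines
#' equivalent (one record object per line). Records are validated row by
#' row; a malformed row raises an error naming its line number.
#'
#' @param path File path.
#' @param dialect `"csv"` (default) or `"jsonl"`.
#' @return A data frame with the columns above; zero rows for a
#'   header-only file.
#' @export
read_annotations <- function(path, dialect = c("csv", "jsonl")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop_input("file not found: ", path)
  if (dialect == "csv") {
    df <- utils::read.csv(path, stringsAsFactors = FALSE,
                          colClasses = c(image_id = "character",
                                         shape = "character",
                                         tags = "character"))
    if (!identical(names(df), ann_columns))
      stop_input("unexpected header; need ", paste(ann_columns, collapse = ","))
  } else {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (!length(lines)) {
      df <- as.data.frame(stats::setNames(
        c(list(character(0), character(0)), rep(list(numeric(0)), 5),
          list(integer(0), numeric(0), character(0))), ann_columns))
    } else {
      recs <- lapply(seq_along(lines), function(i) {
        rec <- tryCatch(jsonlite::fromJSON(lines[i]),
                        error = function(e) stop_input(
                          "malformed JSON record at line ", i, ": ",
                          conditionMessage(e)))
        out <- stats::setNames(as.list(rep(NA, length(ann_columns))), ann_columns)
        out[names(rec)] <- rec
        as.data.frame(out, stringsAsFactors = FALSE)
      })
      df <- do.call(rbind, recs)
      df$image_id <- as.character(df$image_id)
      df$shape <- as.character(df$shape)
      df$tags <- as.character(df$tags)
      for (cc in c("cx", "cy", "r", "w", "h", "confidence"))
        df[[cc]] <- as.numeric(df[[cc]])
      df$class_id <- as.integer(df$class_id)
    }
  }
  df$tags[is.na(df$tags)] <- ""
  validate_annotations(df)
  df
}

validate_annotations <- function(df) {
  for (i in seq_len(nrow(df))) {
    line <- i + 1L  # header is line 1
    sh <- df$shape[i]
    if (!sh %in% c("circle", "rect"))
      stop_input("line ", line, ": unknown shape '", sh, "'")
    if (!is.finite(df$cx[i]) || !is.finite(df$cy[i]))
      stop_input("line ", line, ": non-finite center coordinates")
    if (sh == "circle") {
      if (!is.finite(df$r[i]) || df$r[i] < 0)
        stop_input("line ", line, ": circle needs a non-negative radius")
    } else {
      if (!is.finite(df$w[i]) || !is.finite(df$h[i]) ||
          df$w[i] < 0 || df$h[i] < 0)
        stop_input("line ", line, ": rect needs non-negative w and h")
    }
    if (!is.na(df$confidence[i]) &&
        (df$confidence[i] < 0 || df$confidence[i] > 1))
      stop_input("line ", line, ": confidence outside [0, 1]")
  }
  invisible(df)
}

fmt_num <- function(x) ifelse(is.na(x), "", sprintf("%.6f", x))

#' Write an annotation or detection table
#'
#' Writes records in the dialect of [read_annotations()], with
#' deterministic formatting: numeric fields at 6 decimal places with a
#' locale-independent decimal point, stable sort by `image_id` then
#' confidence descending (ground truth, with no confidence, last within an
#' image). `write_annotations` followed by `read_annotations` is the
#' identity up to that formatting precision.
#'
#' @param records Data frame with (a subset of) the dialect columns;
#'   missing columns are filled as empty.
#' @param path Output file path.
#' @param dialect `"csv"` (default) or `"jsonl"`.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(records, path, dialect = c("csv", "jsonl")) {
  dialect <- match.arg(dialect)
  df <- as.data.frame(records, stringsAsFactors = FALSE)
  for (cc in setdiff(ann_columns, names(df)))
    df[[cc]] <- if (cc %in% c("image_id", "shape", "tags")) NA_character_
                else NA_real_
  if (all(is.na(df$shape)) && nrow(df))
    df$shape <- if ("r" %in% names(records) &&
                    !all(is.na(records$r))) "circle" else "rect"
  df <- df[, ann_columns, drop = FALSE]
  conf_key <- ifelse(is.na(df$confidence), -Inf, df$confidence)
  df <- df[order(df$image_id, -conf_key, seq_len(nrow(df))), , drop = FALSE]
  if (dialect == "csv") {
    lines <- paste(ann_columns, collapse = ",")
    if (nrow(df)) {
      body <- paste(
        df$image_id, df$shape,
        fmt_num(df$cx), fmt_num(df$cy), fmt_num(df$r),
        fmt_num(df$w), fmt_num(df$h),
        ifelse(is.na(df$class_id), "", as.character(df$class_id)),
        fmt_num(df$confidence),
        ifelse(is.na(df$tags), "", df$tags),
        sep = ",")
      lines <- c(lines, body)
    }
    writeLines(lines, path)
  } else {
    lines <- vapply(seq_len(nrow(df)), function(i) {
      rec <- as.list(df[i, , drop = FALSE])
      rec <- rec[!vapply(rec, function(v) is.na(v) || identical(v, ""), TRUE)]
      jsonlite::toJSON(rec, auto_unbox = TRUE, digits = 6)
    }, "")
    writeLines(lines, path)
  }
  invisible(path)
}

#' Import rectangular annotations from VOC-style XML
#'
#' Reads a Pascal-VOC annotation file and returns rectangle records in
#' center format. Pixel coordinates are treated as 0-based half-open, so a
#' box with `xmin = 0, xmax = 4` has width 4 and center 2.
#'
#' @param path Path to the XML file.
#' @return An annotation data frame (shape `"rect"`, no confidence).
#' @export
read_voc_xml <- function(path) {
  if (!file.exists(path)) stop_input("file not found: ", path)
  doc <- xml2::read_xml(path)
  fname <- xml2::xml_text(xml2::xml_find_first(doc, ".//filename"))
  if (is.na(fname) || !nzchar(fname))
    fname <- sub("\\.xml$", "", basename(path))
  objs <- xml2::xml_find_all(doc, ".//object")
  if (!length(objs)) {
    out <- as.data.frame(stats::setNames(
      c(list(character(0), character(0)), rep(list(numeric(0)), 5),
        list(integer(0), numeric(0), character(0))), ann_columns))
    return(out)
  }
  num <- function(node, tag)
    as.numeric(xml2::xml_text(xml2::xml_find_first(node, paste0(".//", tag))))
  recs <- lapply(objs, function(o) {
    xmin <- num(o, "xmin"); ymin <- num(o, "ymin")
    xmax <- num(o, "xmax"); ymax <- num(o, "ymax")
    if (any(!is.finite(c(xmin, ymin, xmax, ymax))))
      stop_input("malformed bndbox in ", path)
    nm <- xml2::xml_text(xml2::xml_find_first(o, ".//name"))
    data.frame(image_id = fname, shape = "rect",
               cx = (xmin + xmax) / 2, cy = (ymin + ymax) / 2,
               r = NA_real_, w = xmax - xmin, h = ymax - ymin,
               class_id = 1L, confidence = NA_real_,
               tags = paste0("name=", nm), stringsAsFactors = FALSE)
  })
  do.call(rbind, recs)
}

#' Write a grayscale image matrix as PNG
#'
#' @param image Numeric matrix in `[0, 1]`, rows = y.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_image_png <- function(image, path) {
  png::writePNG(clamp(image, 0, 1), path)
  invisible(path)
}
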