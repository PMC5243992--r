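#' Derive the McCarty H-score from proportion and intensity
#'
#' The H-score of an immunohistochemistry (IHC) rating is the product of the
#' stained-cell proportion (a percentage in increments of 5) and the staining
#' intensity (1 = weak, 2 = moderate, 3 = strong), giving a value between 0
#' and 300. A proportion of 0 means no stained cancer cells: intensity must
#' then be absent (`NA`) and the H-score is 0.
#'
#' @param proportion Integer vector of stained proportions, each in
#'   `{0, 5, 10, ..., 100}`.
#' @param intensity Integer vector of intensities in `{1, 2, 3}`, `NA`
#'   exactly where `proportion` is 0.
#' @return Integer vector of H-scores in `[0, 300]`.
#' @examples
#' derive_h_score(100, 3) # 300
#' derive_h_score(35, 2)  # 70
#' derive_h_score(0, NA)  # 0
#' @export
derive_h_score <- function(proportion, intensity) {
  if (length(proportion) != length(intensity)) {
    stop("`proportion` and `intensity` must have the same length", call. = FALSE)
  }
  if (anyNA(proportion)) {
    stop("`proportion` must not contain missing values", call. = FALSE)
  }
  bad <- proportion < 0 | proportion > 100 | proportion %% 5 != 0
  if (any(bad)) {
    stop("proportion must be a multiple of 5 in [0, 100]; offending value(s): ",
         paste(unique(proportion[bad]), collapse = ", "), call. = FALSE)
  }
  absent <- is.na(intensity)
  if (any(absent & proportion > 0)) {
    stop("intensity is absent for rating(s) with proportion > 0 (element ",
         paste(which(absent & proportion > 0), collapse = ", "), ")",
         call. = FALSE)
  }
  if (any(!absent & proportion == 0)) {
    stop("intensity is present for rating(s) with proportion == 0 (element ",
         paste(which(!absent & proportion == 0), collapse = ", "), ")",
         call. = FALSE)
  }
  if (any(!absent & !(intensity %in% 1:3))) {
    stop("intensity must be 1, 2 or 3", call. = FALSE)
  }
  out <- integer(length(proportion))
  out[!absent] <- as.integer(proportion[!absent] * intensity[!absent])
  out
}

#' Validate a detection annotation table
#'
#' Checks the long-format detection table: recognised (case-insensitive)
#' labels, 0-based row/column indices inside the grid, and a complete grid --
#' every `(image_id, rater_id)` pair must label each of the `rows * cols`
#' squares exactly once.
#'
#' @param data Data frame with columns `image_id`, `rater_id`, `rater_type`,
#'   `row`, `col`, `label`.
#' @param rows,cols Grid dimensions (default 6 x 6).
#' @return A validated tibble with labels folded to lower case and integer
#'   coordinates.
#' @export
validate_detection <- function(data, rows = 6, cols = 6) {
  required <- c("image_id", "rater_id", "rater_type", "row", "col", "label")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0) {
    stop("detection table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  data <- tibble::as_tibble(data)
  data$label <- tolower(as.character(data$label))
  data$rater_type <- tolower(as.character(data$rater_type))
  data$image_id <- as.character(data$image_id)
  data$rater_id <- as.character(data$rater_id)
  data$row <- as.integer(data$row)
  data$col <- as.integer(data$col)

  bad_label <- !(data$label %in% SQUARE_LABELS)
  if (any(bad_label)) {
    stop("unknown label '", data$label[which(bad_label)[1]], "' at table row ",
         which(bad_label)[1], call. = FALSE)
  }
  bad_type <- !(data$rater_type %in% RATER_TYPES)
  if (any(bad_type)) {
    stop("unknown rater_type '", data$rater_type[which(bad_type)[1]],
         "' at table row ", which(bad_type)[1], call. = FALSE)
  }
  out_of_grid <- data$row < 0 | data$row >= rows | data$col < 0 | data$col >= cols
  if (any(out_of_grid)) {
    i <- which(out_of_grid)[1]
    stop("square (", data$row[i], ",", data$col[i], ") at table row ", i,
         " is outside the ", rows, "x", cols, " grid", call. = FALSE)
  }

  key <- paste(data$image_id, data$rater_id, data$row, data$col, sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) {
    i <- which(dup)[1]
    stop("duplicate square: image '", data$image_id[i], "', rater '",
         data$rater_id[i], "', square (", data$row[i], ",", data$col[i], ")",
         call. = FALSE)
  }
  counts <- dplyr::count(data, .data$image_id, .data$rater_id)
  short <- counts[counts$n != rows * cols, , drop = FALSE]
  if (nrow(short) > 0) {
    expect_keys <- as.vector(outer(0:(rows - 1), 0:(cols - 1),
                                   function(r, c) paste(r, c)))
    got <- data[data$image_id == short$image_id[1] &
                  data$rater_id == short$rater_id[1], ]
    miss <- setdiff(expect_keys, paste(got$row, got$col))
    stop("incomplete grid for image '", short$image_id[1], "', rater '",
         short$rater_id[1], "': ", short$n[1], " of ", rows * cols,
         " squares (missing e.g. (", gsub(" ", ",", miss[1]), "))",
         call. = FALSE)
  }
  dplyr::arrange(data, .data$image_id, .data$rater_id, .data$row, .data$col)
}

#' Read and write detection annotation tables
#'
#' CSV interchange format: header
#' `image_id,rater_id,rater_type,row,col,label` with labels in
#' `{cancer, no_cancer, no_tissue}` (case-insensitive) and 0-based, row-major
#' grid coordinates.
#'
#' @param path File path.
#' @param rows,cols Grid dimensions used for validation.
#' @return `read_detection_table()` returns a validated tibble;
#'   `write_detection_table()` returns `path` invisibly.
#' @export
read_detection_table <- function(path, rows = 6, cols = 6) {
  data <- readr::read_csv(path, col_types = readr::cols(
    image_id = readr::col_character(),
    rater_id = readr::col_character(),
    rater_type = readr::col_character(),
    row = readr::col_integer(),
    col = readr::col_integer(),
    label = readr::col_character()
  ))
  validate_detection(data, rows = rows, cols = cols)
}

#' @rdname read_detection_table
#' @param data A detection table as returned by [validate_detection()].
#' @export
write_detection_table <- function(data, path) {
  cols <- c("image_id", "rater_id", "rater_type", "row", "col", "label")
  readr::write_csv(data[, cols], path)
  invisible(path)
}

#' Validate an IHC rating table
#'
#' Enforces the rating invariants: proportion a multiple of 5 in
#' `[0, 100]`, intensity in `{1, 2, 3}` and absent exactly when proportion is
#' 0, at most one rating per `(image_id, rater_id)`. The H-score column is
#' always recomputed from proportion and intensity, never trusted from input.
#'
#' @param data Data frame with columns `image_id`, `rater_id`, `rater_type`,
#'   `proportion`, `intensity`.
#' @return A validated tibble with a derived `h_score` column.
#' @export
validate_ihc <- function(data) {
  required <- c("image_id", "rater_id", "rater_type", "proportion", "intensity")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0) {
    stop("IHC table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  data <- tibble::as_tibble(data)
  data$image_id <- as.character(data$image_id)
  data$rater_id <- as.character(data$rater_id)
  data$rater_type <- tolower(as.character(data$rater_type))
  data$proportion <- as.integer(data$proportion)
  data$intensity <- as.integer(data$intensity)
  if (!all(data$rater_type %in% RATER_TYPES)) {
    stop("rater_type must be 'lay' or 'expert'", call. = FALSE)
  }
  key <- paste(data$image_id, data$rater_id, sep = "\r")
  if (anyDuplicated(key)) {
    i <- which(duplicated(key))[1]
    stop("duplicate rating: image '", data$image_id[i], "', rater '",
         data$rater_id[i], "'", call. = FALSE)
  }
  data$h_score <- derive_h_score(data$proportion, data$intensity)
  dplyr::arrange(data, .data$image_id, .data$rater_id)
}

#' Read and write IHC rating tables
#'
#' CSV interchange format: header
#' `image_id,rater_id,rater_type,proportion,intensity`; the intensity field
#' is empty when proportion is 0. H-scores are derived on load.
#'
#' @param path File path.
#' @return `read_ihc_table()` returns a validated tibble with `h_score`;
#'   `write_ihc_table()` returns `path` invisibly.
#' @export
read_ihc_table <- function(path) {
  data <- readr::read_csv(path, col_types = readr::cols(
    image_id = readr::col_character(),
    rater_id = readr::col_character(),
    rater_type = readr::col_character(),
    proportion = readr::col_integer(),
    intensity = readr::col_integer()
  ))
  validate_ihc(data)
}

#' @rdname read_ihc_table
#' @param data An IHC rating table as returned by [validate_ihc()].
#' @export
write_ihc_table <- function(data, path) {
  cols <- c("image_id", "rater_id", "rater_type", "proportion", "intensity")
  readr::write_csv(data[, cols], path)
  invisible(path)
}
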