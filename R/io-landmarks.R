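#' Read paired landmarks from CSV or MNI tag files
#'
#' Two dialects are supported:
#' \describe{
#'   \item{`csv`}{Header plus four numeric columns
#'     `fixed_y, fixed_x, moving_y, moving_x` in mm.}
#'   \item{`mni_tag`}{The two-volume `Points` block of an MNI tag point
#'     file: each record carries six coordinates
#'     `x1 y1 z1 x2 y2 z2` (volume 1 = fixed, volume 2 = moving) and an
#'     optional quoted label.  The in-plane `(y, x)` coordinates are kept;
#'     `z` is dropped (the package registers 2D slices).}
#' }
#'
#' @param path file to read.
#' @param format `"csv"` or `"mni_tag"`; default guesses from the
#'   extension (`.tag` means `mni_tag`).
#' @param case_id label for the returned set.
#' @return A [landmark_set()].
#' @export
read_landmarks <- function(path, format = c("auto", "csv", "mni_tag"),
                           case_id = NULL) {
  if (!file.exists(path))
    stop(sprintf("read_landmarks: file not found: %s", path))
  format <- match.arg(format)
  if (format == "auto")
    format <- if (tolower(tools::file_ext(path)) == "tag") "mni_tag" else "csv"
  if (is.null(case_id))
    case_id <- tools::file_path_sans_ext(basename(path))
  if (format == "csv") read_landmarks_csv(path, case_id)
  else read_landmarks_tag(path, case_id)
}

read_landmarks_csv <- function(path, case_id) {
  df <- tryCatch(utils::read.csv(path, header = TRUE),
                 error = function(e)
                   stop(sprintf("read_landmarks: cannot parse %s (%s)",
                                path, conditionMessage(e))))
  if (nrow(df) < 1L)
    stop(sprintf("read_landmarks: no landmark records in %s (pairing error)", path))
  if (ncol(df) < 4L)
    stop(sprintf("read_landmarks: expected 4 numeric columns (fixed_y, fixed_x, moving_y, moving_x) in %s", path))
  m <- as.matrix(df[, 1:4])
  storage.mode(m) <- "double"
  bad <- which(!stats::complete.cases(m))
  if (length(bad))
    stop(sprintf("read_landmarks: malformed record at line %d of %s",
                 bad[1] + 1L, path))
  landmark_set(m[, 1:2, drop = FALSE], m[, 3:4, drop = FALSE], case_id)
}

read_landmarks_tag <- function(path, case_id) {
  lines <- readLines(path, warn = FALSE)
  vol_line <- grep("^\\s*Volumes\\s*=", lines, value = TRUE)
  if (length(vol_line)) {
    nvol <- suppressWarnings(as.integer(gsub("[^0-9]", "", vol_line[1])))
    if (!is.na(nvol) && nvol != 2L)
      stop(sprintf("read_landmarks: %s declares %d volumes; paired landmarks need 2",
                   path, nvol))
  }
  start <- grep("^\\s*Points\\s*=", lines)
  if (!length(start))
    stop(sprintf("read_landmarks: no 'Points =' block in %s", path))
  body <- lines[start[1]:length(lines)]
  body[1] <- sub("^\\s*Points\\s*=\\s*[0-9]*\\s*;?", "", body[1])
  txt <- paste(body, collapse = "\n")
  txt <- gsub("\"[^\"]*\"", "", txt)       # strip labels
  txt <- gsub(";", " ", txt)
  toks <- strsplit(trimws(txt), "\\s+")[[1]]
  toks <- toks[nzchar(toks)]
  if (!length(toks))
    stop(sprintf("read_landmarks: empty Points block in %s (pairing error)", path))
  vals <- suppressWarnings(as.numeric(toks))
  if (any(is.na(vals)))
    stop(sprintf("read_landmarks: non-numeric token '%s' in Points block of %s",
                 toks[which(is.na(vals))[1]], path))
  if (length(vals) %% 6L != 0L)
    stop(sprintf("read_landmarks: Points block of %s has %d coordinates, not a multiple of 6 (pairing error)",
                 path, length(vals)))
  m <- matrix(vals, ncol = 6, byrow = TRUE)    # x1 y1 z1 x2 y2 z2
  landmark_set(cbind(m[, 2], m[, 1]), cbind(m[, 5], m[, 4]), case_id)
}

#' Write paired landmarks to CSV
#'
#' Counterpart of [read_landmarks()]'s CSV dialect.
#'
#' @param lm a [landmark_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_landmarks <- function(lm, path) {
  stopifnot(inherits(lm, "landmark_set"))
  df <- data.frame(fixed_y = lm$fixed_points[, 1],
                   fixed_x = lm$fixed_points[, 2],
                   moving_y = lm$moving_points[, 1],
                   moving_x = lm$moving_points[, 2])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
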