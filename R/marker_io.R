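#' Write a marker sequence as a Qualisys-style TSV export
#'
#' Tab-separated file with a `Frame` column, a `Time` column (seconds), and
#' `<label>_X`, `<label>_Y`, `<label>_Z` columns (millimeters) per marker.
#' Missing samples (gaps) are written as zeros, the convention of tracked
#' mocap exports.
#'
#' @param seq A [marker_seq()].
#' @param path Output file path.
#' @param digits Decimal digits for positions.
#' @return `path`, invisibly.
#' @export
write_marker_tsv <- function(seq, path, digits = 4) {
  stopifnot(inherits(seq, "marker_seq"))
  labels <- marker_labels(seq)
  n <- length(seq$t)
  cols <- vector("list", 2 + 3 * length(labels))
  cols[[1]] <- seq_len(n)
  cols[[2]] <- sprintf("%.6f", seq$t)
  nm <- c("Frame", "Time")
  k <- 3L
  for (lab in labels) {
    xyz <- seq$positions[, , lab, drop = TRUE]
    if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
    xyz[is.na(xyz)] <- 0   # gap convention
    for (j in 1:3) {
      cols[[k]] <- sprintf(paste0("%.", digits, "f"), xyz[, j])
      nm <- c(nm, paste0(lab, "_", c("X", "Y", "Z")[j]))
      k <- k + 1L
    }
  }
  header <- paste(nm, collapse = "\t")
  body <- do.call(paste, c(cols, sep = "\t"))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a marker TSV export
#'
#' Parses the dialect written by [write_marker_tsv()]. Frames where all three
#' coordinates of a marker are exactly zero (or blank) are marked missing
#' (`NA`), the gap convention of tracked mocap exports.
#'
#' @param path Input file path.
#' @param required_labels Optional character vector; an error is raised naming
#'   any required marker absent from the header.
#' @return A [marker_seq()].
#' @export
read_marker_tsv <- function(path, required_labels = NULL) {
  df <- utils::read.delim(path, check.names = FALSE)
  if (nrow(df) == 0) stop("marker file is empty: ", path)
  nm <- names(df)
  if (!all(c("Frame", "Time") %in% nm))
    stop("marker file lacks Frame/Time columns: ", path)
  coord_cols <- grep("_(X|Y|Z)$", nm, value = TRUE)
  labels <- unique(sub("_(X|Y|Z)$", "", coord_cols))
  if (!is.null(required_labels)) {
    absent <- setdiff(required_labels, labels)
    if (length(absent) > 0)
      stop("marker file is missing required markers: ",
           paste(absent, collapse = ", "))
  }
  n <- nrow(df)
  pos <- array(NA_real_, dim = c(n, 3, length(labels)),
               dimnames = list(NULL, c("X", "Y", "Z"), labels))
  for (lab in labels) {
    xyz <- as.matrix(df[, paste0(lab, "_", c("X", "Y", "Z"))])
    gap <- rowSums(xyz == 0, na.rm = TRUE) == 3 | rowSums(is.na(xyz)) > 0
    xyz[gap, ] <- NA_real_
    pos[, , lab] <- xyz
  }
  marker_seq(df$Time, pos)
}
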