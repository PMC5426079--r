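#' Read a grayscale image
#'
#' Reads a PGM file (plain `P2` or binary `P5`, 8- or 16-bit) or a
#' headerless CSV of intensities into a numeric matrix with rows indexing y.
#' The format is chosen from the file extension (`.pgm` / anything else is
#' treated as CSV).
#'
#' @param path file path.
#' @return numeric matrix of intensities.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("cannot read image: ", path, call. = FALSE)
  if (grepl("\\.pgm$", path, ignore.case = TRUE)) return(read_pgm(path))
  as.matrix(read.table(path, sep = ",", header = FALSE))
}

#' Write a grayscale image
#'
#' Writes a numeric matrix as a plain-text PGM (`P2`) or as CSV, by
#' extension.  Values are rounded; `maxval` defaults to 255 and may be up to
#' 65535 (used for label maps).
#'
#' @param img numeric matrix.
#' @param path destination path.
#' @param maxval maximum gray value written in the PGM header.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path, maxval = 255L) {
  stopifnot(is.matrix(img))
  if (grepl("\\.pgm$", path, ignore.case = TRUE)) {
    v <- round(t(img)) # PGM is row-major
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("P2", paste(ncol(img), nrow(img)), as.character(maxval)),
               con)
    apply_rows <- split(as.integer(v), rep(seq_len(nrow(img)),
                                           each = ncol(img)))
    writeLines(vapply(apply_rows, paste, "", collapse = " "), con)
  } else {
    write.table(round(img), path, sep = ",", row.names = FALSE,
                col.names = FALSE)
  }
  invisible(path)
}

read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", 2L))
  if (!magic %in% c("P2", "P5"))
    stop("not a PGM file (P2/P5): ", path, call. = FALSE)
  # header tokens: width, height, maxval; '#' comments allowed
  tokens <- integer(0)
  buf <- character(0)
  while (length(tokens) < 3L) {
    ch <- rawToChar(readBin(con, "raw", 1L))
    if (length(ch) == 0L || ch == "") stop("truncated PGM header")
    if (ch == "#") {
      repeat {
        ch <- rawToChar(readBin(con, "raw", 1L))
        if (ch %in% c("\n", "\r")) break
      }
      ch <- " "
    }
    if (grepl("[[:space:]]", ch)) {
      if (length(buf)) {
        tokens <- c(tokens, as.integer(paste(buf, collapse = "")))
        buf <- character(0)
      }
    } else buf <- c(buf, ch)
  }
  w <- tokens[1]; h <- tokens[2]; maxval <- tokens[3]
  if (magic == "P2") {
    vals <- scan(con, what = integer(), n = w * h, quiet = TRUE)
  } else {
    sz <- if (maxval > 255) 2L else 1L
    vals <- readBin(con, "integer", n = w * h, size = sz, signed = FALSE,
                    endian = "big")
  }
  matrix(vals, nrow = h, ncol = w, byrow = TRUE)
}

#' Read / write a binary mask
#'
#' Masks are 0/1 matrices; on disk any nonzero intensity is foreground.
#'
#' @param path file path.
#' @return 0/1 integer matrix.
#' @export
read_mask <- function(path) {
  m <- read_image(path)
  (m > 0) + 0L
}

#' @param mask 0/1 matrix.
#' @rdname read_mask
#' @export
write_mask <- function(mask, path) {
  write_image(ifelse(mask > 0, 255, 0), path)
}
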