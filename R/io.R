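#' Validate or coerce long-format gradient data
#'
#' A gradient dataset is long-format repeated-measures data with one row per
#' subject-stimulus observation: a subject identifier, the stimulus-dimension
#' value `d`, a subject-level covariate `u` (constant within subject) and a
#' continuous response `y`.
#'
#' @param x a data.frame with columns `subject`, `d`, `u`, `y` (extra columns
#'   are kept but ignored by the analyses).
#' @return `x` with `subject` as a factor and class `"gradient_data"`.
#' @export
as_gradient_data <- function(x) {
  stopifnot(is.data.frame(x))
  need <- c("subject", "d", "u", "y")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  for (col in c("d", "u", "y")) {
    v <- x[[col]]
    if (!is.numeric(v)) {
      v2 <- suppressWarnings(as.numeric(as.character(v)))
      if (anyNA(v2) && !all(is.na(v) == is.na(v2)))
        stop("column `", col, "` has non-numeric entries (first bad row: ",
             which(is.na(v2) & !is.na(v))[1L], ")")
      x[[col]] <- v2
    }
    if (anyNA(x[[col]]))
      stop("column `", col, "` has missing values (first at row ",
           which(is.na(x[[col]]))[1L], ")")
  }
  x$subject <- factor(x$subject)
  u_per_subj <- tapply(x$u, x$subject, function(v) length(unique(v)))
  bad <- names(u_per_subj)[u_per_subj > 1L]
  if (length(bad))
    stop("`u` varies within subject(s): ", paste(bad, collapse = ", "))
  if (!inherits(x, "gradient_data")) class(x) <- c("gradient_data", class(x))
  x
}

#' Read / write gradient datasets as delimited text
#'
#' Plain comma-separated text with a header containing at least
#' `subject,d,u,y`. Floats are written with 17 significant digits so a
#' write/read round trip is lossless.
#'
#' @param path file path.
#' @return `read_gradient_csv()` returns a validated `"gradient_data"`
#'   data.frame; `write_gradient_csv()` returns `path` invisibly.
#' @export
read_gradient_csv <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  as_gradient_data(x)
}

#' @rdname read_gradient_csv
#' @param data a gradient dataset.
#' @export
write_gradient_csv <- function(data, path) {
  data <- as_gradient_data(data)
  out <- data.frame(subject = as.character(data$subject),
                    d = format(data$d, digits = 17, trim = TRUE, scientific = FALSE),
                    u = format(data$u, digits = 17, trim = TRUE, scientific = FALSE),
                    y = format(data$y, digits = 17, trim = TRUE, scientific = FALSE))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
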