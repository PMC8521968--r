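#' Annotated audiogram dataset
#'
#' A data frame of audiometric records: columns `id`, `age` (integer 0-120 or
#' `NA`), `gender` (`"unspecified"`, `"female"`, `"male"`), and `f125` ...
#' `f8000` (thresholds in dB-HL at the standard frequencies; `NA` =
#' undefined). Every record must define at least four frequencies.
#'
#' @param df Data frame with the columns above.
#' @return The validated data frame with class `audiogram_dataset`.
#' @export
audiogram_dataset <- function(df) {
  fcols <- paste0("f", standard_frequencies())
  need <- c("id", "age", "gender", fcols)
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "),
                         call. = FALSE)
  df <- as.data.frame(df)[, need]
  df$age <- as.integer(df$age)
  if (any(!is.na(df$age) & (df$age < 0L | df$age > 120L))) {
    stop("`age` must lie in [0, 120]", call. = FALSE)
  }
  df$gender <- as.character(df$gender)
  if (any(!df$gender %in% c("unspecified", "female", "male"))) {
    stop("`gender` must be unspecified/female/male", call. = FALSE)
  }
  X <- as.matrix(df[, fcols])
  if (any(rowSums(!is.na(X)) < 4)) {
    stop("every record must define at least 4 frequencies", call. = FALSE)
  }
  if (any(!is.finite(X[!is.na(X)]))) {
    stop("thresholds must be finite", call. = FALSE)
  }
  class(df) <- c("audiogram_dataset", "data.frame")
  df
}

#' Read / write audiogram datasets as CSV
#'
#' The CSV schema is `id, age, gender, f125, ..., f8000`; empty cells denote
#' undefined thresholds or unspecified age, and an empty gender cell is read
#' as `"unspecified"`.
#'
#' @param path File path.
#' @rdname audiogram_io
#' @export
read_audiograms <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$gender[is.na(df$gender) | df$gender == ""] <- "unspecified"
  audiogram_dataset(df)
}

#' @param dataset An [audiogram_dataset()].
#' @rdname audiogram_io
#' @export
write_audiograms <- function(dataset, path) {
  utils::write.csv(as.data.frame(dataset), path, row.names = FALSE,
                   na = "")
  invisible(path)
}
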