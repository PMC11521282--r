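#' Sex-specific annual mortality table
#'
#' A life table maps integer age to `qx`, the annual probability of death.
#' Tables must cover at least ages 65-90; queries above the covered range
#' return the last available value (the model never extrapolates mortality
#' downwards). Abridged (5-year) tables are accepted and expanded by
#' repeating the interval value for each single year of age, matching the
#' model's annual cycle.
#'
#' @param age Integer ages, strictly increasing.
#' @param qx Annual death probabilities in \[0, 1\], same length as `age`.
#' @param sex `"female"` or `"male"`.
#' @return A `life_table` object.
#' @export
life_table <- function(age, qx, sex = c("female", "male")) {
  sex <- match.arg(sex)
  age <- as.integer(age)
  if (length(age) != length(qx) || length(age) < 1) {
    stop("age and qx must be non-empty vectors of equal length")
  }
  if (is.unsorted(age, strictly = TRUE)) stop("age column must be strictly increasing")
  bad <- which(!is.finite(qx) | qx < 0 | qx > 1)
  if (length(bad)) {
    stop("qx outside [0, 1] at age(s) ", paste(age[bad], collapse = ", "))
  }
  # expand abridged rows: carry each qx forward to the next listed age
  if (any(diff(age) > 1L)) {
    full_age <- seq(min(age), max(age))
    qx <- qx[findInterval(full_age, age)]
    age <- full_age
  }
  structure(list(age = age, qx = qx, sex = sex), class = "life_table")
}

#' @export
print.life_table <- function(x, ...) {
  cat("<life_table> sex =", x$sex, "| ages", min(x$age), "-", max(x$age),
      "| q(", min(x$age), ") =", signif(x$qx[1], 3),
      "q(", max(x$age), ") =", signif(tail(x$qx, 1), 3), "\n")
  invisible(x)
}

#' Read a life table from a delimited file
#'
#' Expects a tab- or comma-separated file with header columns `age` and
#' `qx`, one file per sex, as in published abridged life tables.
#'
#' @param path Path to the file.
#' @param sex `"female"` or `"male"`.
#' @return A `life_table` object.
#' @export
read_life_table <- function(path, sex = c("female", "male")) {
  sex <- match.arg(sex)
  tb <- read.delim(path, sep = "", stringsAsFactors = FALSE)
  if (!all(c("age", "qx") %in% names(tb))) {
    tb <- read.delim(path, sep = ",", stringsAsFactors = FALSE)
  }
  if (!all(c("age", "qx") %in% names(tb))) {
    stop("life table file must have 'age' and 'qx' columns: ", path)
  }
  life_table(tb$age, tb$qx, sex = sex)
}

#' Write a life table to a tab-separated file
#'
#' @param lt A `life_table` object.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_life_table <- function(lt, path) {
  write.table(data.frame(age = lt$age, qx = lt$qx), path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Annual death probability at a given age
#'
#' Age is floored to an integer (annual cycles, integer start ages); ages
#' above the table's range return the last available value; ages below its
#' minimum are an error.
#'
#' @param lt A `life_table` object.
#' @param age Age(s) in years, numeric.
#' @return Numeric vector of annual death probabilities.
#' @export
mortality <- function(lt, age) {
  stopifnot(inherits(lt, "life_table"), all(age >= 0))
  a <- floor(age)
  if (any(a < min(lt$age))) {
    stop("age below life-table minimum (", min(lt$age), ")")
  }
  idx <- pmin(length(lt$age), a - min(lt$age) + 1)
  lt$qx[idx]
}

#' Packaged synthetic life tables
#'
#' Loads the bundled synthetic life table for the requested sex. These
#' tables are a constructed stand-in for the abridged life table of Japan
#' 2022: single-year `qx` values for ages 65-100 obtained by log-linear
#' hazard interpolation through approximate Japanese old-age mortality
#' anchors (see [synthetic_japan_life_table()]). They reproduce the order
#' of magnitude and age/sex pattern of the official table, not its exact
#' cell values.
#'
#' @param sex `"female"` or `"male"`.
#' @return A `life_table` object.
#' @export
packaged_life_table <- function(sex = c("female", "male")) {
  sex <- match.arg(sex)
  path <- system.file("extdata",
                      paste0("lifetable_japan2022_synthetic_", sex, ".tsv"),
                      package = "hipcea")
  if (path == "") stop("packaged life table fixture not found for sex ", sex)
  read_life_table(path, sex = sex)
}
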