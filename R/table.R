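#' 2x4 case-control contingency table
#'
#' Container for case and control counts across the four joint-exposure
#' categories of two binary factors. The category order is fixed and
#' documented as (A0B0, A1B0, A0B1, A1B1), with A0B0 the reference.
#'
#' @param cases,controls Non-negative integer vectors of length 4 in category
#'   order (A0B0, A1B0, A0B1, A1B1).
#' @return An object of class `addint_table`: a list with integer vectors
#'   `cases` and `controls`, each named by category.
#' @examples
#' oral_cancer()
#' addint_table(cases = c(3, 8, 6, 225), controls = c(20, 18, 12, 166))
#' @export
addint_table <- function(cases, controls) {
  for (nm in c("cases", "controls")) {
    x <- get(nm)
    if (length(x) != 4 || anyNA(x) || any(x < 0) || any(x != round(x)))
      stop("'", nm, "' must be 4 non-negative integer counts", call. = FALSE)
  }
  if (sum(cases) + sum(controls) == 0)
    stop("table must contain at least one subject", call. = FALSE)
  cats <- c("A0B0", "A1B0", "A0B1", "A1B1")
  structure(list(cases = stats::setNames(as.integer(cases), cats),
                 controls = stats::setNames(as.integer(controls), cats)),
            class = "addint_table")
}

#' @export
print.addint_table <- function(x, ...) {
  cat("2x4 case-control table (", sum(x$cases), " cases, ",
      sum(x$controls), " controls)\n", sep = "")
  print(rbind(cases = x$cases, controls = x$controls))
  invisible(x)
}

#' @export
as.data.frame.addint_table <- function(x, ...) expand_subjects(x)

#' Expand a contingency table to subject-level records
#'
#' @param table An [addint_table()].
#' @return A data frame with one row per subject and columns `outcome`
#'   (1 = case), `factor_a` and `factor_b`.
#' @export
expand_subjects <- function(table) {
  stopifnot(inherits(table, "addint_table"))
  a <- c(0L, 1L, 0L, 1L)
  b <- c(0L, 0L, 1L, 1L)
  n <- c(table$cases, table$controls)
  data.frame(
    outcome  = rep(rep(c(1L, 0L), each = 4), times = n),
    factor_a = rep(c(a, a), times = n),
    factor_b = rep(c(b, b), times = n)
  )
}

#' Collapse subject-level records to a 2x4 table
#'
#' Inverse of [expand_subjects()]; only meaningful when there are no
#' confounders to preserve.
#'
#' @param data Data frame with binary columns `outcome`, `factor_a`,
#'   `factor_b`.
#' @return An [addint_table()].
#' @export
collapse_subjects <- function(data) {
  check_subject_data(data)
  cat_idx <- 1L + data$factor_a + 2L * data$factor_b
  counts <- function(keep) tabulate(cat_idx[keep], nbins = 4)
  addint_table(cases = counts(data$outcome == 1),
               controls = counts(data$outcome == 0))
}

check_subject_data <- function(data) {
  need <- c("outcome", "factor_a", "factor_b")
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols))
    stop("subject data lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  for (nm in need)
    if (!all(data[[nm]] %in% c(0, 1)))
      stop("column '", nm, "' must be binary 0/1", call. = FALSE)
  invisible(NULL)
}

# names of confounder columns, in order
confounder_cols <- function(data)
  setdiff(names(data), c("outcome", "factor_a", "factor_b"))

#' Read a 2x4 contingency table from CSV or JSON
#'
#' The CSV format has header `group,a0b0,a1b0,a0b1,a1b1` and two rows named
#' `cases` and `controls`. The JSON format is an object with arrays `cases`
#' and `controls`, each of length 4 in the same category order.
#'
#' @param path Path to a `.csv` or `.json` file.
#' @return An [addint_table()].
#' @export
read_addint_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    x <- jsonlite::read_json(path, simplifyVector = TRUE)
    if (!all(c("cases", "controls") %in% names(x)))
      stop("JSON table must contain 'cases' and 'controls' arrays",
           call. = FALSE)
    return(addint_table(x$cases, x$controls))
  }
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  want <- c("group", "a0b0", "a1b0", "a0b1", "a1b1")
  if (!identical(tolower(names(d)), want))
    stop("malformed header in ", path, ": expected '",
         paste(want, collapse = ","), "'", call. = FALSE)
  rows <- match(c("cases", "controls"), tolower(d$group))
  if (anyNA(rows))
    stop("table file must have rows named 'cases' and 'controls'",
         call. = FALSE)
  counts <- as.matrix(d[rows, -1])
  bad <- which(is.na(counts) | counts < 0, arr.ind = TRUE)
  if (nrow(bad))
    stop("invalid count for ", c("cases", "controls")[bad[1, 1]], " cell '",
         want[-1][bad[1, 2]], "' (line ", rows[bad[1, 1]] + 1L, ")",
         call. = FALSE)
  addint_table(cases = counts[1, ], controls = counts[2, ])
}

#' Write a 2x4 contingency table to CSV or JSON
#'
#' @param table An [addint_table()].
#' @param path Destination; format chosen by extension (`.json` or `.csv`).
#' @return `path`, invisibly.
#' @export
write_addint_table <- function(table, path) {
  stopifnot(inherits(table, "addint_table"))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(list(cases = unname(table$cases),
                              controls = unname(table$controls)),
                         path, digits = NA)
  } else {
    d <- data.frame(group = c("cases", "controls"),
                    rbind(unname(table$cases), unname(table$controls)))
    names(d) <- c("group", "a0b0", "a1b0", "a0b1", "a1b1")
    utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Read subject-level records from CSV
#'
#' Expects columns `outcome,factor_a,factor_b` followed by any number of
#' numeric confounder columns.
#'
#' @param path Path to a CSV file.
#' @return A data frame validated for binary outcome/factors.
#' @export
read_subject_data <- function(path) {
  d <- utils::read.csv(path)
  check_subject_data(d)
  d
}

#' The oral-cancer worked example
#'
#' Case-control counts of smoking and alcohol use in relation to oral cancer
#' among male veterans under 60, the classic example of Rothman and Keller
#' used throughout the additive-interaction literature. Factor A is smoking,
#' factor B alcohol use.
#'
#' @return An [addint_table()] with cases (3, 8, 6, 225) and controls
#'   (20, 18, 12, 166) across (A0B0, A1B0, A0B1, A1B1).
#' @export
oral_cancer <- function() {
  read_addint_table(system.file("extdata", "oral_cancer.csv",
                                package = "addint", mustWork = TRUE))
}
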