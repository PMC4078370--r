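#' Paths to the shipped cohort fixtures
#'
#' Plain-text transcriptions of the published per-patient tables: SUVmax and
#' absolute volumes (with the original footnote symbols kept as missing-data
#' codes), the per-patient overlap percentages with their printed mean row,
#' and a *synthetic* per-patient eligibility flag table whose reason counts
#' match the reported exclusions (the published tables do not state which excluded
#' patient carried which reason, so the per-patient assignment is invented).
#'
#' @param which `"table1"`, `"table2"` or `"flags"`.
#' @return File path.
#' @export
cohort_fixture_path <- function(which = c("table1", "table2", "flags")) {
  which <- match.arg(which)
  fn <- switch(which,
               table1 = "table1_suvmax_volumes.csv",
               table2 = "table2_overlap.csv",
               flags = "cohort_flags_synthetic.csv")
  system.file("extdata", fn, package = "petbtv", mustWork = TRUE)
}

# parse a printed table cell: numeric, or NA carrying the symbol as a code
parse_cells <- function(x) {
  x <- trimws(as.character(x))
  val <- suppressWarnings(as.numeric(x))
  code <- ifelse(is.na(val) & nzchar(x) & !is.na(x), x, NA_character_)
  list(value = val, code = code)
}

#' Read the per-patient SUVmax / volume table
#'
#' Returns the patient rows with numeric columns; non-numeric cells (the
#' printed footnote symbols and the `mCR` marker) become `NA` and their code
#' is kept in a parallel `codes` attribute. The printed `Median` / `Mean`
#' rows are returned separately in attribute `"printed_summary"`.
#'
#' @param path CSV path; defaults to the shipped fixture.
#' @return A data.frame with columns `patient`, `pre_suvmax`, `post_suvmax`,
#'   `gtv_cc`, `pre40_cc`, `pre50_cc`, `post90_cc`, `post80_cc`, `post70_cc`,
#'   `post60_cc`.
#' @export
read_table1 <- function(path = cohort_fixture_path("table1")) {
  raw <- utils::read.csv(path, check.names = FALSE, fileEncoding = "UTF-8",
                         colClasses = "character")
  expected <- c("Patient number", "Pre-treatment SUVmax",
                "Post-treatment SUVmax", "GTV", "Pre40%", "Pre50%",
                "Post90%", "Post80%", "Post70%", "Post60%")
  if (!identical(names(raw), expected))
    stop("malformed table: unexpected column headers")
  is_summary <- raw[[1]] %in% c("Median", "Mean")
  pat <- raw[!is_summary, ]
  out <- data.frame(patient = as.integer(pat[[1]]))
  cols <- c(pre_suvmax = 2, post_suvmax = 3, gtv_cc = 4, pre40_cc = 5,
            pre50_cc = 6, post90_cc = 7, post80_cc = 8, post70_cc = 9,
            post60_cc = 10)
  codes <- data.frame(patient = out$patient)
  for (nm in names(cols)) {
    p <- parse_cells(pat[[cols[[nm]]]])
    out[[nm]] <- p$value
    codes[[nm]] <- p$code
  }
  if (anyNA(out$patient)) stop(sprintf("malformed patient id near row %d",
                                       which(is.na(out$patient))[1]))
  summary_rows <- raw[is_summary, ]
  printed <- list()
  for (i in seq_len(nrow(summary_rows))) {
    vals <- suppressWarnings(as.numeric(summary_rows[i, -1]))
    names(vals) <- names(cols)
    printed[[summary_rows[i, 1]]] <- vals
  }
  attr(out, "codes") <- codes
  attr(out, "printed_summary") <- printed
  out
}

#' Read the per-patient overlap-percentage table
#'
#' @param path CSV path; defaults to the shipped fixture.
#' @return A data.frame with `patient` and eight `ofXX_YY` columns (percent
#'   of the PostYY% volume inside the PreXX% volume); the printed mean row is
#'   in attribute `"printed_mean"`.
#' @export
read_table2 <- function(path = cohort_fixture_path("table2")) {
  raw <- utils::read.csv(path, check.names = FALSE, fileEncoding = "UTF-8",
                         colClasses = "character")
  expected <- c("Patient",
                paste0("Pre40%:Post", c(90, 80, 70, 60), "%"),
                paste0("Pre50%:Post", c(90, 80, 70, 60), "%"))
  if (!identical(names(raw), expected))
    stop("malformed table: unexpected column headers")
  is_mean <- raw[[1]] == "Mean"
  pat <- raw[!is_mean, ]
  nm <- c(paste0("of40_", c(90, 80, 70, 60)), paste0("of50_", c(90, 80, 70, 60)))
  out <- data.frame(patient = as.integer(pat[[1]]))
  for (j in seq_along(nm)) {
    v <- as.numeric(pat[[j + 1]])
    if (anyNA(v)) stop(sprintf("malformed value in column %d", j + 1))
    out[[nm[j]]] <- v
  }
  pm <- as.numeric(raw[is_mean, -1])
  names(pm) <- nm
  attr(out, "printed_mean") <- pm
  out
}

#' Read per-patient eligibility flags
#'
#' @param path CSV path; defaults to the shipped synthetic fixture.
#' @return A data.frame of flags suitable for [check_eligibility()].
#' @export
read_cohort_flags <- function(path = cohort_fixture_path("flags")) {
  utils::read.csv(path)
}

#' Filter a cohort by scan-pair eligibility
#'
#' Applies [check_eligibility()] row by row, preserving order, and tallies
#' exclusion reasons.
#'
#' @param records Data.frame with a `patient` id column plus the eligibility
#'   flag columns.
#' @return List with `included` (data.frame), `excluded` (data.frame with a
#'   `reason` column) and `reason_counts` (named integer vector over all five
#'   reasons).
#' @export
filter_cohort <- function(records) {
  if (anyDuplicated(records$patient))
    stop("duplicate patient ids in cohort")
  res <- lapply(seq_len(nrow(records)),
                function(i) check_eligibility(records[i, ]))
  inc <- vapply(res, `[[`, logical(1), "included")
  reason <- vapply(res, `[[`, character(1), "reason")
  excluded <- records[!inc, , drop = FALSE]
  excluded$reason <- reason[!inc]
  counts <- table(factor(reason[!inc], levels = names(eligibility_reasons)))
  list(included = records[inc, , drop = FALSE],
       excluded = excluded,
       reason_counts = stats::setNames(as.integer(counts), names(counts)))
}

#' Check the threshold-nesting property on a volume table
#'
#' Segmentation at a higher fraction of SUVmax can only shrink the volume, so
#' each patient row must satisfy Post90 <= Post80 <= Post70 <= Post60 and
#' Pre50 <= Pre40.
#'
#' @param tab1 Output of [read_table1()].
#' @param patients Patient ids to check (default: rows with complete
#'   post-treatment volumes).
#' @return Logical vector named by patient id.
#' @export
table1_nesting_ok <- function(tab1, patients = NULL) {
  if (is.null(patients))
    patients <- tab1$patient[stats::complete.cases(
      tab1[, c("post90_cc", "post80_cc", "post70_cc", "post60_cc")])]
  rows <- tab1[match(patients, tab1$patient), ]
  ok <- with(rows, post90_cc <= post80_cc & post80_cc <= post70_cc &
               post70_cc <= post60_cc & pre50_cc <= pre40_cc)
  stats::setNames(ok, patients)
}

#' Recompute the published cohort summaries from the transcribed tables
#'
#' Recomputes, over the analysis set (the patients present in the overlap
#' table), the mean GTV / Pre40 / Pre50 volumes, the eight mean overlap
#' fractions, the GTV range, the analysis-set size and the number of patients
#' whose Post90 volume lies fully inside Pre40, and compares each against the
#' value printed in the tables' own summary rows at a +/-0.05 tolerance
#' (one-decimal rounding agreement).
#'
#' @param table1_path,table2_path Fixture CSV paths.
#' @param tol Comparison tolerance on rounded values.
#' @return A data.frame with columns `quantity`, `computed`, `printed`,
#'   `pass`; attributes `n_analysis`, `gtv_range`, `n_full_post90_in_pre40`.
#' @export
reproduce_tables <- function(table1_path = cohort_fixture_path("table1"),
                             table2_path = cohort_fixture_path("table2"),
                             tol = 0.05) {
  tab1 <- read_table1(table1_path)
  tab2 <- read_table2(table2_path)
  analysis <- tab2$patient
  rows <- tab1[match(analysis, tab1$patient), ]
  printed_mean <- attr(tab1, "printed_summary")[["Mean"]]
  printed_of <- attr(tab2, "printed_mean")

  quantities <- character(); computed <- numeric(); printed <- numeric()
  add <- function(q, comp, pr) {
    quantities[[length(quantities) + 1]] <<- q
    computed[[length(computed) + 1]] <<- round_half_up(comp, 1)
    printed[[length(printed) + 1]] <<- pr
  }
  vol_cols <- c("gtv_cc", "pre40_cc", "pre50_cc", "post90_cc", "post80_cc",
                "post70_cc", "post60_cc")
  for (cl in vol_cols)
    add(paste0("mean_", cl), cohort_summary(rows[[cl]])$mean, printed_mean[[cl]])
  for (cl in names(printed_of))
    add(paste0("mean_", cl), cohort_summary(tab2[[cl]])$mean, printed_of[[cl]])

  out <- data.frame(quantity = quantities, computed = computed,
                    printed = printed,
                    pass = abs(computed - printed) <= tol + 1e-9)
  attr(out, "n_analysis") <- length(analysis)
  attr(out, "gtv_range") <- range(rows$gtv_cc)
  attr(out, "n_full_post90_in_pre40") <- sum(tab2$of40_90 == 100)
  out
}
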