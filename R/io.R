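#' @importFrom utils read.csv write.csv
NULL

# canonical column order for cohort CSVs
.cohort_columns <- c("mouse_id", "strain", "sex", "site", "treatment_group",
                     "day", "distance", "body_weight")

# default header aliases (MPD-style headers -> canonical names); users may
# extend via the `aliases` argument of read_cohort()
.default_aliases <- c(
  animal_id = "mouse_id", id = "mouse_id", mouseid = "mouse_id",
  testing_site = "site", test_site = "site",
  group = "treatment_group", treatment = "treatment_group",
  test_day = "day",
  total_distance = "distance", distance_cm = "distance", dist = "distance",
  weight = "body_weight", bw = "body_weight"
)

#' Read and validate a long-format locomotor cohort table
#'
#' Reads a CSV with one row per mouse per test day: columns `mouse_id`,
#' `strain`, `sex` (`F`/`M`), `site` (e.g. `JAX`/`UNC`), `treatment_group`
#' (`cocaine`/`saline`), `day`, `distance` (cm traveled in the 60-min
#' post-injection interval) and `body_weight` (g, day-1 value). Common
#' alternative headers are mapped to canonical names via `aliases`.
#'
#' Rows with an empty `distance` field are retained with `NA` distance.
#' Validation enforces the record invariants: test day must belong to the
#' protocol schedule, distances must be non-negative, weights positive, and
#' each mouse must carry a single strain/sex/site/treatment across its rows.
#'
#' @param path path to a CSV file.
#' @param strict if `TRUE` (default), duplicated `(mouse_id, day)` rows are an
#'   error; otherwise the last row wins with a warning.
#' @param aliases named character vector mapping non-canonical headers to
#'   canonical column names, merged over the built-in MPD-style map.
#' @param schedule a [protocol_schedule()].
#' @return A `cohort_table`: a [tibble::tibble] of validated records with
#'   attributes `source` (the file path) and `schema_version`.
#' @seealso [write_cohort()], [validate_schedule()]
#' @export
read_cohort <- function(path, strict = TRUE, aliases = character(),
                        schedule = protocol_schedule()) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- read.csv(path, stringsAsFactors = FALSE,
                  colClasses = "character", check.names = FALSE,
                  na.strings = character())
  names(raw) <- tolower(trimws(names(raw)))
  amap <- c(aliases, .default_aliases)
  hit <- names(raw) %in% names(amap)
  names(raw)[hit] <- unname(amap[names(raw)[hit]])
  missing_cols <- setdiff(.cohort_columns, names(raw))
  if (length(missing_cols) > 0L) {
    stop("schema error: missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  raw <- raw[.cohort_columns]
  to_num <- function(x) suppressWarnings(as.numeric(ifelse(x == "", NA, x)))
  tab <- tibble::tibble(
    mouse_id = as.character(raw$mouse_id),
    strain = as.character(raw$strain),
    sex = as.character(raw$sex),
    site = as.character(raw$site),
    treatment_group = as.character(raw$treatment_group),
    day = as.integer(to_num(raw$day)),
    distance = to_num(raw$distance),
    body_weight = to_num(raw$body_weight)
  )
  dup <- duplicated(tab[c("mouse_id", "day")])
  if (any(dup)) {
    if (strict) {
      stop("integrity error: duplicate (mouse_id, day) rows: ",
           paste(utils::head(paste0(tab$mouse_id[dup], "/day ", tab$day[dup]), 5L),
                 collapse = ", "))
    }
    warning(sum(dup), " duplicate (mouse_id, day) row(s); keeping last")
    tab <- tab[!duplicated(tab[c("mouse_id", "day")], fromLast = TRUE), ]
  }
  as_cohort_table(tab, source = path, schedule = schedule)
}

#' Construct a validated cohort table from a data frame
#'
#' @param x data frame with the canonical cohort columns.
#' @param source source label stored as an attribute.
#' @param schedule a [protocol_schedule()].
#' @return A `cohort_table` tibble.
#' @export
as_cohort_table <- function(x, source = "in-memory",
                            schedule = protocol_schedule()) {
  tab <- tibble::as_tibble(x)[, .cohort_columns]
  tab$day <- as.integer(tab$day)
  bad_day <- !is.na(tab$day) & !(tab$day %in% schedule$test_days)
  if (any(bad_day)) {
    i <- which(bad_day)[1L]
    stop("integrity error: row ", i, " (mouse ", tab$mouse_id[i],
         ") has day ", tab$day[i], ", not a protocol test day")
  }
  if (anyNA(tab$day)) stop("integrity error: missing day value")
  if (any(tab$distance < 0, na.rm = TRUE)) {
    stop("integrity error: negative distance")
  }
  if (any(tab$body_weight <= 0, na.rm = TRUE)) {
    stop("integrity error: non-positive body weight")
  }
  bad_sex <- !tab$sex %in% c("F", "M")
  if (any(bad_sex)) stop("integrity error: sex must be F or M")
  if (any(!tab$treatment_group %in% c("cocaine", "saline"))) {
    stop("integrity error: treatment_group must be 'cocaine' or 'saline'")
  }
  # each mouse carries a single strain/sex/site/treatment across rows
  for (col in c("strain", "sex", "site", "treatment_group")) {
    n_lev <- tapply(tab[[col]], tab$mouse_id, function(v) length(unique(v)))
    if (any(n_lev > 1L)) {
      stop("integrity error: mouse ", names(n_lev)[which(n_lev > 1L)[1L]],
           " has inconsistent ", col)
    }
  }
  tab <- tab[order(tab$mouse_id, tab$day), ]
  attr(tab, "source") <- source
  attr(tab, "schema_version") <- "1.0"
  class(tab) <- c("cohort_table", class(tab))
  tab
}

#' Write a cohort table as a canonical CSV
#'
#' Columns are written in canonical order and rows sorted by
#' `(mouse_id, day)`. Missing numeric values are written as empty fields;
#' distances are written with 3 decimal places so that a write/read
#' round-trip is exact at that precision.
#'
#' @param table a `cohort_table`.
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_cohort <- function(table, path) {
  tab <- as.data.frame(table)[, .cohort_columns]
  tab <- tab[order(tab$mouse_id, tab$day), ]
  fmt <- function(x, digits) ifelse(is.na(x), "", formatC(x, digits = digits,
                                                          format = "f"))
  out <- data.frame(
    mouse_id = tab$mouse_id, strain = tab$strain, sex = tab$sex,
    site = tab$site, treatment_group = tab$treatment_group,
    day = tab$day,
    distance = fmt(tab$distance, 3L),
    body_weight = fmt(tab$body_weight, 3L),
    stringsAsFactors = FALSE
  )
  write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Check a cohort against the sensitization protocol
#'
#' Report-only validation: for each mouse, lists the protocol test days it is
#' missing, flags derived phenotypes that become underivable because of the
#' missing days, and flags rows whose recorded injection (if an `injection`
#' column is present in `extra`) contradicts the treatment-group/day map.
#'
#' @param table a `cohort_table`.
#' @param schedule a [protocol_schedule()].
#' @param injections optional data frame with `mouse_id`, `day`, `injection`
#'   (`SAL`/`COC`) giving the injections actually administered, to be checked
#'   against the schedule.
#' @return A list of class `validation_report` with elements
#'   `missing_days` (tibble: mouse_id, day), `underivable` (tibble: mouse_id,
#'   variable, reason) and `injection_mismatch` (tibble), plus `ok` —
#'   `TRUE` when all three are empty. Serializable to JSON via
#'   [report_to_json()].
#' @export
validate_schedule <- function(table, schedule = protocol_schedule(),
                              injections = NULL) {
  mice <- unique(table$mouse_id)
  have <- table(factor(table$mouse_id, levels = mice),
                factor(table$day, levels = schedule$test_days))
  miss <- which(have == 0L, arr.ind = TRUE)
  missing_days <- tibble::tibble(
    mouse_id = mice[miss[, 1L]],
    day = schedule$test_days[miss[, 2L]]
  )
  missing_days <- missing_days[order(missing_days$mouse_id, missing_days$day), ]

  day_sets <- phenotype_day_sets()
  under <- list()
  if (nrow(missing_days) > 0L) {
    by_mouse <- split(missing_days$day, missing_days$mouse_id)
    for (m in names(by_mouse)) {
      for (v in names(day_sets)) {
        lost <- intersect(day_sets[[v]], by_mouse[[m]])
        if (length(lost) > 0L) {
          under[[length(under) + 1L]] <- tibble::tibble(
            mouse_id = m, variable = v,
            reason = paste0("missing day(s) ", paste(lost, collapse = ","))
          )
        }
      }
    }
  }
  underivable <- if (length(under)) do.call(rbind, under) else
    tibble::tibble(mouse_id = character(), variable = character(),
                   reason = character())

  mismatch <- tibble::tibble(mouse_id = character(), day = integer(),
                             expected = character(), observed = character())
  if (!is.null(injections)) {
    grp <- table$treatment_group[match(injections$mouse_id, table$mouse_id)]
    expected <- injection_on_day(grp, injections$day, schedule)
    bad <- injections$injection != expected
    mismatch <- tibble::tibble(
      mouse_id = injections$mouse_id[bad], day = as.integer(injections$day[bad]),
      expected = expected[bad], observed = injections$injection[bad]
    )
  }
  structure(
    list(missing_days = missing_days, underivable = underivable,
         injection_mismatch = mismatch,
         ok = nrow(missing_days) == 0L && nrow(mismatch) == 0L),
    class = "validation_report"
  )
}

#' Serialize a validation report to JSON
#'
#' @param report a `validation_report` from [validate_schedule()].
#' @param path optional output path; if `NULL` the JSON string is returned.
#' @return JSON string (invisibly when written to `path`).
#' @export
report_to_json <- function(report, path = NULL) {
  js <- jsonlite::toJSON(lapply(unclass(report), function(x) {
    if (is.data.frame(x)) as.data.frame(x) else x
  }), auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
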