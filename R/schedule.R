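#' The 19-day behavioral sensitization protocol schedule
#'
#' Mice are tested in the open field on nine calendar days of a 19-day
#' protocol. The saline-exposed group receives a saline injection on every
#' test day. The drug-exposed group receives saline on days 1, 2 and 12
#' (baseline and conditioned-activation probes) and cocaine on days 3, 5, 7,
#' 9, 11 (five consecutive exposures) and day 19 (expression of
#' sensitization after a one-week drug-free period).
#'
#' @return An object of class `protocol_schedule`: a list with
#'   * `test_days` — integer vector `c(1, 2, 3, 5, 7, 9, 11, 12, 19)`,
#'   * `injection_map` — data frame with columns `treatment_group`, `day`,
#'     `injection` (`"SAL"` or `"COC"`),
#'   * `cocaine_days_drug_group`, `saline_days_drug_group` — the day splits
#'     for the drug-exposed arm.
#' @examples
#' sched <- protocol_schedule()
#' sched$cocaine_days_drug_group
#' @export
protocol_schedule <- function() {
  test_days <- c(1L, 2L, 3L, 5L, 7L, 9L, 11L, 12L, 19L)
  coc_days <- c(3L, 5L, 7L, 9L, 11L, 19L)
  sal_days <- c(1L, 2L, 12L)
  injection_map <- data.frame(
    treatment_group = rep(c("cocaine", "saline"), each = length(test_days)),
    day = rep(test_days, 2L),
    injection = c(ifelse(test_days %in% coc_days, "COC", "SAL"),
                  rep("SAL", length(test_days))),
    stringsAsFactors = FALSE
  )
  structure(
    list(
      test_days = test_days,
      injection_map = injection_map,
      cocaine_days_drug_group = coc_days,
      saline_days_drug_group = sal_days
    ),
    class = "protocol_schedule"
  )
}

#' Injection given to a treatment group on a given day
#'
#' @param treatment_group `"cocaine"` or `"saline"`.
#' @param day integer test day (must be one of the protocol test days).
#' @param schedule a [protocol_schedule()].
#' @return Character vector of `"SAL"` / `"COC"`, recycled over inputs.
#' @export
injection_on_day <- function(treatment_group, day,
                             schedule = protocol_schedule()) {
  stopifnot(all(day %in% schedule$test_days))
  stopifnot(all(treatment_group %in% c("cocaine", "saline")))
  key <- paste(treatment_group, day)
  map <- schedule$injection_map
  map$injection[match(key, paste(map$treatment_group, map$day))]
}

# exposure index (1..6) of a drug-group cocaine day; NA for saline days
.exposure_index <- function(day, schedule = protocol_schedule()) {
  match(day, schedule$cocaine_days_drug_group)
}
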