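#' Day-type calendar
#'
#' Maps each weekday to a day type reflecting visitor pressure. The default
#' is the zoo calendar of the studied enclosure: closed on Monday, weekday
#' Tuesday--Friday, weekend Saturday--Sunday.
#'
#' @param mapping named character vector over `Mon ... Sun` with values in
#'   `closed`, `weekday`, `weekend`; `NULL` for the default.
#' @return an object of class `day_type_calendar` (named character vector,
#'   one entry per weekday).
#' @export
day_type_calendar <- function(mapping = NULL) {
  wd <- c("Mon", "Tue", "Wed", "Thu", "Fri", "Sat", "Sun")
  if (is.null(mapping))
    mapping <- setNames(c("closed", rep("weekday", 4L), "weekend",
                          "weekend"), wd)
  if (!identical(sort(names(mapping)), sort(wd)))
    stop_input("mapping must cover all seven weekdays Mon..Sun")
  if (!all(mapping %in% c("closed", "weekday", "weekend")))
    stop_input("day types must be closed, weekday or weekend")
  structure(mapping[wd], class = "day_type_calendar")
}

#' Annotate per-minute records with light condition and day type
#'
#' Fills (or overwrites) the `condition` and `day_type` columns of a raw
#' per-minute activity table: a minute belongs to the light condition iff
#' its minute-of-day falls in the closed-open `[light_on, light_off)` span
#' of the schedule, and its day type comes from the weekday calendar.
#' Annotation is total (every record gets exactly one condition and one day
#' type) and idempotent.
#'
#' @param records data frame with columns `timestamp` (POSIXct or ISO-8601
#'   text, minute resolution), `individual`, `active`, optional
#'   `categories`.
#' @param schedule a [light_schedule()].
#' @param calendar a [day_type_calendar()].
#' @return the annotated data frame, class `activity_table`.
#' @export
annotate_activity <- function(records, schedule = light_schedule(),
                              calendar = day_type_calendar()) {
  stopifnot(is.data.frame(records), inherits(schedule, "light_schedule"),
            inherits(calendar, "day_type_calendar"))
  need <- c("timestamp", "individual", "active")
  if (!all(need %in% names(records)))
    stop_input("records need columns ", paste(need, collapse = ", "))
  d <- as.data.frame(records)
  class(d) <- "data.frame"
  if (!inherits(d$timestamp, "POSIXct"))
    d$timestamp <- as.POSIXct(d$timestamp, tz = "UTC",
                              tryFormats = c("%Y-%m-%dT%H:%M:%OS",
                                             "%Y-%m-%dT%H:%M",
                                             "%Y-%m-%d %H:%M:%OS",
                                             "%Y-%m-%d %H:%M"))
  if (anyNA(d$timestamp)) stop_input("unparseable timestamps")
  if (anyDuplicated(d[c("individual", "timestamp")]))
    stop_input("duplicate (individual, timestamp) records")
  if (is.null(d$categories)) d$categories <- ""
  d$categories[is.na(d$categories)] <- ""
  if (any(nzchar(d$categories) & d$active == 0))
    stop_input("inactive minutes must have empty categories")
  lt <- as.POSIXlt(d$timestamp, tz = "UTC")
  minute_of_day <- lt$hour * 60L + lt$min
  d$condition <- ifelse(is_light_minute(minute_of_day, schedule),
                        "light", "dark")
  wd <- c("Mon", "Tue", "Wed", "Thu", "Fri", "Sat", "Sun")[
    (lt$wday + 6L) %% 7L + 1L]  # POSIXlt wday: 0 = Sunday
  d$day_type <- unname(unclass(calendar)[wd])
  d$date <- format(d$timestamp, "%Y-%m-%d", tz = "UTC")
  class(d) <- c("activity_table", "data.frame")
  d
}

as_activity_table <- function(table, schedule = light_schedule(),
                              calendar = day_type_calendar()) {
  if (inherits(table, "activity_table")) return(table)
  annotate_activity(table, schedule, calendar)
}

#' Ethogram activity budget
#'
#' Counts active minutes per individual, condition and (optionally)
#' ethogram category. Category scoring is multi-label: a minute carrying k
#' categories contributes 1 to each of the k category counts, so the sum
#' over categories is at least the active-minute count.
#'
#' @param table an annotated `activity_table` (raw tables are annotated
#'   with defaults first).
#' @param by `"condition"`, `"category"`, or both (default).
#' @return a data frame of counts.
#' @export
activity_budget <- function(table, by = c("condition", "category")) {
  by <- match.arg(by, several.ok = TRUE)
  d <- as_activity_table(table)
  d <- d[d$active == 1, , drop = FALSE]
  if (!"category" %in% by) {
    if (nrow(d) == 0L)
      return(data.frame(individual = character(0), condition = character(0),
                        minutes = integer(0)))
    out <- aggregate(list(minutes = rep(1L, nrow(d))),
                     d[c("individual", "condition")], sum)
    return(out[order(out$individual, out$condition), , drop = FALSE])
  }
  cats <- if (nrow(d)) strsplit(d$categories, ";", fixed = TRUE) else list()
  n_per <- lengths(cats)
  long <- data.frame(
    individual = rep(d$individual, n_per),
    condition = rep(d$condition, n_per),
    category = unlist(cats),
    stringsAsFactors = FALSE)
  long <- long[nzchar(long$category), , drop = FALSE]
  grp <- if ("condition" %in% by) c("individual", "condition", "category")
  else c("individual", "category")
  if (nrow(long) == 0L)
    return(stats::setNames(
      data.frame(matrix(character(0), ncol = length(grp)), integer(0)),
      c(grp, "minutes")))
  out <- aggregate(list(minutes = rep(1L, nrow(long))), long[grp], sum)
  out[do.call(order, out[grp]), , drop = FALSE]
}

#' Light-vs-dark Wilcoxon signed-rank test of activity
#'
#' For each individual, computes the per-calendar-day frequency of active
#' time separately in the light and dark conditions (active minutes divided
#' by that day's observed minutes in the condition, so unequal light/dark
#' durations do not bias the comparison), pairs the two frequencies by day,
#' and applies the Wilcoxon signed-rank test (zero differences excluded;
#' exact distribution for small n without ties, normal approximation with
#' continuity correction otherwise, as in [stats::wilcox.test()]).
#' Bonferroni adjustment is over the family of all individuals tested in
#' the run. Individuals with fewer than 6 paired days are flagged
#' underpowered but still computed.
#'
#' @param table an `activity_table` (raw tables are annotated with
#'   defaults).
#' @return data frame of class `lightdark_test` with columns `individual`,
#'   `n_days`, `mean_freq_light`, `mean_freq_dark`, `statistic`, `p_value`,
#'   `p_adjusted`, `flag`.
#' @export
lightdark_test <- function(table) {
  d <- as_activity_table(table)
  out <- do.call(rbind, lapply(split(d, d$individual), function(di) {
    byday <- aggregate(cbind(active = di$active,
                             minutes = rep(1L, nrow(di))),
                       di[c("date", "condition")], sum)
    li <- byday[byday$condition == "light", c("date", "active", "minutes")]
    da <- byday[byday$condition == "dark", c("date", "active", "minutes")]
    m <- merge(li, da, by = "date", suffixes = c("_light", "_dark"))
    fl <- m$active_light / m$minutes_light
    fd <- m$active_dark / m$minutes_dark
    n_days <- length(fl)
    flag <- if (n_days < 6L) "underpowered" else "ok"
    if (n_days == 0L || all(fl == fd)) {
      stat <- 0; p <- 1
      if (n_days > 0L) flag <- paste(flag, "no_nonzero_differences",
                                     sep = ";")
    } else {
      wt <- suppressWarnings(wilcox.test(fl, fd, paired = TRUE))
      stat <- unname(wt$statistic); p <- wt$p.value
    }
    data.frame(individual = di$individual[1L], n_days = n_days,
               mean_freq_light = if (n_days) mean(fl) else NA_real_,
               mean_freq_dark = if (n_days) mean(fd) else NA_real_,
               statistic = stat, p_value = p, flag = flag,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out$p_adjusted <- pmin(1, out$p_value * nrow(out))
  out <- out[c("individual", "n_days", "mean_freq_light", "mean_freq_dark",
               "statistic", "p_value", "p_adjusted", "flag")]
  class(out) <- c("lightdark_test", "data.frame")
  out
}

#' Day-type by time-of-day chi-squared test
#'
#' Per individual, builds the contingency table of active-minute counts
#' with day types (closed / weekday / weekend) as rows and time-of-day bins
#' of `bin_hours` hours as columns, and applies Pearson's chi-squared test.
#' With all three day types present and the default 3-h bins (8 per day),
#' df = (3 - 1)(8 - 1) = 14. Empty rows or columns are dropped with a
#' warning and df recomputed. `n` is the individual's total active-minute
#' count.
#'
#' @param table an `activity_table` (raw tables are annotated with
#'   defaults).
#' @param bin_hours bin width in hours; must divide 24. Default 3.
#' @return data frame of class `daytype_chisq` with columns `individual`,
#'   `n`, `statistic`, `df`, `p_value`; the per-individual contingency
#'   tables are attached as attribute `"tables"`.
#' @export
daytype_chisq <- function(table, bin_hours = 3L) {
  bin_hours <- as.integer(bin_hours)
  if (bin_hours < 1L || 24L %% bin_hours != 0L)
    stop_input("bin_hours must divide 24")
  d <- as_activity_table(table)
  d <- d[d$active == 1, , drop = FALSE]
  lt <- as.POSIXlt(d$timestamp, tz = "UTC")
  d$bin <- (lt$hour %/% bin_hours)
  tabs <- list()
  out <- do.call(rbind, lapply(split(d, d$individual), function(di) {
    tab <- table(factor(di$day_type,
                        levels = c("closed", "weekday", "weekend")),
                 factor(di$bin, levels = 0:(24L %/% bin_hours - 1L)))
    drop_r <- rowSums(tab) == 0
    drop_c <- colSums(tab) == 0
    if (any(drop_r) || any(drop_c))
      warning("empty day-type row(s) or time bin(s) dropped for ",
              di$individual[1L], "; df recomputed", call. = FALSE)
    tab <- tab[!drop_r, !drop_c, drop = FALSE]
    if (nrow(tab) < 2L || ncol(tab) < 2L)
      stop_input("contingency table for ", di$individual[1L],
                 " has fewer than 2 rows or columns after dropping ",
                 "empty margins")
    ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
    tabs[[di$individual[1L]]] <<- tab
    data.frame(individual = di$individual[1L], n = sum(tab),
               statistic = unname(ct$statistic),
               df = unname(ct$parameter), p_value = ct$p.value,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  attr(out, "tables") <- tabs
  attr(out, "bin_hours") <- bin_hours
  class(out) <- c("daytype_chisq", "data.frame")
  out
}
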