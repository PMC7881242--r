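# Temporal aggregation: ISO-week averaging, decadal splits, September-
# anchored annual means, and monthly-to-weekly interpolation of
# environmental series.

.isoWeekLabel <- function(date) format(date, "%G-W%V")

# Monday of the ISO week containing `date`.
.isoWeekStart <- function(date) {
  wd <- as.integer(format(date, "%u"))  # 1 = Monday
  date - (wd - 1L)
}

#' Average samples within ISO calendar weeks
#'
#' Weeks are ISO-8601 weeks of the sample date. Each output row is the
#' arithmetic mean of that week's samples; weeks without samples yield no
#' row. Output rows are labelled `YYYY-Www` and dated by the week's Monday.
#'
#' @param x a dated [SampleTable-class].
#' @return A [SampleTable-class] with one row per observed week.
#' @export
weeklyAverage <- function(x) {
  stopifnot(is(x, "SampleTable"))
  if (!length(x@date)) stop("weeklyAverage requires a dated table")
  wk <- .isoWeekLabel(x@date)
  start <- .isoWeekStart(x@date)
  ord <- order(start)
  wkLevels <- unique(wk[ord])
  f <- factor(wk, levels = wkLevels)
  v <- sampleValues(x)
  m <- vapply(seq_len(ncol(v)),
              function(j) as.numeric(tapply(v[, j], f, mean)),
              numeric(length(wkLevels)))
  m <- matrix(m, nrow = length(wkLevels),
              dimnames = list(wkLevels, colnames(v)))
  wkStart <- as.Date(tapply(start, f, min), origin = "1970-01-01")
  SampleTable(m, date = wkStart, varType = x@varType)
}

#' Split a dated table into calendar-year periods
#'
#' @param x a dated [SampleTable-class].
#' @param periods data.frame with columns `label`, `start`, `end`
#'   (inclusive calendar years); see [decadePeriods()].
#' @return Named list of [SampleTable-class] objects, one per period, in
#'   the order given; samples outside all periods are omitted.
#' @export
temporalSplit <- function(x, periods = decadePeriods()) {
  stopifnot(is(x, "SampleTable"))
  if (!length(x@date)) stop("temporalSplit requires a dated table")
  stopifnot(all(c("label", "start", "end") %in% names(periods)))
  if (any(periods$start > periods$end)) stop("period start must be <= end")
  if (nrow(periods) > 1L) {
    o <- order(periods$start)
    if (any(periods$end[o][-nrow(periods)] >= periods$start[o][-1L]))
      stop("periods must not overlap")
  }
  yr <- as.integer(format(x@date, "%Y"))
  out <- lapply(seq_len(nrow(periods)), function(i)
    x[yr >= periods$start[i] & yr <= periods$end[i], ])
  names(out) <- periods$label
  out
}

#' The three standard decadal periods
#'
#' 1971-1980, 1981-1990 and 1991-2000; the middle decade brackets the
#' mid-1980s Irish Sea regime shift.
#'
#' @return A data.frame with columns `label`, `start`, `end`.
#' @export
decadePeriods <- function() {
  data.frame(label = c("1970s", "1980s", "1990s"),
             start = c(1971L, 1981L, 1991L),
             end = c(1980L, 1990L, 2000L))
}

#' Interpolate a monthly series to weekly values
#'
#' Linear interpolation between month midpoints (used for sea surface
#' temperature); values outside the observed range are held constant at the
#' nearest endpoint.
#'
#' @param months `Date` vector (any day within each month) or `"YYYY-MM"`
#'   strings, one per monthly value.
#' @param values numeric monthly values.
#' @param weeks `Date` vector of target dates (typically ISO-week Mondays).
#' @return Numeric vector of interpolated values, one per entry of `weeks`.
#' @export
#' @examples
#' interpolateMonthlyToWeekly(c("2000-01", "2000-02"), c(10, 14),
#'                            as.Date("2000-01-31"))
interpolateMonthlyToWeekly <- function(months, values, weeks) {
  if (!length(months)) stop("empty monthly series")
  if (length(months) != length(values))
    stop("months and values must have equal length")
  if (is.character(months)) months <- as.Date(paste0(months, "-01"))
  months <- as.Date(format(as.Date(months), "%Y-%m-01"))
  mo <- as.integer(format(months, "%m"))
  yr <- as.integer(format(months, "%Y"))
  nextFirst <- as.Date(sprintf("%04d-%02d-01",
                               yr + (mo == 12L), ifelse(mo == 12L, 1L, mo + 1L)))
  nd <- as.numeric(nextFirst - months)
  mid <- as.numeric(months) + (nd - 1) / 2
  if (length(values) == 1L) return(rep(values, length(weeks)))
  stats::approx(mid, values, xout = as.numeric(as.Date(weeks)),
                method = "linear", rule = 2)$y
}

#' Assign a monthly index to weeks by month membership
#'
#' Used for the NAO index, which is carried to weeks by the month the week's
#' Monday falls in rather than interpolated.
#'
#' @param months `"YYYY-MM"` strings or `Date`s, one per value.
#' @param values numeric monthly values.
#' @param weeks `Date` vector of week-start dates.
#' @return Numeric vector, one value per week (`NA` for uncovered months).
#' @export
monthlyToWeeklyByMonth <- function(months, values, weeks) {
  if (!length(months)) stop("empty monthly series")
  key <- if (is.character(months)) months else format(as.Date(months), "%Y-%m")
  values[match(format(as.Date(weeks), "%Y-%m"), key)]
}

#' September-anchored yearly averages
#'
#' Averages each variable over September-to-August windows (the herring
#' spawning year); the output row is labelled by the window's starting
#' calendar year.
#'
#' @param x a dated [SampleTable-class].
#' @return A [SampleTable-class] with one row per observed spawning year,
#'   dated by the window's September 1st.
#' @export
yearlyAverageFromSeptember <- function(x) {
  stopifnot(is(x, "SampleTable"))
  if (!length(x@date)) stop("yearlyAverageFromSeptember requires a dated table")
  mo <- as.integer(format(x@date, "%m"))
  yr <- as.integer(format(x@date, "%Y"))
  startYr <- ifelse(mo >= 9L, yr, yr - 1L)
  lev <- sort(unique(startYr))
  f <- factor(startYr, levels = lev)
  v <- sampleValues(x)
  m <- vapply(seq_len(ncol(v)),
              function(j) as.numeric(tapply(v[, j], f, mean)),
              numeric(length(lev)))
  m <- matrix(m, nrow = length(lev),
              dimnames = list(as.character(lev), colnames(v)))
  SampleTable(m, date = as.Date(paste0(lev, "-09-01")), varType = x@varType)
}
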