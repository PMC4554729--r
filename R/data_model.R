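# Capture-record and trap-deployment structures, filtering rules,
# capture-history construction, and descriptive summaries.

#' Trap array
#'
#' A set of camera-trap stations with projected coordinates (metres) and a
#' per-occasion activity matrix.  One occasion is one calendar day; an entry
#' of 1 means the trap was active (deployed for the full day) on that
#' occasion.  The sum of the activity matrix is the survey effort in
#' trap-days.
#'
#' @param trap_id character or integer vector of unique trap identifiers.
#' @param x,y numeric vectors of projected easting/northing in metres.
#' @param activity binary matrix, traps x occasions; defaults to all-active
#'   for `n_occasions` days.
#' @param n_occasions number of daily occasions, used only when `activity`
#'   is missing.
#' @return An object of class `trap_array` with elements `trap_id`, `x`,
#'   `y`, `activity`.
#' @export
trap_array <- function(trap_id, x, y, activity = NULL, n_occasions = NULL) {
  trap_id <- as.character(trap_id)
  if (anyDuplicated(trap_id)) stop("trap_ids must be unique")
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("trap coordinates must be finite")
  n <- length(trap_id)
  if (length(x) != n || length(y) != n)
    stop("trap_id, x, y must have equal length")
  if (is.null(activity)) {
    if (is.null(n_occasions)) stop("supply activity or n_occasions")
    activity <- matrix(1L, n, n_occasions)
  }
  activity <- as.matrix(activity)
  if (nrow(activity) != n) stop("activity must have one row per trap")
  if (!all(activity %in% c(0L, 1L))) stop("activity entries must be 0/1")
  storage.mode(activity) <- "integer"
  rownames(activity) <- trap_id
  structure(list(trap_id = trap_id, x = as.numeric(x), y = as.numeric(y),
                 activity = activity),
            class = "trap_array")
}

#' @export
print.trap_array <- function(x, ...) {
  cat(sprintf("trap_array: %d traps, %d occasions, %d trap-days\n",
              length(x$trap_id), ncol(x$activity), trap_days(x)))
  invisible(x)
}

#' Total survey effort in trap-days
#' @param traps a `trap_array`.
#' @return integer: the sum of the activity matrix.
#' @export
trap_days <- function(traps) {
  stopifnot(inherits(traps, "trap_array"))
  sum(traps$activity)
}

#' Read a trap-deployment table
#'
#' Expects the deployment dialect `LOC_ID, X, Y` followed by one 1/0 column
#' per daily occasion.
#'
#' @param path CSV file path.
#' @return a [trap_array].
#' @export
read_trap_deployment <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  need <- c("LOC_ID", "X", "Y")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("trap deployment file missing column(s): ", paste(miss, collapse = ", "))
  act <- as.matrix(df[, setdiff(names(df), need), drop = FALSE])
  trap_array(df$LOC_ID, df$X, df$Y, activity = act)
}

#' Write a trap-deployment table
#' @param traps a [trap_array].
#' @param path output CSV path.
#' @export
write_trap_deployment <- function(traps, path) {
  act <- traps$activity
  colnames(act) <- paste0("D", seq_len(ncol(act)))
  df <- data.frame(LOC_ID = traps$trap_id, X = traps$x, Y = traps$y,
                   act, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read animal-capture records
#'
#' Reads the capture dialect `LOC_ID, ANIMAL_ID, TIMESTAMP` (ISO 8601
#' date-times) or the occasion-numbered variant `LOC_ID, ANIMAL_ID, SO`.
#' Malformed timestamp rows are reported with their line numbers.
#'
#' @param path CSV file path.
#' @return data.frame of class `capture_records` with columns `trap_id`,
#'   `individual_id` and either `timestamp` (POSIXct, UTC) or `occasion`
#'   (integer).
#' @export
read_capture_records <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE,
                        colClasses = "character")
  need <- c("LOC_ID", "ANIMAL_ID")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("capture file missing column(s): ", paste(miss, collapse = ", "))
  out <- data.frame(trap_id = df$LOC_ID, individual_id = df$ANIMAL_ID,
                    stringsAsFactors = FALSE)
  if ("TIMESTAMP" %in% names(df)) {
    fmts <- c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S",
              "%Y-%m-%d %H:%M", "%Y-%m-%d")
    ts <- as.POSIXct(rep(NA_real_, nrow(df)), tz = "UTC",
                     origin = "1970-01-01")
    for (fmt in fmts) {
      need <- is.na(ts)
      if (!any(need)) break
      ts[need] <- as.POSIXct(strptime(df$TIMESTAMP[need], fmt, tz = "UTC"))
    }
    bad <- which(is.na(ts) & nzchar(df$TIMESTAMP))
    if (length(bad))
      stop("unparseable TIMESTAMP on data line(s): ",
           paste(bad, collapse = ", "))
    out$timestamp <- ts
  } else if ("SO" %in% names(df)) {
    so <- suppressWarnings(as.integer(df$SO))
    bad <- which(is.na(so))
    if (length(bad))
      stop("unparseable SO (occasion) on data line(s): ",
           paste(bad, collapse = ", "))
    out$occasion <- so
  } else {
    stop("capture file missing column(s): TIMESTAMP (or SO)")
  }
  class(out) <- c("capture_records", "data.frame")
  out
}

#' Write animal-capture records
#' @param records a `capture_records` data.frame.
#' @param path output CSV path.
#' @export
write_capture_records <- function(records, path) {
  if (!is.null(records$timestamp)) {
    df <- data.frame(LOC_ID = records$trap_id,
                     ANIMAL_ID = records$individual_id,
                     TIMESTAMP = format(records$timestamp,
                                        "%Y-%m-%dT%H:%M:%S", tz = "UTC"))
  } else {
    df <- data.frame(LOC_ID = records$trap_id,
                     ANIMAL_ID = records$individual_id,
                     SO = records$occasion)
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Filter raw capture records
#'
#' Two filtering rules applied before building a capture history:
#' * same-individual, same-trap captures closer than `dedup_window_hours`
#'   to an already-kept capture are discarded (independence of captures);
#' * captures falling on an incomplete deployment day of their trap (the
#'   partial first or last day of a deployment window) are discarded.
#'
#' The second rule requires `deployment`, a data.frame with columns
#' `trap_id`, `start`, `end` (POSIXct).  A day is incomplete when the
#' deployment starts after the beginning or ends before the end of that
#' calendar day.
#'
#' @param records a `capture_records` data.frame with a `timestamp` column.
#' @param dedup_window_hours positive duplicate window in hours (default 6).
#' @param deployment optional per-trap deployment window table.
#' @return list with `kept` (filtered records) and `discarded` (records
#'   plus a `reason` column).
#' @export
filter_capture_records <- function(records, dedup_window_hours = 6,
                                   deployment = NULL) {
  if (dedup_window_hours <= 0) stop("dedup_window_hours must be > 0")
  if (nrow(records) == 0)
    return(list(kept = records, discarded = cbind(records, reason = character(0))))
  if (is.null(records$timestamp))
    stop("filtering requires timestamped records")
  reason <- rep(NA_character_, nrow(records))

  # incomplete deployment-day rule first: those captures never count
  if (!is.null(deployment)) {
    dep <- deployment
    idx <- match(records$trap_id, dep$trap_id)
    day0 <- as.POSIXct(format(records$timestamp, "%Y-%m-%d"), tz = "UTC")
    day1 <- day0 + 86400
    partial <- !is.na(idx) &
      (dep$start[idx] > day0 | dep$end[idx] < day1)
    reason[partial] <- "incomplete deployment day"
  }

  ord <- order(records$individual_id, records$trap_id, records$timestamp)
  win <- dedup_window_hours * 3600
  last_key <- ""
  last_time <- -Inf
  for (r in ord) {
    if (!is.na(reason[r])) next
    key <- paste(records$individual_id[r], records$trap_id[r], sep = "\r")
    tm <- as.numeric(records$timestamp[r])
    if (key == last_key && tm - last_time < win) {
      reason[r] <- "duplicate within dedup window"
    } else {
      last_key <- key
      last_time <- tm
    }
  }
  drop <- !is.na(reason)
  discarded <- records[drop, , drop = FALSE]
  discarded$reason <- reason[drop]
  list(kept = records[!drop, , drop = FALSE], discarded = discarded)
}

#' Build a binary capture-history tensor
#'
#' Converts filtered capture records to the SECR likelihood input
#' `y[i, j, k]` (individual x trap x occasion).  Repeated same-day
#' same-trap captures of one individual collapse to a single 1.
#'
#' @param records filtered `capture_records`.
#' @param traps a [trap_array].
#' @param occasion_calendar Date vector, one entry per occasion, mapping
#'   calendar days to occasion index.  Not needed when records carry an
#'   `occasion` column.
#' @return object of class `capture_history`: list with binary array `y`
#'   and counts `n_individuals`, `n_traps`, `n_occasions`.
#' @export
build_capture_history <- function(records, traps, occasion_calendar = NULL) {
  stopifnot(inherits(traps, "trap_array"))
  if (nrow(records) == 0) stop("no capture records: capture history undefined")
  j <- match(records$trap_id, traps$trap_id)
  if (anyNA(j))
    stop("records at unknown trap(s): ",
         paste(unique(records$trap_id[is.na(j)]), collapse = ", "))
  if (!is.null(records$occasion)) {
    k <- records$occasion
  } else {
    if (is.null(occasion_calendar))
      stop("occasion_calendar required for timestamped records")
    k <- match(as.Date(records$timestamp, tz = "UTC"), occasion_calendar)
    if (anyNA(k))
      stop("capture date outside occasion calendar at row(s): ",
           paste(which(is.na(k)), collapse = ", "))
  }
  K <- ncol(traps$activity)
  if (any(k < 1 | k > K)) stop("occasion index outside 1..", K)
  bad <- traps$activity[cbind(j, k)] == 0L
  if (any(bad))
    stop("capture at inactive trap-occasion at row(s): ",
         paste(which(bad), collapse = ", "))
  ids <- sort(unique(records$individual_id))
  i <- match(records$individual_id, ids)
  y <- array(0L, dim = c(length(ids), length(traps$trap_id), K),
             dimnames = list(ids, traps$trap_id, NULL))
  y[cbind(i, j, k)] <- 1L
  structure(list(y = y, individual_id = ids,
                 n_individuals = length(ids),
                 n_traps = length(traps$trap_id), n_occasions = K),
            class = "capture_history")
}

#' @export
print.capture_history <- function(x, ...) {
  cat(sprintf("capture_history: %d individuals x %d traps x %d occasions, %d captures\n",
              x$n_individuals, x$n_traps, x$n_occasions, sum(x$y)))
  invisible(x)
}

#' Capture success per 100 trap-days
#'
#' @param n_captures number of independent captures.
#' @param trap_days total survey effort in trap-days.
#' @return captures per 100 trap-days (unrounded).
#' @export
capture_success <- function(n_captures, trap_days) {
  if (trap_days <= 0) stop("trap_days must be > 0")
  100 * n_captures / trap_days
}

#' Capture-frequency distribution
#'
#' Tabulates how many individuals were captured once, twice, ... .
#'
#' @param history a `capture_history`.
#' @return named integer vector: names are capture counts, values are
#'   numbers of individuals.  `sum(count * individuals)` equals the total
#'   number of captures.
#' @export
capture_frequency <- function(history) {
  stopifnot(inherits(history, "capture_history"))
  per_ind <- apply(history$y, 1, sum)
  if (any(per_ind == 0))
    stop("capture_history invariant violated: individual with zero captures")
  tab <- table(per_ind)
  out <- as.integer(tab)
  names(out) <- names(tab)
  out
}

#' Mean maximum distance moved (MMDM)
#'
#' For each individual captured at two or more distinct traps, the maximum
#' pairwise Euclidean distance among its capture traps.  MMDM is the mean
#' of these per-individual maxima; half-MMDM (a classical ad hoc buffer
#' width) is exactly MMDM/2.  Both the sample SD and SD/sqrt(n) of the
#' maxima are reported because field studies label either as "SE".
#'
#' @param history a `capture_history`.
#' @param traps the matching [trap_array].
#' @return object of class `movement_summary`: list with `per_individual`
#'   (named vector of maxima, metres), `mmdm`, `half_mmdm`, `sd`, `se`,
#'   `n_individuals`, and `defined` (FALSE when no individual moved
#'   between traps; distances are then NA, never zero).
#' @export
mmdm <- function(history, traps) {
  stopifnot(inherits(history, "capture_history"), inherits(traps, "trap_array"))
  caught <- apply(history$y, c(1, 2), sum) > 0   # individuals x traps
  maxima <- numeric(0)
  for (i in seq_len(nrow(caught))) {
    js <- which(caught[i, ])
    if (length(js) < 2) next
    d <- stats::dist(cbind(traps$x[js], traps$y[js]))
    maxima[history$individual_id[i]] <- max(d)
  }
  if (length(maxima) == 0) {
    return(structure(list(per_individual = maxima, mmdm = NA_real_,
                          half_mmdm = NA_real_, sd = NA_real_, se = NA_real_,
                          n_individuals = 0L, defined = FALSE),
                     class = "movement_summary"))
  }
  m <- mean(maxima)
  s <- stats::sd(maxima)
  structure(list(per_individual = maxima, mmdm = m, half_mmdm = m / 2,
                 sd = s, se = s / sqrt(length(maxima)),
                 n_individuals = length(maxima), defined = TRUE),
            class = "movement_summary")
}

#' @export
print.movement_summary <- function(x, ...) {
  if (!x$defined) {
    cat("movement_summary: undefined (no individual captured at >= 2 traps)\n")
  } else {
    cat(sprintf("movement_summary: MMDM %.2f km (sd %.2f, se %.2f, n = %d); half-MMDM %.2f km\n",
                x$mmdm / 1000, x$sd / 1000, x$se / 1000, x$n_individuals,
                x$half_mmdm / 1000))
  }
  invisible(x)
}
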