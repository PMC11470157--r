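## Deterministic preprocessing for nesting encounter data: dispersal
## distances, spring index, consecutive-encounter pairing, exposure intervals.

#' Euclidean distance between two UTM points
#'
#' Distance in meters between two nest locations recorded as UTM
#' easting/northing pairs (same zone, meters).
#'
#' @param p1,p2 Numeric vectors of length 2, \code{c(easting, northing)} in
#'   meters.
#' @return Distance in meters (non-negative scalar).
#' @examples
#' euclidean_distance(c(0, 0), c(3, 4)) # 5
#' @export
euclidean_distance <- function(p1, p2) {
  if (length(p1) != 2L || length(p2) != 2L)
    stop("points must be length-2 (easting, northing) vectors")
  p1 <- as.numeric(p1); p2 <- as.numeric(p2)
  if (!all(is.finite(p1)) || !all(is.finite(p2)))
    stop("non-finite coordinates")
  sqrt(sum((p1 - p2)^2))
}

#' Early-late spring index
#'
#' Centers each year's mean nest initiation date on the long-term average:
#' \code{s_j = mean_init_j - mean(mean_init)}. Positive values indicate a
#' late spring. By construction the indices sum to zero across years.
#'
#' @param mean_init_by_year Named numeric vector (names are years) or a
#'   numeric vector with a parallel \code{years} argument.
#' @param years Optional integer vector of years if
#'   \code{mean_init_by_year} is unnamed.
#' @return Named numeric vector of spring indices (days), one per year.
#' @export
spring_index <- function(mean_init_by_year, years = NULL) {
  x <- as.numeric(mean_init_by_year)
  if (length(x) == 0L) stop("need at least one year with a mean initiation date")
  if (!all(is.finite(x))) stop("non-finite mean initiation dates")
  nm <- if (!is.null(years)) as.character(years) else names(mean_init_by_year)
  s <- x - mean(x)
  names(s) <- nm
  s
}

#' Pair consecutive nest encounters of the same individual
#'
#' Retains, for each individual, every pair of encounters in consecutive
#' calendar years with valid coordinates in both, and computes the dispersal
#' distance between the two nest locations. The previous year's nest fate is
#' carried onto the pair (\code{NA} if unknown), along with the previous
#' year's last-check nest age used by the missing-fate submodel.
#'
#' @param encounters Data frame with columns \code{individual_id},
#'   \code{year}, \code{easting}, \code{northing}, \code{fate} (one of
#'   \code{"success"}, \code{"fail"}, \code{"unknown"}), and optionally
#'   \code{last_check_age}.
#' @param years Optional data frame with columns \code{year}, \code{flood},
#'   \code{mean_init_day}; if supplied, flood and spring-index covariates are
#'   attached to each pair (flood refers to the previous year,
#'   \code{w_{j-1}}).
#' @return Data frame of encounter pairs with columns \code{individual_id},
#'   \code{year} (the later year j), \code{prev_year}, \code{dispersal_m},
#'   \code{prev_fate} (0 success, 1 fail, NA unknown),
#'   \code{prev_last_check_age}, and, when \code{years} is given,
#'   \code{flood_prev} and \code{spring_index}. A \code{"dropped"} attribute
#'   summarizes encounters not used in any pair.
#' @export
pair_consecutive <- function(encounters, years = NULL) {
  req <- c("individual_id", "year", "easting", "northing", "fate")
  if (!all(req %in% names(encounters)))
    stop("encounters must have columns: ", paste(req, collapse = ", "))
  enc <- encounters[order(encounters$individual_id, encounters$year), ]
  ok_xy <- is.finite(enc$easting) & is.finite(enc$northing)
  if (!"last_check_age" %in% names(enc)) enc$last_check_age <- NA_integer_

  same_ind <- c(FALSE, enc$individual_id[-1] == enc$individual_id[-nrow(enc)])
  consec <- c(FALSE, diff(enc$year) == 1L) & same_ind
  usable <- consec & ok_xy & c(FALSE, ok_xy[-nrow(enc)])
  j <- which(usable)      # row index of the later (year j) encounter
  i <- j - 1L             # previous-year encounter

  de <- enc$easting[j] - enc$easting[i]
  dn <- enc$northing[j] - enc$northing[i]
  pf <- ifelse(enc$fate[i] == "success", 0L,
        ifelse(enc$fate[i] == "fail", 1L, NA_integer_))
  pairs <- data.frame(
    individual_id = enc$individual_id[j],
    year = enc$year[j],
    prev_year = enc$year[i],
    dispersal_m = sqrt(de^2 + dn^2),
    prev_fate = pf,
    prev_last_check_age = enc$last_check_age[i],
    stringsAsFactors = FALSE
  )
  if (!is.null(years)) {
    s <- spring_index(years$mean_init_day, years$year)
    pairs$flood_prev <- years$flood[match(pairs$prev_year, years$year)]
    pairs$spring_index <- unname(s[as.character(pairs$year)])
  }
  used <- unique(c(i, j))
  attr(pairs, "dropped") <- list(
    n_encounters = nrow(enc),
    n_pairs = nrow(pairs),
    n_encounters_unused = nrow(enc) - length(used)
  )
  pairs
}

#' Build exposure intervals from nest visit histories
#'
#' Converts per-nest visit records into the exposure intervals used by the
#' nest survival likelihood: one interval per adjacent pair of visits, with
#' length in days and a binary outcome (1 = the nest was alive or hatched at
#' the interval's end, 0 = it had failed). Visits after a terminal event
#' (hatch or failure) contribute nothing. Nests whose final recorded status
#' is neither hatched nor failed are flagged censored; by default they are
#' dropped entirely (whole-nest censoring), but their alive-to-alive
#' intervals can be retained with \code{keep_censored_intervals = TRUE}.
#'
#' @param visits Data frame with columns \code{nest_id}, \code{visit_age}
#'   (nest age in days at the visit) and \code{status} (one of
#'   \code{"alive"}, \code{"failed"}, \code{"hatched"}, \code{"unknown"});
#'   extra columns \code{individual_id} and \code{year} are carried through
#'   if present.
#' @param keep_censored_intervals Keep alive-to-alive intervals of
#'   censored nests instead of dropping the whole nest (default FALSE).
#' @return Data frame of intervals (\code{nest_id}, \code{length_days},
#'   \code{outcome}, \code{age_start}, plus carried columns) with a
#'   \code{"censored"} attribute naming the censored nests and a
#'   \code{"summary"} attribute with retained/censored counts.
#' @export
build_exposure_intervals <- function(visits, keep_censored_intervals = FALSE) {
  req <- c("nest_id", "visit_age", "status")
  if (!all(req %in% names(visits)))
    stop("visits must have columns: ", paste(req, collapse = ", "))
  carry <- intersect(c("individual_id", "year"), names(visits))
  visits <- visits[order(visits$nest_id, visits$visit_age), ]
  out <- vector("list", length(unique(visits$nest_id)))
  censored <- character(0)
  k <- 0L
  for (v in split(visits, visits$nest_id, drop = TRUE)) {
    k <- k + 1L
    if (any(diff(v$visit_age) <= 0))
      stop("non-monotone visit ages for nest ", v$nest_id[1])
    if (v$status[1] != "alive")
      stop("first visit of nest ", v$nest_id[1], " must be 'alive'")
    term <- match(TRUE, v$status %in% c("failed", "hatched"))
    cens <- is.na(term)
    last <- if (cens) nrow(v) else term
    if (cens) {
      censored <- c(censored, v$nest_id[1])
      # trailing 'unknown' statuses carry no exposure information
      last <- max(which(v$status == "alive"))
    }
    if (last < 2L) next
    idx <- seq_len(last - 1L)
    iv <- data.frame(
      nest_id = v$nest_id[1],
      length_days = v$visit_age[idx + 1L] - v$visit_age[idx],
      outcome = as.integer(v$status[idx + 1L] != "failed"),
      age_start = v$visit_age[idx],
      stringsAsFactors = FALSE
    )
    for (cc in carry) iv[[cc]] <- v[[cc]][1]
    iv$censored <- cens
    out[[k]] <- iv
  }
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(res))
    res <- data.frame(nest_id = character(0), length_days = integer(0),
                      outcome = integer(0), age_start = integer(0),
                      censored = logical(0))
  if (!keep_censored_intervals) res <- res[!res$censored, , drop = FALSE]
  res$censored <- NULL
  rownames(res) <- NULL
  attr(res, "censored") <- censored
  attr(res, "summary") <- list(
    n_nests = length(unique(visits$nest_id)),
    n_censored = length(censored),
    n_retained = length(unique(res$nest_id)),
    n_intervals = nrow(res)
  )
  res
}

#' Read preprocessed input tables
#'
#' Readers for the three input CSVs: encounter records, nest visit
#' histories, and year-level covariates. Files are UTF-8 with a header row.
#'
#' @param path Path to the CSV file.
#' @return A validated data frame.
#' @name read_inputs
NULL

#' @rdname read_inputs
#' @export
read_encounters <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("individual_id", "year", "easting", "northing", "fate")
  if (!all(req %in% names(x)))
    stop("encounters file must have columns: ", paste(req, collapse = ", "))
  bad <- !x$fate %in% c("success", "fail", "unknown")
  if (any(bad)) stop("invalid fate values: ", paste(unique(x$fate[bad]), collapse = ", "))
  x
}

#' @rdname read_inputs
#' @export
read_visits <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("nest_id", "visit_age", "status")
  if (!all(req %in% names(x)))
    stop("visits file must have columns: ", paste(req, collapse = ", "))
  x
}

#' @rdname read_inputs
#' @export
read_years <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("year", "flood", "mean_init_day")
  if (!all(req %in% names(x)))
    stop("years file must have columns: ", paste(req, collapse = ", "))
  x
}

#' Write preprocessing outputs
#'
#' Writes paired encounters and exposure intervals as CSV together with a
#' JSON summary of retained/dropped/censored counts.
#'
#' @param pairs Output of [pair_consecutive()] (or the synthetic generator).
#' @param intervals Output of [build_exposure_intervals()].
#' @param dir Output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
write_preprocessed <- function(pairs, intervals, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pp <- file.path(dir, "pairs.csv")
  ip <- file.path(dir, "intervals.csv")
  sp <- file.path(dir, "preprocessing_summary.json")
  utils::write.csv(pairs, pp, row.names = FALSE)
  utils::write.csv(intervals, ip, row.names = FALSE)
  summ <- list(pairs = attr(pairs, "dropped"),
               intervals = attr(intervals, "summary"))
  jsonlite::write_json(summ, sp, auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(c(pairs = pp, intervals = ip, summary = sp))
}
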