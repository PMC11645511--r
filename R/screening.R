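#' Flag respondents who answered faster than the speed threshold
#'
#' A respondent is flagged when mean time per assigned item falls strictly
#' below the threshold — "less than 1 second per item" — so exactly 1 s/item
#' is retained.
#'
#' @param durations total survey duration in seconds, one per respondent.
#' @param items_assigned number of items assigned, one per respondent (or a
#'   scalar recycled).
#' @param threshold seconds per item; default 1.
#' @return Logical vector of `too_fast` flags.
#' @export
filter_speeders <- function(durations, items_assigned, threshold = 1) {
  if (length(items_assigned) == 1L) {
    items_assigned <- rep(items_assigned, length(durations))
  }
  stopifnot(length(durations) == length(items_assigned))
  if (any(durations <= 0, na.rm = TRUE)) stop("durations must be positive")
  if (any(items_assigned <= 0)) stop("items_assigned must be positive")
  durations / items_assigned < threshold
}

#' Flag respondents who answered less than the minimum share of items
#'
#' Strict inequality: answering exactly half of the assigned items is
#' retained ("at least half").
#'
#' @param responses data.frame or matrix of item responses (a leading
#'   `respondent_id` column is ignored); `NA` = unanswered.
#' @param items_assigned items assigned per respondent; defaults to the number
#'   of item columns.
#' @param min_prop minimum answered proportion; default 0.5.
#' @return Logical vector of `incomplete` flags.
#' @export
filter_incomplete <- function(responses, items_assigned = NULL,
                              min_prop = 0.5) {
  m <- drop_id(responses)
  if (is.null(items_assigned)) items_assigned <- ncol(m)
  if (length(items_assigned) == 1L) {
    items_assigned <- rep(items_assigned, nrow(m))
  }
  if (any(items_assigned <= 0)) stop("items_assigned must be positive")
  answered <- rowSums(!is.na(m))
  answered / items_assigned < min_prop
}

#' Flag respondents who endorsed one or both fake conditions
#'
#' @param endorsements data.frame with 0/1 condition columns (a
#'   `respondent_id` column is ignored).
#' @param fake_ids names of the fake-condition columns.
#' @return Logical vector of `fake_endorser` flags.
#' @export
flag_fake_endorsers <- function(endorsements,
                                fake_ids = c("syndomitis", "chekalism")) {
  missing <- setdiff(fake_ids, names(endorsements))
  if (length(missing)) {
    stop("missing fake-condition columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  fk <- as.matrix(endorsements[, fake_ids, drop = FALSE])
  rowSums(fk == 1L, na.rm = TRUE) > 0
}

#' Completion rate
#'
#' Analytic respondents divided by surveys fielded.
#'
#' @param n_analytic analytic dataset size.
#' @param n_fielded surveys fielded (or assigned).
#' @return A proportion.
#' @export
completion_rate <- function(n_analytic, n_fielded) {
  stopifnot(n_fielded > 0, n_analytic >= 0, n_analytic <= n_fielded)
  n_analytic / n_fielded
}

# strip a respondent_id column if present, return a plain matrix of responses
drop_id <- function(x) {
  if (is.data.frame(x) && "respondent_id" %in% names(x)) {
    x <- x[, setdiff(names(x), "respondent_id"), drop = FALSE]
  }
  as.matrix(x)
}

#' Build the analytic dataset and the respondent accounting table
#'
#' Applies the cleaning sequence: out-of-range responses are coerced to
#' missing (and counted), respondents with response times under
#' `speed_threshold` seconds per item or with less than `min_prop` of their
#' assigned items answered are removed, and fake-condition endorsement is
#' evaluated on the remaining (analytic) respondents. A respondent failing
#' both removal rules is counted once, under `too_fast`.
#'
#' @param responses response matrix with `respondent_id` column.
#' @param durations data.frame with `respondent_id`, `duration_s`, and
#'   optionally `items_assigned`.
#' @param endorsements endorsement table with `respondent_id` column.
#' @param range declared response range, default 1-5.
#' @param fake_ids fake-condition column names.
#' @param speed_threshold seconds per item, default 1 (strict `<`).
#' @param min_prop minimum answered proportion, default 0.5 (strict `<`).
#' @param n_fielded surveys fielded, for the completion rate; defaults to the
#'   number of rows received (i.e. everyone who reached field close).
#' @return A list with `analytic` (cleaned response matrix of retained
#'   respondents), `flags` (per-respondent QC flags), and `accounting`
#'   (class `qc_accounting`).
#' @export
build_analytic <- function(responses, durations, endorsements,
                           range = c(1L, 5L),
                           fake_ids = c("syndomitis", "chekalism"),
                           speed_threshold = 1, min_prop = 0.5,
                           n_fielded = NULL) {
  if (anyDuplicated(responses$respondent_id)) {
    stop("duplicate respondent IDs", call. = FALSE)
  }
  stopifnot(identical(responses$respondent_id, durations$respondent_id),
            identical(responses$respondent_id, endorsements$respondent_id))
  n_total <- nrow(responses)
  n_fielded <- n_fielded %||% n_total

  item_cols <- setdiff(names(responses), "respondent_id")
  m <- as.matrix(responses[, item_cols, drop = FALSE])
  out_of_range <- !is.na(m) & (m < range[1] | m > range[2])
  m[out_of_range] <- NA_integer_
  cleaned <- responses
  if (n_total > 0) cleaned[, item_cols] <- m

  items_assigned <- durations$items_assigned %||% length(item_cols)
  too_fast <- filter_speeders(durations$duration_s, items_assigned,
                              speed_threshold)
  incomplete <- filter_incomplete(cleaned, items_assigned, min_prop)

  in_analytic <- !too_fast & !incomplete
  fake_endorser <- rep(NA, n_total)
  fake_endorser[in_analytic] <-
    flag_fake_endorsers(endorsements[in_analytic, , drop = FALSE], fake_ids)

  flags <- data.frame(respondent_id = responses$respondent_id,
                      too_fast = too_fast, incomplete = incomplete,
                      fake_endorser = fake_endorser,
                      in_analytic = in_analytic)

  n_analytic <- sum(in_analytic)
  accounting <- structure(list(
    surveys_fielded = n_fielded,
    final_total = n_total,
    n_too_fast = sum(too_fast),                      # overlap counted here
    n_incomplete = sum(incomplete & !too_fast),
    n_analytic = n_analytic,
    n_fake = sum(fake_endorser, na.rm = TRUE),
    n_out_of_range_values = sum(out_of_range),
    completion_rate = if (n_fielded > 0) n_analytic / n_fielded else NA_real_
  ), class = "qc_accounting")

  list(analytic = cleaned[in_analytic, , drop = FALSE],
       flags = flags, accounting = accounting)
}

#' @export
print.qc_accounting <- function(x, ...) {
  pct <- function(a, b) if (b > 0) sprintf("%.1f", 100 * a / b) else "NA"
  cat("Respondent accounting\n")
  cat(sprintf("  Surveys fielded, n                           %d\n",
              x$surveys_fielded))
  cat(sprintf("  Final total upon field close, n              %d\n",
              x$final_total))
  cat(sprintf("  Too short response times, n (%%)              %d (%s)\n",
              x$n_too_fast, pct(x$n_too_fast, x$final_total)))
  cat(sprintf("  Incomplete surveys, n/N (%%)                  %d/%d (%s)\n",
              x$n_incomplete, x$final_total,
              pct(x$n_incomplete, x$final_total)))
  cat(sprintf("  Analytic dataset, n                          %d\n",
              x$n_analytic))
  cat(sprintf("  Completion rate, n/N (%%)                     %d/%d (%s)\n",
              x$n_analytic, x$surveys_fielded,
              pct(x$n_analytic, x$surveys_fielded)))
  cat(sprintf("  Endorsed fake conditions, n/N (%%)            %d/%d (%s)\n",
              x$n_fake, x$n_analytic, pct(x$n_fake, x$n_analytic)))
  invisible(x)
}
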