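#' Tokenize free-text survey answers
#'
#' Deterministic normalization: casefold, strip punctuation, collapse
#' whitespace, split on spaces. "Identical" text runs are judged on these
#' word tokens, not on bytes.
#'
#' @param text character vector.
#' @return List of character token vectors.
#' @export
tokenize_text <- function(text) {
  text <- tolower(ifelse(is.na(text), "", text))
  text <- gsub("[^a-z0-9 ]+", " ", text)
  text <- trimws(gsub("[[:space:]]+", " ", text))
  out <- strsplit(text, " ", fixed = TRUE)
  lapply(out, function(t) t[nzchar(t)])
}

# longest common contiguous token run between two token vectors (DP over
# suffix lengths, O(len_a * len_b); answers are short)
longest_common_run <- function(a, b) {
  la <- length(a); lb <- length(b)
  if (la == 0L || lb == 0L) return(list(len = 0L, start_a = NA_integer_))
  best <- 0L; best_a <- NA_integer_
  prev <- integer(lb)
  for (i in seq_len(la)) {
    cur <- integer(lb)
    match_j <- which(b == a[i])
    for (j in match_j) {
      cur[j] <- if (j > 1L) prev[j - 1L] + 1L else 1L
      if (cur[j] > best) {
        best <- cur[j]
        best_a <- i - best + 1L
      }
    }
    prev <- cur
  }
  list(len = best, start_a = best_a)
}

#' Detect copied or identical open-text responses
#'
#' A respondent is flagged when their answer contains a contiguous run of at
#' least `min_run` word tokens that is identical to a run in at least one
#' other respondent's answer, and that run covers at least `min_cover` of the
#' respondent's own token count. Coverage is evaluated per respondent, so in
#' a matching pair only the member(s) whose own answer is sufficiently
#' covered are flagged.
#'
#' Candidate pairs are prefiltered by shared `min_run`-token shingles, so
#' collections with no verbatim overlap are processed in linear time; exact
#' run lengths are then computed per candidate pair.
#'
#' @param texts data.frame with `respondent_id` and `text` columns, or a
#'   character vector.
#' @param min_run minimum run length in words, default 10.
#' @param min_cover minimum share of the respondent's own tokens the run must
#'   cover, default 0.75.
#' @return A list of class `qc_textdup`: `flags` (logical, named by
#'   respondent), `pairs` (data.frame of matched pairs with run length, the
#'   two coverages, and the matched excerpt), `n`.
#' @export
find_copied <- function(texts, min_run = 10L, min_cover = 0.75) {
  if (is.character(texts)) {
    texts <- data.frame(respondent_id = sprintf("t%05d", seq_along(texts)),
                        text = texts)
  }
  stopifnot(nrow(texts) >= 2L)
  id <- texts$respondent_id
  toks <- tokenize_text(texts$text)
  n <- length(toks)
  lens <- lengths(toks)

  # shingle prefilter: min_run-grams -> responders containing them
  shingle_owner <- new.env(parent = emptyenv())
  for (i in seq_len(n)) {
    if (lens[i] < min_run) next
    t <- toks[[i]]
    grams <- unique(vapply(seq_len(lens[i] - min_run + 1L), function(s) {
      paste(t[s:(s + min_run - 1L)], collapse = "\037")
    }, character(1)))
    for (g in grams) {
      shingle_owner[[g]] <- c(shingle_owner[[g]], i)
    }
  }
  cand <- new.env(parent = emptyenv())
  for (g in ls(shingle_owner)) {
    own <- unique(shingle_owner[[g]])
    if (length(own) < 2L) next
    for (a in seq_along(own)) {
      for (b in seq_along(own)) {
        if (a < b) {
          key <- paste(own[a], own[b])
          cand[[key]] <- TRUE
        }
      }
    }
  }

  flags <- rep(FALSE, n)
  pair_rows <- list()
  for (key in ls(cand)) {
    ij <- as.integer(strsplit(key, " ", fixed = TRUE)[[1]])
    i <- ij[1]; j <- ij[2]
    run <- longest_common_run(toks[[i]], toks[[j]])
    if (run$len < min_run) next
    cover_i <- run$len / lens[i]
    cover_j <- run$len / lens[j]
    hit_i <- cover_i >= min_cover
    hit_j <- cover_j >= min_cover
    if (hit_i) flags[i] <- TRUE
    if (hit_j) flags[j] <- TRUE
    if (hit_i || hit_j) {
      excerpt <- paste(
        toks[[i]][run$start_a:(run$start_a + run$len - 1L)], collapse = " ")
      pair_rows[[length(pair_rows) + 1L]] <- data.frame(
        id_a = id[i], id_b = id[j], run_length = run$len,
        coverage_a = cover_i, coverage_b = cover_j, excerpt = excerpt)
    }
  }
  pairs <- if (length(pair_rows)) {
    do.call(rbind, pair_rows)
  } else {
    data.frame(id_a = character(), id_b = character(),
               run_length = integer(), coverage_a = numeric(),
               coverage_b = numeric(), excerpt = character())
  }
  structure(list(flags = setNames(flags, id), pairs = pairs, n = n),
            class = "qc_textdup")
}

#' @export
print.qc_textdup <- function(x, ...) {
  cat(sprintf("Copied-text screen: %d/%d respondents flagged (%d matched pairs)\n",
              sum(x$flags), x$n, nrow(x$pairs)))
  invisible(x)
}

#' Crude screen for minimal-effort answers (optional heuristic)
#'
#' Flags answers with fewer than `min_words` tokens or consisting only of
#' entries from a short stop list ("good", "text", "nice", ...). This is a
#' deliberately simple length/stop-list heuristic, clearly not a substitute
#' for human judgment of whether an answer addresses the question, and it is
#' excluded from all headline quality metrics.
#'
#' @param texts data.frame with `text` column, or character vector.
#' @param min_words minimum token count, default 3.
#' @param stoplist lowercase tokens considered contentless.
#' @return Logical flags.
#' @export
flag_low_effort <- function(texts, min_words = 3L,
                            stoplist = c("good", "bad", "text", "nice", "ok",
                                         "okay", "yes", "no", "none", "na")) {
  if (is.data.frame(texts)) texts <- texts$text
  toks <- tokenize_text(texts)
  vapply(toks, function(t) {
    length(t) < min_words || all(t %in% stoplist)
  }, logical(1))
}
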