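#' Survey codebook: items, scales, batteries, item pairs, conditions
#'
#' The codebook declares everything the quality metrics need to know about the
#' instrument: which ordinal items exist and their response range, which items
#' form each multi-item scale (and which of those are reverse-worded), which
#' consecutive same-response-category batteries are subject to straight-lining
#' rules (and which single category, if any, is an allowed straight-line), the
#' repeated item pairs used for response-consistency kappa, and the names of
#' the condition-checklist columns including the embedded fake conditions.
#'
#' `default_codebook()` returns the instrument used throughout this package: a
#' PROMIS-style health profile with seven 4-item domain scales plus a 2-item
#' cognitive scale, a 6-item physical-function battery, two 3-item sleep sets
#' of mixed wording direction, five repeated consistency pairs, and a 24-entry
#' condition checklist containing the two fake conditions "syndomitis" and
#' "chekalism".
#'
#' @return A list of class `qc_codebook` with elements `items`, `range`,
#'   `scales`, `batteries`, `pairs`, `conditions`, `fake_conditions`.
#' @export
default_codebook <- function() {
  items <- c(
    paste0("pf", 1:6),                  # physical function (6-item battery)
    paste0("ft", 1:4),                  # fatigue
    paste0("pi", 1:4),                  # pain interference
    paste0("dp", 1:4),                  # depressive symptoms
    paste0("ax", 1:4),                  # anxiety
    paste0("ap", 1:4),                  # ability to participate
    paste0("sl", 1:6),                  # sleep: two 3-item mixed-wording sets
    paste0("cg", 1:2),                  # cognitive function
    paste0("pr", 1:5)                   # repeated items for consistency pairs
  )
  scales <- list(
    physical_function  = list(items = paste0("pf", 1:4), reverse = character()),
    fatigue            = list(items = paste0("ft", 1:4), reverse = character()),
    pain_interference  = list(items = paste0("pi", 1:4), reverse = character()),
    depressive_symptoms= list(items = paste0("dp", 1:4), reverse = character()),
    anxiety            = list(items = paste0("ax", 1:4), reverse = character()),
    ability_participate= list(items = paste0("ap", 1:4), reverse = character()),
    # 4-item sleep scale with one reverse-worded item, mirroring a sleep
    # disturbance scale whose items are asked in both directions
    sleep_disturbance  = list(items = c("sl1", "sl2", "sl3", "sl5"),
                              reverse = "sl1"),
    cognitive_function = list(items = paste0("cg", 1:2), reverse = character())
  )
  batteries <- list(
    physical_function6 = list(items = paste0("pf", 1:6), allowed = 5L,
                              reverse = character()),
    fatigue            = list(items = paste0("ft", 1:4), allowed = NA_integer_,
                              reverse = character()),
    pain_interference  = list(items = paste0("pi", 1:4), allowed = NA_integer_,
                              reverse = character()),
    depressive         = list(items = paste0("dp", 1:4), allowed = NA_integer_,
                              reverse = character()),
    anxiety            = list(items = paste0("ax", 1:4), allowed = NA_integer_,
                              reverse = character()),
    ability_participate= list(items = paste0("ap", 1:4), allowed = NA_integer_,
                              reverse = character()),
    sleep_set1         = list(items = paste0("sl", 1:3), allowed = 3L,
                              reverse = "sl1"),
    sleep_set2         = list(items = paste0("sl", 4:6), allowed = 3L,
                              reverse = "sl4")
  )
  pairs <- list(
    pain_interference = c("pi1", "pr1"),
    trouble_doing     = c("ft2", "pr2"),
    sleep_problems    = c("sl2", "pr3"),
    concentrate_focus = c("cg1", "pr4"),
    memory            = c("cg2", "pr5")
  )
  real_conditions <- c(
    "back_pain", "neck_pain", "anxiety_dx", "depression_dx", "hypertension",
    "asthma", "diabetes", "heart_attack", "chd", "angina", "copd", "cancer",
    "stroke", "arthritis", "migraine", "thyroid", "kidney_disease",
    "liver_disease", "osteoporosis", "ulcer", "allergies", "insomnia_dx"
  )
  cb <- list(
    items = items,
    range = c(1L, 5L),
    scales = scales,
    batteries = batteries,
    pairs = pairs,
    conditions = c(real_conditions, "syndomitis", "chekalism"),
    fake_conditions = c("syndomitis", "chekalism")
  )
  class(cb) <- "qc_codebook"
  cb
}

#' Read a codebook from a YAML file
#'
#' @param path YAML file with the same structure as [default_codebook()].
#' @return A `qc_codebook` list.
#' @export
read_codebook <- function(path) {
  raw <- yaml::read_yaml(path)
  stopifnot(!is.null(raw$items), !is.null(raw$range), !is.null(raw$scales))
  raw$range <- as.integer(raw$range)
  fix_chr <- function(x) if (is.null(x)) character() else as.character(x)
  raw$scales <- lapply(raw$scales, function(s) {
    list(items = as.character(s$items), reverse = fix_chr(s$reverse))
  })
  raw$batteries <- lapply(raw$batteries, function(b) {
    list(items = as.character(b$items),
         allowed = if (is.null(b$allowed)) NA_integer_ else as.integer(b$allowed),
         reverse = fix_chr(b$reverse))
  })
  raw$pairs <- lapply(raw$pairs, as.character)
  validate_codebook(raw)
  class(raw) <- "qc_codebook"
  raw
}

#' Write a codebook to YAML
#'
#' @param cb a `qc_codebook`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_codebook <- function(cb, path) {
  yaml::write_yaml(unclass(cb), path)
  invisible(path)
}

validate_codebook <- function(cb) {
  all_scale_items <- unlist(lapply(cb$scales, `[[`, "items"), use.names = FALSE)
  if (anyDuplicated(all_scale_items)) {
    stop("scale item sets must be disjoint", call. = FALSE)
  }
  known <- cb$items
  refd <- unique(c(all_scale_items,
                   unlist(lapply(cb$batteries, `[[`, "items"), use.names = FALSE),
                   unlist(cb$pairs, use.names = FALSE)))
  missing <- setdiff(refd, known)
  if (length(missing)) {
    stop("codebook references undeclared items: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  for (nm in names(cb$batteries)) {
    b <- cb$batteries[[nm]]
    if (length(b$items) < 2L) stop("battery ", nm, " needs >= 2 items")
    if (!is.na(b$allowed) &&
        (b$allowed < cb$range[1] || b$allowed > cb$range[2])) {
      stop("battery ", nm, " allowed category outside declared range")
    }
  }
  if (!all(lengths(cb$pairs) == 2L)) stop("item pairs must have 2 items each")
  if (!all(cb$fake_conditions %in% cb$conditions)) {
    stop("fake conditions must appear in the condition list")
  }
  invisible(TRUE)
}
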