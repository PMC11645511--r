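#' Persona configuration for the synthetic respondent cohort
#'
#' Builds and validates the generative configuration for [generate_cohort()].
#' Personas are mutually exclusive: each respondent is exactly one of
#' `attentive` (latent-trait ordinal responder), `straightliner` (constant
#' response within every battery), `speeder` (total duration below 1 s/item),
#' `misrepresenter` (endorses fake and real conditions at inflated rates), or
#' `copier` (shares a verbatim text run with at least one other copier).
#' Mixed behaviour is available only through explicit secondary toggles
#' (`misrep_straightline_prob`), off by default, so ground truth stays
#' unambiguous.
#'
#' Default values encode the convenience-panel conditions reported for a large
#' crowdworker survey: a 14.4% misrepresenter share, a 3.5% incomplete rate,
#' no speeders, and demographic selection bias toward younger, better-educated,
#' lower-income respondents.
#'
#' @param n number of respondents.
#' @param persona_mix named proportions over the five personas; must sum to 1.
#' @param fake_endorse_prob probability a misrepresenter endorses each of the
#'   two fake conditions.
#' @param overendorse_prob probability a misrepresenter endorses each real
#'   condition (free parameter; honest endorsement is trait-linked instead).
#' @param trait_corr correlation matrix over the 8 latent health traits
#'   (one per scale of the codebook); symmetric positive semi-definite.
#' @param loading item loading on its domain trait (drives inter-item
#'   correlation, hence alpha).
#' @param pair_rho latent correlation between a repeated pair item and its
#'   partner item (drives pairwise kappa).
#' @param demo_marginals per-variable category proportions in the target
#'   population; each variable must sum to 1.
#' @param demo_bias multiplicative selection weights distorting
#'   `demo_marginals` in the realized sample (1 = no bias).
#' @param trait_demo_effects named list `trait -> variable -> category shifts`
#'   added to the latent trait mean, linking traits to demographics.
#' @param condition_base honest base endorsement probability per real
#'   condition.
#' @param condition_trait_slope logit slope linking honest condition
#'   endorsement to the respondent's symptom burden.
#' @param miss_rate independent per-item missingness for attentive-like
#'   responders.
#' @param incomplete_rate share of respondents overlaid as incompletes
#'   (answering < half of their items); an explicit toggle, recorded in truth.
#' @param misrep_straightline_prob probability a misrepresenter additionally
#'   straight-lines the sleep sets (secondary flag, default off).
#' @param straightliner_values candidate constant categories for planted
#'   straight-liners; the default avoids both allowed categories (5 on the
#'   physical-function battery, 3 on the sleep sets) so every plant violates
#'   all three straight-lining rules.
#' @param duration_meanlog_per_item named per-persona meanlog of the lognormal
#'   seconds-per-item rate.
#' @param duration_sdlog_per_item named per-persona sdlog of the same.
#' @param copier_templates character vector of template sentences (each at
#'   least 10 words) copiers copy from.
#' @param vocab_size size of the synthetic vocabulary used for attentive
#'   word-salad answers.
#' @param codebook a [default_codebook()]-style codebook.
#' @param seed integer seed.
#' @return A validated list of class `persona_config`.
#' @export
persona_config <- function(n = 6750,
                           persona_mix = c(attentive = 0.816,
                                           straightliner = 0.02,
                                           speeder = 0,
                                           misrepresenter = 0.144,
                                           copier = 0.02),
                           fake_endorse_prob = 0.9,
                           overendorse_prob = 0.8,
                           trait_corr = default_trait_corr(),
                           loading = 0.85,
                           pair_rho = 0.9,
                           demo_marginals = default_demo_marginals(),
                           demo_bias = default_demo_bias(),
                           trait_demo_effects = default_trait_demo_effects(),
                           condition_base = default_condition_base(),
                           condition_trait_slope = 0.6,
                           miss_rate = 0.02,
                           incomplete_rate = 0.035,
                           misrep_straightline_prob = 0,
                           straightliner_values = c(1L, 2L, 4L),
                           duration_meanlog_per_item =
                             c(attentive = log(12), straightliner = log(4),
                               speeder = log(0.5), misrepresenter = log(9),
                               copier = log(12)),
                           duration_sdlog_per_item =
                             c(attentive = 0.4, straightliner = 0.3,
                               speeder = 0.25, misrepresenter = 0.4,
                               copier = 0.4),
                           copier_templates = default_copier_templates(),
                           vocab_size = 2500L,
                           codebook = default_codebook(),
                           seed = 1L) {
  personas <- c("attentive", "straightliner", "speeder", "misrepresenter",
                "copier")
  if (!setequal(names(persona_mix), personas)) {
    stop("persona_mix must be named over: ", paste(personas, collapse = ", "),
         call. = FALSE)
  }
  persona_mix <- persona_mix[personas]
  assert_proportions(persona_mix, "persona_mix")
  assert_psd(trait_corr, "trait_corr")
  if (!identical(rownames(trait_corr), names(codebook$scales))) {
    stop("trait_corr must be named by the codebook's scales", call. = FALSE)
  }
  for (v in names(demo_marginals)) {
    assert_proportions(demo_marginals[[v]], paste0("demo_marginals$", v))
  }
  for (v in names(demo_bias)) {
    if (!v %in% names(demo_marginals)) {
      stop("demo_bias names unknown variable: ", v, call. = FALSE)
    }
    unknown <- setdiff(names(demo_bias[[v]]), names(demo_marginals[[v]]))
    if (length(unknown)) {
      stop("demo_bias has unknown category in ", v, ": ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
  }
  stopifnot(n >= 0, fake_endorse_prob >= 0, fake_endorse_prob <= 1,
            overendorse_prob >= 0, overendorse_prob <= 1,
            loading > 0, loading < 1, pair_rho > 0, pair_rho <= 1,
            miss_rate >= 0, miss_rate < 1,
            incomplete_rate >= 0, incomplete_rate < 1,
            misrep_straightline_prob >= 0, misrep_straightline_prob <= 1)
  if (any(nchar(gsub("[^ ]", "", copier_templates)) < 9L)) {
    stop("copier templates must have at least 10 words", call. = FALSE)
  }
  cfg <- list(n = as.integer(n), persona_mix = persona_mix,
              fake_endorse_prob = fake_endorse_prob,
              overendorse_prob = overendorse_prob,
              trait_corr = trait_corr, loading = loading, pair_rho = pair_rho,
              demo_marginals = demo_marginals, demo_bias = demo_bias,
              trait_demo_effects = trait_demo_effects,
              condition_base = condition_base,
              condition_trait_slope = condition_trait_slope,
              miss_rate = miss_rate, incomplete_rate = incomplete_rate,
              misrep_straightline_prob = misrep_straightline_prob,
              straightliner_values = as.integer(straightliner_values),
              duration_meanlog_per_item = duration_meanlog_per_item,
              duration_sdlog_per_item = duration_sdlog_per_item,
              copier_templates = copier_templates,
              vocab_size = as.integer(vocab_size),
              codebook = codebook, seed = as.integer(seed))
  class(cfg) <- "persona_config"
  cfg
}

#' Read a persona configuration from YAML
#'
#' Scalar and vector fields are taken from the file; anything absent keeps the
#' [persona_config()] default. The codebook and trait correlation matrix are
#' not representable in the flat YAML and always come from the defaults (or
#' can be set afterwards).
#'
#' @param path YAML file.
#' @return A `persona_config`.
#' @export
read_persona_config <- function(path) {
  raw <- yaml::read_yaml(path)
  args <- list()
  for (nm in c("n", "fake_endorse_prob", "overendorse_prob", "loading",
               "pair_rho", "miss_rate", "incomplete_rate",
               "misrep_straightline_prob", "seed", "vocab_size",
               "condition_trait_slope")) {
    if (!is.null(raw[[nm]])) args[[nm]] <- raw[[nm]]
  }
  if (!is.null(raw$persona_mix)) args$persona_mix <- unlist(raw$persona_mix)
  if (!is.null(raw$demo_marginals)) {
    args$demo_marginals <- lapply(raw$demo_marginals, unlist)
  }
  if (!is.null(raw$demo_bias)) args$demo_bias <- lapply(raw$demo_bias, unlist)
  do.call(persona_config, args)
}

#' Default latent-trait correlation structure
#'
#' One general health factor: symptom traits load positively, functioning
#' traits negatively, giving the sign pattern seen in health-profile
#' correlation matrices. Rank-1 loadings plus a diagonal guarantee positive
#' semi-definiteness.
#'
#' @return An 8x8 correlation matrix named by scale.
#' @export
default_trait_corr <- function() {
  g <- c(physical_function = -0.60, fatigue = 0.65, pain_interference = 0.60,
         depressive_symptoms = 0.65, anxiety = 0.60,
         ability_participate = -0.60, sleep_disturbance = 0.55,
         cognitive_function = -0.50)
  m <- outer(g, g)
  diag(m) <- 1
  m
}

#' Default population marginals for the six weighting demographics
#'
#' Category proportions for US adults (age, gender, race/ethnicity, education,
#' income, census region) matching published national benchmark proportions;
#' each variable is normalized to sum exactly to 1. The combined 34.8%
#' bachelor-or-higher share is split 21.8 / 13.0 between bachelor's and
#' master's-or-higher.
#'
#' @return Named list of named proportion vectors.
#' @export
default_demo_marginals <- function() {
  norm1 <- function(x) x / sum(x)
  list(
    age = norm1(c(`18-29` = 0.199, `30-44` = 0.259, `45-60` = 0.240,
                  `60+` = 0.303)),
    gender = norm1(c(female = 0.507, male = 0.493)),
    race_ethnicity = norm1(c(hispanic = 0.172, multiracial = 0.014,
                             nh_black = 0.120, nh_white = 0.620,
                             nh_other = 0.073)),
    education = norm1(c(no_hs = 0.096, hs_grad = 0.292, some_college = 0.264,
                        bachelor = 0.218, masters_plus = 0.130)),
    income = norm1(c(lt_10k = 0.036, `10k_50k` = 0.249, `50k_100k` = 0.286,
                     ge_100k = 0.429)),
    region = norm1(c(northeast = 0.174, midwest = 0.206, south = 0.383,
                     west = 0.237))
  )
}

#' Default convenience-panel selection bias
#'
#' Multiplicative selection weights reproducing the characteristic skew of a
#' crowdworker sample relative to national marginals: younger, more male, far
#' better educated (bachelor's over-represented, no-high-school nearly
#' absent), and lower income. Values are the ratio of the observed
#' convenience-sample share to the national share for each category,
#' anchored on the fake-excluded sample (the subset the poststratification
#' weighting operates on).
#'
#' @return Named list of named multiplier vectors.
#' @export
default_demo_bias <- function() {
  list(
    age = c(`18-29` = 0.98, `30-44` = 1.95, `45-60` = 0.87, `60+` = 0.27),
    gender = c(female = 0.89, male = 1.07),
    race_ethnicity = c(hispanic = 0.82, multiracial = 1.50, nh_black = 0.69,
                       nh_white = 1.11, nh_other = 0.78),
    education = c(no_hs = 0.032, hs_grad = 0.27, some_college = 0.91,
                  bachelor = 2.23, masters_plus = 1.36),
    income = c(lt_10k = 1.20, `10k_50k` = 1.70, `50k_100k` = 1.39,
               ge_100k = 0.29),
    region = c(northeast = 1.01, midwest = 0.95, south = 1.03, west = 0.94)
  )
}

#' Default links between demographics and latent traits
#'
#' Older age lowers physical function; lower income raises depressive
#' symptoms. These links give the raking-recovery tests a trait whose
#' population mean is computable from the generator's own marginals.
#'
#' @return Nested named list `trait -> variable -> category shifts`.
#' @export
default_trait_demo_effects <- function() {
  list(
    physical_function = list(
      age = c(`18-29` = 0.35, `30-44` = 0.15, `45-60` = -0.15, `60+` = -0.50)),
    depressive_symptoms = list(
      income = c(lt_10k = 0.30, `10k_50k` = 0.10, `50k_100k` = -0.05,
                 ge_100k = -0.25))
  )
}

#' Default honest base prevalence for the 22 real conditions
#'
#' @return Named probability vector over the codebook's real conditions.
#' @export
default_condition_base <- function() {
  c(back_pain = 0.40, neck_pain = 0.20, anxiety_dx = 0.20,
    depression_dx = 0.20, hypertension = 0.38, asthma = 0.13,
    diabetes = 0.13, heart_attack = 0.04, chd = 0.04, angina = 0.03,
    copd = 0.05, cancer = 0.10, stroke = 0.03, arthritis = 0.22,
    migraine = 0.15, thyroid = 0.10, kidney_disease = 0.04,
    liver_disease = 0.02, osteoporosis = 0.06, ulcer = 0.05,
    allergies = 0.30, insomnia_dx = 0.12)
}

#' Template sentences shared by copy-paste responders
#' @return Character vector of sentences with at least 10 words each.
#' @export
default_copier_templates <- function() {
  c(paste("chronic pain means my back hurts every single day and it never",
          "really goes away completely"),
    paste("to me chronic pain is constant discomfort that lasts for months",
          "and interferes with my normal daily life"),
    paste("pain that does not stop even after treatment and keeps me from",
          "doing the things i used to enjoy"))
}

# equal-spaced thresholds on a standard-normal latent mapped to 1..5
discretize_latent <- function(y, n_cat = 5L) {
  th <- seq(-1.5, 1.5, length.out = n_cat - 1L)
  findInterval(y, th) + 1L
}

# domain trait of each codebook item (pair items inherit their partner's)
item_domains <- function(cb) {
  dom <- setNames(rep(NA_character_, length(cb$items)), cb$items)
  for (sc in names(cb$scales)) dom[cb$scales[[sc]]$items] <- sc
  dom[paste0("pf", 5:6)] <- "physical_function"
  dom[paste0("sl", 1:6)] <- "sleep_disturbance"
  dom
}

# items answered in the reverse direction by a consistent responder
reverse_worded_items <- function(cb) {
  unique(unlist(lapply(cb$batteries, `[[`, "reverse"), use.names = FALSE))
}

#' Generate a demographics table under biased selection
#'
#' Each variable is sampled independently with realized category probability
#' proportional to `marginal * bias`, renormalized — the realized share of a
#' category with marginal p and a bias factor b (others 1) is bp / (1 - p + bp).
#'
#' @param marginals named list of per-variable category proportions.
#' @param bias named list of multiplicative selection weights; categories
#'   absent from `bias` default to 1. Unknown categories are an error.
#' @param n number of respondents.
#' @param seed integer seed.
#' @return A data.frame of factors, one column per variable, `n` rows.
#' @export
generate_demographics <- function(marginals, bias = list(), n, seed = 1L) {
  set.seed(seed)
  out <- list()
  for (v in names(marginals)) {
    m <- marginals[[v]]
    b <- rep(1, length(m))
    names(b) <- names(m)
    if (!is.null(bias[[v]])) {
      unknown <- setdiff(names(bias[[v]]), names(m))
      if (length(unknown)) {
        stop("unknown category in bias for ", v, ": ",
             paste(unknown, collapse = ", "), call. = FALSE)
      }
      b[names(bias[[v]])] <- bias[[v]]
    }
    p <- m * b
    p <- p / sum(p)
    out[[v]] <- factor(
      if (n > 0) sample(names(m), n, replace = TRUE, prob = p) else character(),
      levels = names(m))
  }
  as.data.frame(out, optional = TRUE)
}

#' Generate a synthetic respondent cohort with known ground truth
#'
#' Produces every table the downstream pipeline consumes: the ordinal response
#' matrix (1-5, missing as `NA`), demographics, per-respondent durations with
#' items assigned, condition endorsements (0/1, including the two fake
#' conditions), open-text answers, and a truth table holding the persona
#' label, latent traits, and true condition status of every respondent.
#'
#' Attentive respondents answer through a latent-trait ordinal model: each
#' item's latent value is `loading * trait + noise`, cut at equal-spaced
#' thresholds into categories 1-5, with reverse-worded items answered in the
#' opposite direction. Straight-liners emit one constant category everywhere.
#' Speeders answer uniformly at random in under one second per item.
#' Misrepresenters endorse each fake condition with `fake_endorse_prob` and
#' each real condition with `overendorse_prob`. Copiers share a verbatim
#' template sentence (at least 10 words, at least 75% of their answer) with at
#' least one other copier whenever two or more copiers are generated.
#'
#' @param config a [persona_config()].
#' @return A list of class `synthetic_cohort` with elements `responses`,
#'   `demographics`, `durations`, `endorsements`, `texts`, `truth`, `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "persona_config"))
  set.seed(config$seed)
  cb <- config$codebook
  n <- config$n
  items <- cb$items
  n_items <- length(items)
  id <- sprintf("r%05d", seq_len(n))
  personas <- names(config$persona_mix)

  if (n == 0L) {
    empty <- data.frame(respondent_id = character())
    return(structure(list(
      responses = cbind(empty, as.data.frame(
        setNames(rep(list(integer()), n_items), items))),
      demographics = cbind(empty, generate_demographics(
        config$demo_marginals, config$demo_bias, 0L, config$seed)),
      durations = data.frame(respondent_id = character(), duration_s = numeric(),
                             items_assigned = integer()),
      endorsements = cbind(empty, as.data.frame(
        setNames(rep(list(integer()), length(cb$conditions)), cb$conditions))),
      texts = data.frame(respondent_id = character(), text = character()),
      truth = data.frame(respondent_id = character(), persona = character(),
                         incomplete = logical()),
      config = config), class = "synthetic_cohort"))
  }

  persona <- sample(personas, n, replace = TRUE, prob = config$persona_mix)

  demographics <- generate_demographics(config$demo_marginals,
                                        config$demo_bias, n,
                                        seed = sample.int(2^31 - 2, 1))

  ## latent traits: demographic shift + correlated noise
  traits <- matrix(stats::rnorm(n * nrow(config$trait_corr)), n) %*%
    chol(config$trait_corr)
  colnames(traits) <- rownames(config$trait_corr)
  for (tr in names(config$trait_demo_effects)) {
    for (v in names(config$trait_demo_effects[[tr]])) {
      eff <- config$trait_demo_effects[[tr]][[v]]
      traits[, tr] <- traits[, tr] +
        eff[as.character(demographics[[v]])]
    }
  }

  ## ordinal responses
  dom <- item_domains(cb)
  rev_items <- reverse_worded_items(cb)
  lam <- config$loading
  latent <- matrix(NA_real_, n, n_items, dimnames = list(NULL, items))
  resp <- matrix(NA_integer_, n, n_items, dimnames = list(NULL, items))
  for (j in seq_len(n_items)) {
    it <- items[j]
    if (grepl("^pr", it)) next  # paired items filled from partners below
    latent[, j] <- lam * traits[, dom[it]] +
      sqrt(1 - lam^2) * stats::rnorm(n)
    cat_j <- discretize_latent(latent[, j])
    resp[, j] <- if (it %in% rev_items) 6L - cat_j else cat_j
  }
  rho <- config$pair_rho
  for (k in seq_along(cb$pairs)) {
    pr_it <- cb$pairs[[k]][2]
    partner <- cb$pairs[[k]][1]
    latent[, pr_it] <- rho * latent[, partner] +
      sqrt(1 - rho^2) * stats::rnorm(n)
    resp[, pr_it] <- discretize_latent(latent[, pr_it])
  }

  ## attentive-like missingness
  if (config$miss_rate > 0) {
    attn_like <- persona %in% c("attentive", "misrepresenter", "copier")
    drop <- matrix(stats::runif(n * n_items) < config$miss_rate, n)
    drop[!attn_like, ] <- FALSE
    resp[drop] <- NA_integer_
  }

  ## persona overrides
  sl_idx <- which(persona == "straightliner")
  if (length(sl_idx)) {
    v <- sample(config$straightliner_values, length(sl_idx), replace = TRUE)
    resp[sl_idx, ] <- matrix(rep(v, n_items), length(sl_idx))
  }
  sp_idx <- which(persona == "speeder")
  if (length(sp_idx)) {
    resp[sp_idx, ] <- sample(seq(cb$range[1], cb$range[2]),
                             length(sp_idx) * n_items, replace = TRUE)
  }
  mr_idx <- which(persona == "misrepresenter")
  if (length(mr_idx) && config$misrep_straightline_prob > 0) {
    hit <- mr_idx[stats::runif(length(mr_idx)) < config$misrep_straightline_prob]
    sleep_items <- unique(c(cb$batteries$sleep_set1$items,
                            cb$batteries$sleep_set2$items))
    sleep_items <- intersect(sleep_items, items)
    if (length(hit) && length(sleep_items)) {
      vals <- setdiff(seq(cb$range[1], cb$range[2]),
                      stats::na.omit(c(cb$batteries$sleep_set1$allowed,
                                       cb$batteries$sleep_set2$allowed)))
      v <- sample(vals, length(hit), replace = TRUE)
      resp[hit, sleep_items] <- matrix(rep(v, length(sleep_items)),
                                       length(hit))
    }
  }

  ## incompleteness overlay (explicit toggle, recorded in truth)
  incomplete <- rep(FALSE, n)
  if (config$incomplete_rate > 0) {
    n_inc <- stats::rbinom(1L, n, config$incomplete_rate)
    if (n_inc > 0) {
      inc_idx <- sample.int(n, n_inc)
      incomplete[inc_idx] <- TRUE
      for (i in inc_idx) {
        keep_n <- floor(stats::runif(1, 0.05, 0.45) * n_items)
        blank <- sample.int(n_items, n_items - keep_n)
        resp[i, blank] <- NA_integer_
      }
    }
  }

  ## condition endorsements: truth from the honest trait-linked model
  burden <- rowMeans(traits[, c("fatigue", "pain_interference",
                                "depressive_symptoms", "anxiety",
                                "sleep_disturbance"), drop = FALSE])
  real_conds <- setdiff(cb$conditions, cb$fake_conditions)
  base <- config$condition_base[real_conds]
  if (anyNA(base)) stop("condition_base must cover all real conditions")
  p_true <- stats::plogis(
    outer(config$condition_trait_slope * burden, stats::qlogis(base), "+"))
  true_cond <- matrix(stats::rbinom(n * length(real_conds), 1L, p_true),
                      n, dimnames = list(NULL, real_conds))
  endors <- true_cond
  if (length(mr_idx)) {
    endors[mr_idx, ] <- stats::rbinom(length(mr_idx) * length(real_conds), 1L,
                                      config$overendorse_prob)
  }
  fake <- matrix(0L, n, length(cb$fake_conditions),
                 dimnames = list(NULL, cb$fake_conditions))
  if (length(mr_idx)) {
    fake[mr_idx, ] <- stats::rbinom(
      length(mr_idx) * length(cb$fake_conditions), 1L,
      config$fake_endorse_prob)
  }
  endors <- cbind(endors, fake)[, cb$conditions, drop = FALSE]

  ## durations (seconds): lognormal per-item rate by persona
  rate <- stats::rlnorm(n,
                        config$duration_meanlog_per_item[persona],
                        config$duration_sdlog_per_item[persona])
  # speeders must sit strictly below the 1 s/item screening boundary
  rate[sp_idx] <- pmin(rate[sp_idx], 0.98)
  durations <- data.frame(respondent_id = id,
                          duration_s = rate * n_items,
                          items_assigned = n_items)

  ## open text
  vocab <- sprintf("word%04d", seq_len(config$vocab_size))
  text <- character(n)
  for (i in seq_len(n)) {
    len <- sample(12:30, 1L)
    text[i] <- paste(sample(vocab, len), collapse = " ")
  }
  cp_idx <- which(persona == "copier")
  if (length(cp_idx)) {
    # pair copiers so every template in use has at least two users
    grp <- rep(seq_len(max(1L, floor(length(cp_idx) / 2))), each = 2L,
               length.out = length(cp_idx))
    tpl <- config$copier_templates[
      (grp - 1L) %% length(config$copier_templates) + 1L]
    extra_n <- sample(0:2, length(cp_idx), replace = TRUE)
    for (k in seq_along(cp_idx)) {
      extra <- if (extra_n[k] > 0) {
        paste(sample(vocab, extra_n[k]), collapse = " ")
      } else ""
      text[cp_idx[k]] <- trimws(paste(tpl[k], extra))
    }
  }

  truth <- data.frame(respondent_id = id, persona = persona,
                      incomplete = incomplete)
  truth <- cbind(truth,
                 as.data.frame(traits)[
                   , paste0("", colnames(traits)), drop = FALSE])
  names(truth)[-(1:3)] <- paste0("trait_", colnames(traits))
  truth$true_n_conditions <- rowSums(true_cond)

  structure(list(
    responses = cbind(data.frame(respondent_id = id),
                      as.data.frame(resp)),
    demographics = cbind(data.frame(respondent_id = id), demographics),
    durations = durations,
    endorsements = cbind(data.frame(respondent_id = id),
                         as.data.frame(endors)),
    texts = data.frame(respondent_id = id, text = text),
    truth = truth,
    config = config), class = "synthetic_cohort")
}

#' Write a cohort's tables to CSV files
#'
#' Missing ordinal responses are written as empty cells; endorsements as 0/1.
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if needed).
#' @return Named vector of file paths, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- c(responses = "responses.csv", demographics = "demographics.csv",
             durations = "durations.csv", endorsements = "endorsements.csv",
             texts = "texts.csv", truth = "truth.csv")
  for (nm in names(files)) {
    utils::write.csv(cohort[[nm]], file.path(dir, files[nm]),
                     row.names = FALSE, na = "")
  }
  invisible(setNames(file.path(dir, files), names(files)))
}
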