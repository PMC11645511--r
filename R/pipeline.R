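#' Configuration for the two-panel quality-comparison pipeline
#'
#' Assembles everything [run_pipeline()] needs: a persona configuration for
#' the convenience-panel cohort and one for the probability-panel cohort,
#' surveys-fielded counts for completion rates, raking targets, demographic
#' benchmarks, and stage toggles. Defaults emulate the study conditions of a
#' large two-panel comparison: a convenience cohort of 6997 respondents at
#' field close (13,608 surveys fielded, 14.4% misrepresenters, 3.5%
#' incompletes, strong selection bias, education linked to health contrary to
#' theory) and a probability cohort of 4149 respondents (7224 assigned, 0.5%
#' misrepresenters, 0.4% incompletes, mild selection bias).
#'
#' @param seed base integer seed; fanned out to named per-stage substreams so
#'   toggling one stage never shifts another stage's randomness.
#' @param n_convenience,n_probability cohort sizes at field close.
#' @param fielded_convenience,fielded_probability surveys fielded/assigned.
#' @param convenience,probability optional `persona_config` overrides.
#' @param targets raking targets; default the generator's population
#'   marginals.
#' @param max_weight_convenience,max_weight_probability trim caps.
#' @param stages character subset of
#'   `c("screen", "metrics", "textdup", "weight", "compare")`.
#' @param outdir output directory, or `NULL` to skip writing files.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L,
                            n_convenience = 6997L,
                            n_probability = 4149L,
                            fielded_convenience = 13608L,
                            fielded_probability = 7224L,
                            convenience = NULL,
                            probability = NULL,
                            targets = default_demo_marginals(),
                            max_weight_convenience = 30,
                            max_weight_probability = 5,
                            stages = c("screen", "metrics", "textdup",
                                       "weight", "compare"),
                            outdir = NULL) {
  eff_conv <- default_trait_demo_effects()
  # education linked to health contrary to theory in the convenience cohort
  eff_conv$physical_function$education <-
    c(no_hs = 0.20, hs_grad = 0.10, some_college = 0, bachelor = -0.20,
      masters_plus = -0.30)
  eff_prob <- default_trait_demo_effects()
  eff_prob$physical_function$education <-
    c(no_hs = -0.25, hs_grad = -0.10, some_college = 0, bachelor = 0.15,
      masters_plus = 0.25)

  convenience <- convenience %||% persona_config(
    n = n_convenience,
    persona_mix = c(attentive = 0.816, straightliner = 0.02, speeder = 0,
                    misrepresenter = 0.144, copier = 0.02),
    incomplete_rate = 0.035,
    misrep_straightline_prob = 0.3,
    trait_demo_effects = eff_conv,
    seed = substream_seed(seed, "simulate_convenience"))
  probability <- probability %||% persona_config(
    n = n_probability,
    persona_mix = c(attentive = 0.985, straightliner = 0.01, speeder = 0,
                    misrepresenter = 0.005, copier = 0),
    incomplete_rate = 0.004,
    misrep_straightline_prob = 0.3,
    demo_bias = list(
      age = c(`18-29` = 0.68, `30-44` = 0.89, `45-60` = 0.92, `60+` = 1.36),
      education = c(no_hs = 0.70, hs_grad = 0.91, some_college = 1.00,
                    bachelor = 1.00, masters_plus = 1.42),
      income = c(lt_10k = 0.81, `10k_50k` = 0.98, `50k_100k` = 1.06,
                 ge_100k = 0.99)),
    trait_demo_effects = eff_prob,
    seed = substream_seed(seed, "simulate_probability"))

  structure(list(seed = as.integer(seed),
                 fielded = c(convenience = fielded_convenience,
                             probability = fielded_probability),
                 convenience = convenience, probability = probability,
                 targets = targets,
                 max_weight = c(convenience = max_weight_convenience,
                                probability = max_weight_probability),
                 stages = stages, outdir = outdir),
            class = "pipeline_config")
}

# scale scores: mean of (reverse-recoded) scale items, listwise within scale
scale_scores <- function(responses, codebook) {
  out <- list()
  for (sc in names(codebook$scales)) {
    def <- codebook$scales[[sc]]
    m <- battery_matrix(responses, def$items)
    storage.mode(m) <- "double"
    for (it in def$reverse) {
      m[, it] <- codebook$range[1] + codebook$range[2] - m[, it]
    }
    out[[sc]] <- rowMeans(m)
  }
  as.data.frame(out)
}

demo_numeric <- function(demographics) {
  data.frame(
    age = c(`18-29` = 23.5, `30-44` = 37, `45-60` = 52.5,
            `60+` = 67)[as.character(demographics$age)],
    education = as.numeric(factor(
      demographics$education,
      levels = c("no_hs", "hs_grad", "some_college", "bachelor",
                 "masters_plus"))),
    income = as.numeric(factor(
      demographics$income,
      levels = c("lt_10k", "10k_50k", "50k_100k", "ge_100k"))))
}

flatten_margins <- function(demographics, weights = NULL) {
  weights <- weights %||% rep(1, nrow(demographics))
  out <- c()
  for (v in names(demographics)) {
    x <- demographics[[v]]
    lv <- if (is.factor(x)) levels(x) else sort(unique(as.character(x)))
    m <- weighted_margin(as.character(x), weights, lv)
    names(m) <- paste(v, lv, sep = ".")
    out <- c(out, m)
  }
  out
}

panel_metrics <- function(analytic, durations, codebook) {
  keep <- durations$respondent_id %in% analytic$respondent_id
  list(careless = careless_metrics(analytic, durations[keep, , drop = FALSE],
                                   codebook),
       alphas = scale_alphas(analytic, codebook))
}

#' Run the full two-panel quality-assessment pipeline
#'
#' Simulates the convenience and probability cohorts, builds the analytic
#' datasets (speed and completeness screens, fake-condition flags,
#' accounting), computes the careless-response and reliability metric bundle
#' on the full and fake-excluded subsets of each cohort with cross-sample
#' reliability tests, screens open text for copied responses, rakes each
#' cohort to the population targets, and compares point estimates against
#' benchmarks and correlation matrices across cohorts. Every artifact
#' carries the seed and a configuration fingerprint.
#'
#' @param config a [pipeline_config()].
#' @return A nested list of class `quality_report`; when `config$outdir` is
#'   set, JSON/CSV artifacts are written there as a side effect.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  report <- list(provenance = list(
    seed = config$seed,
    config_hash = config_fingerprint(config),
    package_version = as.character(utils::packageVersion("panelqc"))))

  cohorts <- list(convenience = generate_cohort(config$convenience),
                  probability = generate_cohort(config$probability))

  panels <- list()
  for (nm in names(cohorts)) {
    co <- cohorts[[nm]]
    cb <- co$config$codebook
    panel <- list(cohort = co)

    if ("screen" %in% config$stages) {
      scr <- build_analytic(co$responses, co$durations, co$endorsements,
                            range = cb$range, fake_ids = cb$fake_conditions,
                            n_fielded = unname(config$fielded[nm]))
      panel$screen <- scr
      analytic_ids <- scr$analytic$respondent_id
      nofake_ids <- scr$flags$respondent_id[
        scr$flags$in_analytic & !scr$flags$fake_endorser]
      panel$subsets <- list(all = analytic_ids, no_fake = nofake_ids)

      if ("metrics" %in% config$stages) {
        sub <- function(df, ids) df[df$respondent_id %in% ids, , drop = FALSE]
        panel$metrics <- list(
          all = panel_metrics(scr$analytic, co$durations, cb),
          no_fake = panel_metrics(sub(scr$analytic, nofake_ids),
                                  co$durations, cb))
      }
      if ("textdup" %in% config$stages) {
        panel$textdup <- find_copied(sub_df <- co$texts[
          co$texts$respondent_id %in% nofake_ids, , drop = FALSE])
      }
      if ("weight" %in% config$stages) {
        dem_nf <- co$demographics[
          co$demographics$respondent_id %in% nofake_ids, , drop = FALSE]
        panel$weights <- rake(dem_nf, config$targets,
                              max_weight = unname(config$max_weight[nm]))
        panel$weighted_margins <- flatten_margins(
          dem_nf[names(config$targets)], panel$weights$weights)
      }
    }
    panels[[nm]] <- panel
  }
  report$panels <- lapply(panels, function(p) p[setdiff(names(p), "cohort")])

  if (all(c("screen", "metrics") %in% config$stages)) {
    cb <- cohorts$convenience$config$codebook
    report$alpha_tests <- lapply(names(cb$scales), function(sc) {
      a1 <- panels$convenience$metrics$no_fake$alphas[[sc]]
      a2 <- panels$probability$metrics$no_fake$alphas[[sc]]
      c(list(scale = sc, alpha_convenience = a1$alpha,
             alpha_probability = a2$alpha),
        unclass(compare_alphas(a1$alpha, a1$n, a1$k, a2$alpha, a2$n, a2$k)))
    })
  }

  if (all(c("screen", "compare") %in% config$stages)) {
    cb <- cohorts$convenience$config$codebook
    sub <- function(df, ids) df[df$respondent_id %in% ids, , drop = FALSE]
    frames <- lapply(names(panels), function(nm) {
      ids <- panels[[nm]]$subsets$no_fake
      co <- cohorts[[nm]]
      cbind(scale_scores(sub(co$responses, ids), cb),
            demo_numeric(sub(co$demographics, ids)))
    })
    names(frames) <- names(panels)
    # T-standardization against the probability cohort as synthetic reference
    ref <- frames$probability
    tsc <- lapply(frames, function(f) {
      out <- f
      for (v in names(cb$scales)) {
        out[[v]] <- tscore_standardize(f[[v]], ref[[v]])
      }
      out
    })
    cm <- lapply(tsc, correlation_matrix)
    report$correlations <- list(
      convenience = cm$convenience, probability = cm$probability,
      comparison = compare_correlation_matrices(cm$convenience,
                                                cm$probability))
    tmeans <- lapply(tsc, function(f) {
      colMeans(as.matrix(f[names(cb$scales)]), na.rm = TRUE)
    })
    report$tscore_flags <- mapply(
      effect_flag, tmeans$convenience, tmeans$probability)

    if ("weight" %in% config$stages) {
      bench <- flatten_margins_targets(config$targets)
      demos <- lapply(names(panels), function(nm) {
        co <- cohorts[[nm]]
        all_ids <- panels[[nm]]$subsets$all
        nf_ids <- panels[[nm]]$subsets$no_fake
        dem <- co$demographics[names(config$targets)]
        keep_all <- co$demographics$respondent_id %in% all_ids
        keep_nf <- co$demographics$respondent_id %in% nf_ids
        benchmark_table(
          flatten_margins(dem[keep_all, , drop = FALSE]),
          flatten_margins(dem[keep_nf, , drop = FALSE]),
          flatten_margins(dem[keep_nf, , drop = FALSE],
                          panels[[nm]]$weights$weights),
          bench)
      })
      names(demos) <- names(panels)
      report$benchmark <- demos
    }
  }

  class(report) <- "quality_report"
  if (!is.null(config$outdir)) write_report(report, config$outdir)
  report
}

flatten_margins_targets <- function(targets) {
  out <- c()
  for (v in names(targets)) {
    m <- targets[[v]]
    names(m) <- paste(v, names(m), sep = ".")
    out <- c(out, m)
  }
  out
}

# order-insensitive numeric fingerprint of a configuration
config_fingerprint <- function(config) {
  txt <- paste(deparse(config[setdiff(names(config), "outdir")]),
               collapse = "")
  h <- 0
  for (cp in utf8ToInt(txt)) h <- (h * 31 + cp) %% 2147483647
  sprintf("%08x", h)
}

as_plain <- function(x) {
  if (inherits(x, "qc_cormat")) {
    return(list(method = x$method, r = apply(x$r, 1L, as.list)))
  }
  if (is.data.frame(x)) return(x)
  if (is.list(x)) return(lapply(unclass(x), as_plain))
  x
}

#' Write a quality report bundle to disk
#'
#' @param report a `quality_report` from [run_pipeline()].
#' @param outdir output directory.
#' @return `outdir`, invisibly.
#' @export
write_report <- function(report, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  light <- report
  # row-level tables go to CSV (or stay in memory); JSON carries summaries
  for (nm in names(light$panels)) {
    p <- light$panels[[nm]]
    if (!is.null(p$screen)) {
      utils::write.csv(p$screen$flags,
                       file.path(outdir, paste0("qc_flags_", nm, ".csv")),
                       row.names = FALSE)
      p$screen <- list(accounting = p$screen$accounting)
    }
    if (!is.null(p$weights)) {
      utils::write.csv(
        data.frame(respondent_id = p$subsets$no_fake,
                   weight = p$weights$weights),
        file.path(outdir, paste0("weights_", nm, ".csv")), row.names = FALSE)
      p$weights <- p$weights[setdiff(names(unclass(p$weights)), "weights")]
    }
    if (!is.null(p$textdup)) {
      p$textdup <- list(n_flagged = sum(p$textdup$flags), n = p$textdup$n,
                        n_pairs = nrow(p$textdup$pairs))
    }
    p$subsets <- lapply(p$subsets, length)
    light$panels[[nm]] <- p
  }
  keep <- setdiff(names(light), c("correlations", "benchmark"))
  write_json_report(as_plain(light[keep]),
                    file.path(outdir, "quality_report.json"))
  if (!is.null(report$correlations)) {
    utils::write.csv(report$correlations$convenience$r,
                     file.path(outdir, "correlations_convenience.csv"))
    utils::write.csv(report$correlations$probability$r,
                     file.path(outdir, "correlations_probability.csv"))
    write_json_report(as_plain(unclass(report$correlations$comparison)),
                      file.path(outdir, "correlation_comparison.json"))
  }
  if (!is.null(report$benchmark)) {
    for (nm in names(report$benchmark)) {
      utils::write.csv(report$benchmark[[nm]],
                       file.path(outdir, paste0("benchmark_", nm, ".csv")),
                       row.names = FALSE)
    }
  }
  invisible(outdir)
}
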