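#!/usr/bin/env Rscript
# Stage 3: careless-response and reliability metrics.
#
# For each panel, computes the data-quality bundle on the full analytic set
# and on the fake-excluded subset: weighted kappa on the five repeated item
# pairs, the three straight-lining rules, mean root of pairs on the sleep
# sets, Cronbach alpha per scale with cross-panel reliability tests, the
# complete-all-items share, Winsorized response burden, and the copied-text
# screen. Results go to results/metrics.json.

library(panelqc)

seed <- 314
report <- run_pipeline(pipeline_config(
  seed = seed, stages = c("screen", "metrics", "textdup")))

fmt_pct <- function(x) sprintf("%.1f%%", x)
for (nm in names(report$panels)) {
  p <- report$panels[[nm]]
  cat("\n==", nm, "panel (analytic n =",
      p$screen$accounting$n_analytic, ") ==\n")
  for (sub in c("all", "no_fake")) {
    m <- p$metrics[[sub]]$careless
    cat(sprintf("  [%s] straight-lining: all sets %s | physical set %s | sleep sets %s\n",
                sub, fmt_pct(m$straightlining$all_sets$pct),
                fmt_pct(m$straightlining$physical_function6$pct),
                fmt_pct(m$straightlining$sleep_sets$pct)))
    cat(sprintf("  [%s] complete all items %s; burden %.0f (SD %.0f) min\n",
                sub, fmt_pct(m$complete_all_items$pct),
                m$burden$mean, m$burden$sd))
  }
  kap <- p$metrics$no_fake$careless$kappa
  cat("  kappa (no fake):",
      paste(sprintf("%s %.2f (%s)", names(kap),
                    vapply(kap, `[[`, 0, "kappa"),
                    vapply(kap, `[[`, "", "interpretation")),
            collapse = "; "), "\n")
  cat(sprintf("  copied text: %d/%d flagged\n",
              sum(p$textdup$flags), p$textdup$n))
}

cat("\nCross-panel reliability tests (no-fake subsets):\n")
for (tst in report$alpha_tests) {
  cat(sprintf("  %-20s alpha %0.3f vs %0.3f  z = %6.2f  p = %.3g\n",
              tst$scale, tst$alpha_convenience, tst$alpha_probability,
              tst$statistic, tst$p_value))
}

slim <- lapply(report$panels, function(p) {
  list(metrics = p$metrics,
       textdup = list(n_flagged = sum(p$textdup$flags), n = p$textdup$n))
})
write_json_report(c(report$provenance, slim,
                    list(alpha_tests = report$alpha_tests)),
                  "results/metrics.json")
cat("\nMetric bundle written to results/metrics.json\n")
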