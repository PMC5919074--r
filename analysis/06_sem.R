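#!/usr/bin/env Rscript
# Stage 6: what drives immune state?
#
# Fits the three latent-variable structural equation models (adaptive
# cellular, innate cellular, humoral immune state driven by Season, Age,
# Condition and Infection) separately for each sex, reports standardized
# estimates and fit indices, and applies the fit-acceptance rules.

suppressPackageStartupMessages(library(ecoimmune))
cohort <- read_cohort("results/cohort_condition.csv", "canonical")
cohort <- compute_smi(cohort)          # smi column is not canonical
cohort$burden <- infection_descriptives(cohort)$burden

models <- default_models()
rows <- list(); est_rows <- list()
for (mn in names(models)) {
  for (sx in c("female", "male")) {
    dat <- cohort[cohort$sex == sx, ]
    fit <- fit_ml(models[[mn]], dat, seed = 1)
    acc <- acceptance_report(fit)
    key <- paste(mn, sx, sep = "_")
    rows[[key]] <- data.frame(
      model = mn, sex = sx, n = fit$n, chi2 = fit$chi2, df = fit$df,
      p = fit$chi2_p, rmsea = fit$rmsea, rmsea_lo = fit$rmsea_ci[1],
      rmsea_hi = fit$rmsea_ci[2], cfi = fit$cfi, srmr = fit$srmr,
      verdict = acc$verdict)
    est_rows[[key]] <- cbind(model = mn, sex = sx, fit$estimates)
    cat(sprintf(
      "%-8s %-6s n=%3d chi2=%6.2f df=%2d p=%.3f RMSEA=%.3f (%.3f-%.3f) CFI=%.3f SRMR=%.3f -> %s\n",
      mn, sx, fit$n, fit$chi2, fit$df, fit$chi2_p, fit$rmsea,
      fit$rmsea_ci[1], fit$rmsea_ci[2], fit$cfi, fit$srmr, acc$verdict))
  }
}
write.csv(do.call(rbind, rows), "results/sem_fit_indices.csv",
          row.names = FALSE)
write.csv(do.call(rbind, est_rows), "results/sem_estimates.csv",
          row.names = FALSE)

adapt <- do.call(rbind, est_rows)
paths <- adapt[adapt$type == "path" & adapt$to == "ImmuneState", ]
cat("\nstandardized paths into ImmuneState (by model/sex):\n")
print(paths[c("model", "sex", "from", "std", "p")], row.names = FALSE)
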