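#!/usr/bin/env Rscript

# Step 2 -- fit the population model.
#
# Laplacian estimation with the M3 censored-data likelihood, starting from
# the published final estimates (the same values the model file declares as
# initial estimates). Writes the estimates, empirical Bayes etas and a run
# log under results/.

library(arsdhapk)

ds <- read_dataset("results/dataset.csv")
start <- final_model()

t0 <- Sys.time()
f <- fit(ds, start, spec = likelihood_spec("M3", "laplacian"))
elapsed <- as.numeric(Sys.time() - t0, units = "secs")

est <- fit_coef(f)
jsonlite::write_json(
  list(estimates = as.list(est), ofv = f$ofv, ofv_nonmem = f$ofv_nonmem,
       converged = f$converged, n_function_evals = f$n_function_evals,
       blq_method = f$spec$blq_method, estimation = f$spec$estimation),
  "results/fit.json", auto_unbox = TRUE, digits = NA)
write.csv(data.frame(id = rownames(f$ebes), f$ebes),
          "results/ebes.csv", row.names = FALSE)

cat(sprintf("Fit %s in %.0f s (%d objective evaluations), OFV %.3f\n",
            if (f$converged) "converged" else "did NOT converge",
            elapsed, f$n_function_evals, f$ofv))
cat("Estimates (generating values in parentheses):\n")
truth <- fit_coef(structure(list(estimates = start), class = "pk_fit"))
for (nm in names(est))
  cat(sprintf("  %-18s %10.4g  (%.4g)\n", nm, est[[nm]], truth[[nm]]))
cat("Written: results/fit.json, results/ebes.csv\n")
if (!f$converged) quit(status = 1)
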