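#!/usr/bin/env Rscript

# Step 3 -- model diagnostics.
#
# Rebuilds the fitted model from results/fit.json, recomputes the empirical
# Bayes etas, and writes goodness-of-fit tables (including conditional
# weighted residuals), eta/epsilon shrinkage, a prediction-corrected VPC
# with BLQ panels, and a stratified nonparametric bootstrap summary.
# The bootstrap here runs 50 replicates to keep the driver quick; the
# published analysis used 1,000 (pass a larger count as the first argument
# to reproduce that scale) and 2,000 VPC simulations.

library(arsdhapk)

args <- commandArgs(trailingOnly = TRUE)
n_boot <- if (length(args)) as.integer(args[[1]]) else 50L
n_sim <- if (length(args) > 1) as.integer(args[[2]]) else 500L

stopifnot(file.exists("results/fit.json"))
ds <- read_dataset("results/dataset.csv")
fj <- jsonlite::read_json("results/fit.json", simplifyVector = TRUE)
est <- fj$estimates

model <- final_model()   # template: same structure, refreshed values
model$cl_ars <- est$cl_ars; model$v_ars <- est$v_ars
model$cl_dha <- est$cl_dha; model$v_dha <- est$v_dha; model$mtt <- est$mtt
model$effects$beta_cl_dha_preg$theta <- est$beta_cl_dha_preg
model$effects$beta_f_alt$theta <- est$beta_f_alt
model$effects$beta_f_lnpc$theta <- est$beta_f_lnpc
model$omega[] <- unlist(est[paste0("omega_", names(model$omega))])
model$sigma[] <- unlist(est[paste0("sigma_", names(model$sigma))])

lap <- laplacian_ofv(ds, model)
f <- structure(list(estimates = model, dataset = ds, ebes = lap$eta,
                    ofv = lap$ofv, converged = fj$converged,
                    spec = likelihood_spec()),
               class = "pk_fit")

g <- gof_tables(f)
write.csv(g, "results/gof.csv", row.names = FALSE)
sh <- shrinkage(f)
cat("Shrinkage (%):\n")
cat("  eta:    ", paste(sprintf("%s %.1f", names(sh$eta), sh$eta),
                        collapse = ", "), "\n")
cat("  epsilon:", paste(sprintf("%s %.1f", names(sh$epsilon), sh$epsilon),
                        collapse = ", "), "\n")
cat(sprintf("  (reported for the clinical fit: eta 30/40/5.7/25, epsilon 11.1/10.4)\n"))

v <- pc_vpc(f, n_sim = n_sim, seed = 11)
write.csv(v$percentiles, "results/vpc_percentiles.csv", row.names = FALSE)
write.csv(v$blq, "results/vpc_blq.csv", row.names = FALSE)
inside <- mean(v$percentiles$obs >= v$percentiles$lo &
                 v$percentiles$obs <= v$percentiles$hi)
cat(sprintf("pcVPC (%d simulations): %.0f%% of observed percentiles inside the 95%% bands\n",
            v$n_sim, 100 * inside))

cat(sprintf("Bootstrap (%d replicates, stratified on pregnancy) ...\n", n_boot))
b <- bootstrap(ds, model, n = n_boot, seed = 12)
write.csv(b$summary, "results/bootstrap.csv", row.names = FALSE)
cat(sprintf("  %d of %d replicates successful\n", b$n_successful,
            b$n_requested))
key <- b$summary[b$summary$parameter %in%
                   c("cl_dha", "v_dha", "mtt", "beta_cl_dha_preg"), ]
print(key, row.names = FALSE, digits = 4)
cat("Written: results/gof.csv, results/vpc_*.csv, results/bootstrap.csv\n")
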