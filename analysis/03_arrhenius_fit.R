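#!/usr/bin/env Rscript
# Stage 3 — the Arrhenius model.
#
# The energy barrier of a substitution is E = |ddG|. A single shared
# pre-exponential factor explains only ~10% of the log-rate variance; the
# five-level model (a in 0.01, 0.05, 0.1, 0.2, 0.4; b = 1) assigns each of
# the 380 pairs to its nearest Arrhenius curve (vertical distance in rate
# space, anchored on the LG matrix) and predicts rates q_hat = a exp(-E).

suppressMessages(library(stabrate))
dir.create("results", showWarnings = FALSE)

res <- run_pipeline(pipeline_config(out_dir = "results/arrhenius"))

cat("== single-factor fit (LG reference) ==\n")
cat(sprintf("ln q = ln(a) - E: a_hat = %.4f, slope = %.3f, R^2 = %.3f\n",
            res$single_factor$a_hat, res$single_factor$slope,
            res$single_factor$r_squared))
cat("-> stability alone leaves most rate variance unexplained, motivating\n",
    "  pair-specific pre-exponential factors.\n\n")

cat("== five-level partition ==\n")
print(table(group = res$groups))
cat("\ncorrelation table (incl. the model matrix Q_Arrh):\n")
print(round(res$correlations, 4))
cat("\nvariance in empirical rates explained by Q_Arrh (OLS R^2):\n")
print(round(sapply(res$comparisons, function(x) x$r_squared), 3))
cat("-> the five-curve model recovers most of the structure of the modern\n",
    "  matrices (JTT, LG); artifacts under results/arrhenius/.\n")
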