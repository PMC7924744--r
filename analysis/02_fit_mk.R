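#!/usr/bin/env Rscript
# Fit Mk1 (equal-rates) and Mk2 (all-rates-different) models to the binary
# trap-jaw character, compare them by AICc, and write marginal ancestral
# state probabilities for every internal node under the preferred model.
source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(),
                                                 value = TRUE))), "00_common.R"))

tree <- parse_newick(file = file.path(OUT_DIR, "tree.nwk"))
tips <- read.delim(file.path(OUT_DIR, "tip_table.tsv"), comment.char = "#")
tab <- join_tips(tree, tips)
states <- setNames(tab$mandible_state, tab$species)

fits <- list(Mk1_ER = fit_mk(tree, states, "ER"),
             Mk2_ARD = fit_mk(tree, states, "ARD"))
cmp <- data.frame(model = names(fits),
                  n_params = vapply(fits, `[[`, 0L, "n_params"),
                  loglik = vapply(fits, `[[`, 0, "loglik"),
                  aicc = vapply(fits, `[[`, 0, "aicc"))
cmp$delta_aicc <- cmp$aicc - min(cmp$aicc)
cmp$preferred <- cmp$delta_aicc == 0
write_tsv_with_header(cmp, "mk_model_comparison.tsv", "02_fit_mk.R")
print(cmp, row.names = FALSE)

best <- fits[[which.min(cmp$aicc)]]
message("preferred model: ", cmp$model[cmp$preferred],
        " (rates ", paste(signif(best$rates, 4), collapse = ", "), " per My)")

M <- marginal_ancestral(tree, states, best$Q, best$root_prior,
                        best$state_space)
n_tip <- length(tree$tip.label)
ids <- branch_ids(tree)
internal <- tree$edge[, 2][tree$edge[, 2] > n_tip]
anc <- data.frame(branch_id = ids[tree$edge[, 2] %in% internal],
                  node = internal,
                  round(M[internal, , drop = FALSE], 6))
write_tsv_with_header(anc, "ancestral_marginals.tsv", "02_fit_mk.R")
message("root P(TRAP) = ", round(M[n_tip + 1, "TRAP"], 4))
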