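#!/usr/bin/env Rscript
# Generate the synthetic study system: a dated 470-species phylogeny, a
# trap-jaw character with a known number of independent origins, single-area
# biogeographic states, strike traces for a gripping and a trap-jaw form,
# ecomorph landmark configurations, and locus presence/absence matrices.
# Everything downstream reads these files, so fixtures and "real" data are
# interchangeable by construction.
source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(),
                                                 value = TRUE))), "00_common.R"))

# Dated phylogeny with three engineered trap-jaw origins and no losses:
# a known-truth stand-in for the empirical radiation.
rad <- simulate_radiation_with_convergence(470, 3, birth_rate = 0.12,
                                           seed = SEED,
                                           clade_size = c(10, 80))
write_newick(rad$tree, file.path(OUT_DIR, "tree.nwk"))
message("tree: 470 tips, ", sum(rad$states == "TRAP"),
        " trap-jaw species in ", rad$truth$n_origins, " true clades")

# Tip table: mandible states plus regions assigned clade-wise (each derived
# clade and the background get a region, echoing single-area occupancy).
regions <- c("Afrotropics", "Asia", "Madagascan", "Nearctic", "Neotropical",
             "Oceanian")
set.seed(SEED + 1)
sets <- trapjawkit:::clade_tip_sets(rad$tree)
region_of <- rep("Neotropical", 470)
for (i in seq_along(rad$truth$origin_edges)) {
  region_of[sets[[rad$truth$origin_edges[i]]]] <- regions[1 + (i %% 5)]
}
tips <- data.frame(
  species = rad$tree$tip.label,
  mandible_state = unname(rad$states),
  region = region_of,
  mandible_index = round(ifelse(rad$states == "TRAP",
                                runif(470, 0.5, 1.6), runif(470, 0.2, 0.5)), 3),
  latch_angle = ifelse(rad$states == "TRAP",
                       round(runif(470, 5, 270), 1), NA))
write_tsv_with_header(tips, "tip_table.tsv", "01_simulate.R")

# Strike traces: one trap-jaw (50 us event at 800 kfps) and one gripping
# strike (10 ms at 2.5 kfps), both logistic closing profiles.
for (cfg in list(list(nm = "trap", ts = 5e-5, fps = 8e5),
                 list(nm = "grip", ts = 1e-2, fps = 2500))) {
  s <- simulate_strike("logistic", amplitude = 1.2, timescale = cfg$ts,
                       fps = cfg$fps, noise_sd = 0.2 * pi / 180,
                       seed = SEED + 10)
  write_tsv_with_header(
    data.frame(specimen = cfg$nm, time_s = s$trace$time,
               angle_rad = s$trace$angle),
    paste0("strike_", cfg$nm, ".csv"), "01_simulate.R")
}

# Landmark configurations: 3 ecomorph mean shapes, 9 specimens each, under
# rigid+scale nuisance transforms (27 specimens, 12 landmarks).
tet <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
lm12 <- rbind(tet, tet + 2, tet - 2)  # 12 landmarks
means <- list(GRP = lm12,
              STRAP = lm12 + 0.3 * outer(rep(c(1, 0), 6), c(1, 0, 0)),
              LTRAP = lm12 + 0.3 * outer(rep(c(0, 1), 6), c(0, 0, 1)))
lms <- simulate_landmarks(means, within_sd = 0.02, n_per_group = 9,
                          seed = SEED + 20)
long <- do.call(rbind, lapply(names(lms$configs), function(nm) {
  cbind(data.frame(specimen = nm,
                   group = sub("_.*", "", nm),
                   landmark = 1:12),
        setNames(as.data.frame(lms$configs[[nm]]), c("x", "y", "z")))
}))
write_tsv_with_header(long, "landmarks.csv", "01_simulate.R")

# Locus presence/absence: random vs clade-structured dropout at matched
# missingness, on a 60-tip subtree for a tractable audit.
sub <- ape::keep.tip(rad$tree, rad$tree$tip.label[seq(1, 470, by = 8)])
cl <- simulate_locus_presence(sub, 500, "clade", disruption_rate = 0.05,
                              seed = SEED + 30)
rd <- simulate_locus_presence(sub, 500, "random", dropout = 1 - mean(cl),
                              seed = SEED + 31)
write_newick(sub, file.path(OUT_DIR, "subtree.nwk"))
write_tsv_with_header(as.data.frame(cbind(taxon = rownames(cl), cl)),
                      "loci_clade.tsv", "01_simulate.R")
write_tsv_with_header(as.data.frame(cbind(taxon = rownames(rd), rd)),
                      "loci_random.tsv", "01_simulate.R")
message("done: synthetic inputs in ", OUT_DIR)
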