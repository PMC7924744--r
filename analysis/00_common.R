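# Shared bootstrap for the analysis scripts: library, output directory,
# seed handling, and a provenance header written atop every table.
suppressPackageStartupMessages(library(trapjawkit))

args <- commandArgs(trailingOnly = TRUE)
opt <- function(flag, default) {
  i <- which(args == flag)
  if (length(i) && i < length(args)) args[i + 1] else default
}
SEED <- as.integer(opt("--seed", "1"))
OUT_DIR <- opt("--out", "results")
dir.create(OUT_DIR, showWarnings = FALSE, recursive = TRUE)

write_tsv_with_header <- function(df, file, script) {
  con <- file(file.path(OUT_DIR, file), "w")
  writeLines(sprintf("# produced by %s | trapjawkit %s | seed %d",
                     script, as.character(packageVersion("trapjawkit")),
                     SEED), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  message("wrote ", file.path(OUT_DIR, file))
}
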