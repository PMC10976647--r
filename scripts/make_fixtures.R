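#!/usr/bin/env Rscript
# Regenerates the packaged molecular integral fixtures under inst/extdata/
# using the package's s-orbital restricted Hartree-Fock engine. Offline;
# run from the repository root. Molecular-orbital phases are aligned
# along each geometry grid so that state tracking sees continuous
# coefficients.

if (requireNamespace("fsvqe", quietly = TRUE)) {
  library(fsvqe)
} else {
  for (f in list.files("R", full.names = TRUE)) source(f)
}

out_dir <- file.path("inst", "extdata")
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

h2_grid <- c(0.50, 0.74, 1.00, 1.50, 2.00)
lih_grid <- c(1.60)

prev <- NULL
for (L in h2_grid) {
  mi <- molecular_integrals("H2", L, mo_reference = prev)
  path <- file.path(out_dir, sprintf("h2_%.2f.dat", L))
  write_integrals(mi, path)
  cat(sprintf("wrote %s  (E_HF = %.8f)\n", path, mi$hf_energy))
  prev <- mi
}

prev <- NULL
for (L in lih_grid) {
  mi <- molecular_integrals("LiH", L, mo_reference = prev)
  path <- file.path(out_dir, sprintf("lih_%.2f.dat", L))
  write_integrals(mi, path)
  cat(sprintf("wrote %s  (E_HF = %.8f)\n", path, mi$hf_energy))
  prev <- mi
}
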