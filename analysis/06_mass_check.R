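#!/usr/bin/env Rscript
# Stage 6: verify the biotinylated-adduct identification arithmetic.
suppressPackageStartupMessages(library(chemcis))

f <- "C29H33N3O9S"
message("formula:            ", format_formula(parse_formula(f)))
message(sprintf("monoisotopic mass:  %.4f Da", monoisotopic_mass(f)))
message(sprintf("[M+H]+ theoretical: %.4f (measured 600.2033)",
                adduct_mz(f, "M+H")))
message(sprintf("[M+Na]+ theoretical: %.4f (measured 622.1858)",
                adduct_mz(f, "M+Na")))
message(sprintf("Na-H adduct spacing: %.6f Da", 
                adduct_mz(f, "M+Na") - adduct_mz(f, "M+H")))
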