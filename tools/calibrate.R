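#!/usr/bin/env Rscript
# Regenerates the Rytov-SC default coefficients in R/constants.R.
# Run from the repository root after changes to the forward models:
#   Rscript tools/calibrate.R
library(spherepipe)
cal <- calibrate_rytov_sc()
print(cal$table)
print(cal$coeffs)
cat(sprintf(".RYTOV_SC_COEFFS <- c(c_n0 = %.8g, c_n1 = %.8g, c_r0 = %.8g, c_r1 = %.8g)\n",
            cal$coeffs[1], cal$coeffs[2], cal$coeffs[3], cal$coeffs[4]))
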