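# default dark-room conditions used across the suite: D65 white at
# 250 cd/m2, La = 50, Yb = 20, dark surround
default_vc <- function() cam16_conditions()

table2 <- function() hk_dataset("table2")

# relative difference helper
rel_diff <- function(a, b) abs(a - b) / pmax(abs(b), .Machine$double.eps)
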