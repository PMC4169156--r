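# Recognition-helix position labels tracked throughout the package,
# anchored to the first conserved histidine (his1). Offsets are residue
# index minus his1_pos; C2 is anchored to the first cysteine instead.
.helix_offsets <- c("-2" = -8L, "-1" = -7L, "1" = -6L, "2" = -5L,
                    "3" = -4L, "5" = -2L, "6" = -1L)

.contacting_labels <- c("-1", "2", "3", "6")
.non_contacting_labels <- c("C2", "-2", "1", "5")
.tracked_labels <- c("C2", "-2", "-1", "1", "2", "3", "5", "6")

.score_methods <- c("sift", "polyphen2_hdiv", "mutation_taster", "fathmm")

# the 20 standard amino acids
.aa20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
           "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
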