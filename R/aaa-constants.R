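# Integer codes 1..4 for A,C,G,U; the fixed channel order of the encoders
# and the row order of every base-indexed table in the package.
RNA_BASES <- c("A", "C", "G", "U")
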