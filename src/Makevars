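# Disable floating-point contraction so the compiled update rule rounds
# exactly like the scalar R reference (no FMA fusing).
PKG_CXXFLAGS = -ffp-contract=off
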