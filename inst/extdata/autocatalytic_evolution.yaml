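# Reference recursive-evolution scenario: 50 mM monomer feedstock with the
# default autocatalytic condensation chemistry, diameter threshold 60 um,
# fuse-with-feedstock + split recursion for 10 generations.
scenario: autocatalytic_evolution
seed: 0
output_dir: evolve-out
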