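# Residue-selection template for segment-RMSD state classification.
#
# Replace the segment ranges below with the residue numbering of your
# receptor and reference structures — for a GPCR, the intracellular
# portions of TM5 and TM6 whose displacement separates the active from the
# inactive state (take the exact ranges from the reference structures you
# superpose against, e.g. the CXCR4 pair 8U4P/3OE6 or the GCGR
# active/inactive pair). The values shipped here match the synthetic
# two-state fixture (50-residue CA trace, displaced middle segment) so the
# file loads and works out of the box.
#
# atom_subset: CA | backbone | all-heavy
atom_subset: CA
segments:
  - chain: A
    start: 16
    end: 35
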