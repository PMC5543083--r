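# Canonical EMT marker genes used as default seeds for random-walk
# prioritization. Edit freely: one HUGO symbol per line.
CDH1
CDH2
VIM
FN1
SNAI1
SNAI2
ZEB1
ZEB2
TWIST1
TWIST2
CLDN3
CLDN4
CLDN7
DSP
KRT8
KRT18
MMP2
MMP9
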