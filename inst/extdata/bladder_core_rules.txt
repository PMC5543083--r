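# Bladder cancer EMT regulatory core: three-layer logic model.
#
# Reconstruction of the regulatory-layer Boolean rules, constrained to
# reproduce (i) the published 64-vector input-output table (EMT level equals
# the number of active drivers among E2F1, TGFBR1, FGFR1; EGFR, CXCR1 and
# RARA are non-influential) and (ii) the published double-perturbation
# outcomes at the fully invasive state (ZEB1 knocked out together with SNAI1,
# TWIST1 or NFKB1; ZEB1 knockout plus CDH1 activation; SMAD2/3/4 knocked out
# together with TWIST1 or NFKB1 - each reduces EMT from 3 to 1).
#
# Wiring rationale: TGF-beta receptor signalling activates the SMAD module,
# which (with E2F1 or CXCR1 signalling) induces ZEB1; SNAI1 requires joint
# SMAD and ZEB1 activity; E2F1 drives TWIST1 via NFKB1; CDH1 (E-Cadherin) is
# repressed by the jointly upregulated SNAI1 and TWIST1 (its dominant
# repressors in the invasive contrast). EGFR and RARA feed nodes outside the
# EMT marker chain (SRC, FOXO3), and CXCR1's input to ZEB1 is redundant with
# E2F1/SMAD signalling - which is why these three receptors are free inputs.
#! inputs: E2F1, TGFBR1, FGFR1, EGFR, CXCR1, RARA
#! output: EMT
targets, factors
NFKB1, E2F1
SMAD2/3/4, TGFBR1
ZEB1, E2F1 OR SMAD2/3/4 OR CXCR1
TWIST1, NFKB1
SNAI1, SMAD2/3/4 AND ZEB1
CDH1, NOT (SNAI1 AND TWIST1)
SRC, EGFR
FOXO3, RARA
EMT, ((SMAD2/3/4 AND SNAI1) OR (ZEB1 AND TWIST1)) + (NOT CDH1) + FGFR1
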