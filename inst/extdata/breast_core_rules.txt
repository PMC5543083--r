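# Breast cancer EMT regulatory core: three-layer logic model.
#
# Reconstruction of the regulatory-layer Boolean rules, constrained to
# reproduce (i) the published 128-vector input-output table (EMT level equals
# the number of active drivers among E2F1, TGFBR2, EGFR; HMMR, THRB, IL1R1
# and RARA are non-influential) and (ii) the published double-perturbation
# outcomes at the fully invasive state (any pair drawn from knockout of SRC,
# FN1, SNAI1, SNAI2 or activation of CDH1 reduces EMT from 3 to 1).
#
# Wiring rationale: TGF-beta receptor 2 signalling activates the SMAD module,
# which induces Fibronectin (FN1) and SNAI2; E2F1 drives SRC and SNAI2;
# SNAI1 integrates both branches and additionally requires FN1/SRC signalling
# (which makes the four mesenchymal markers mutually dependent, so silencing
# any pair collapses the invasive program); CDH1 is repressed by its jointly
# upregulated repressors SNAI1 and SNAI2. HMMR, THRB, IL1R1 and RARA feed
# nodes outside the marker chain (KPNA2, MYC, TRAF1, FOXA1) and are therefore
# free inputs; the EMT output is gated by EGFR as the decisive receptor.
#! inputs: E2F1, TGFBR2, EGFR, HMMR, THRB, IL1R1, RARA
#! output: EMT
targets, factors
SMAD2/3/4, TGFBR2
SRC, E2F1
FN1, SMAD2/3/4
SNAI2, E2F1 OR SMAD2/3/4
SNAI1, (E2F1 OR SMAD2/3/4) AND (FN1 OR SRC)
CDH1, NOT (SNAI1 AND SNAI2)
TRAF1, IL1R1
MYC, THRB
KPNA2, HMMR
FOXA1, RARA
EMT, (SNAI1 AND SNAI2 AND FN1 AND SRC) + (NOT CDH1) + EGFR
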