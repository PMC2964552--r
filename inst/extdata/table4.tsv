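# Published per-locus population-differentiation statistics between wild
# green foxtail and cultivated foxtail millet: shared, fixed and
# species-specific segregating sites and Hudson-style Fst.
locus	S_shared	S_fixed	S_wild_specific	S_cultivar_specific	Fst
DACP	18	0	9	1	0.0254
SIGT	5	0	4	1	0.0289
ADTY	4	0	37	1	0.4085
PP2C	2	0	4	0	0.0933
SPS1	2	0	8	1	0.1546
UPL	1	0	8	4	0.4082
TIFIIF	3	0	6	1	0.1002
TRAN	7	0	8	3	0.1075
MDEH	10	0	9	6	0.0556
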