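# Step-wise affinity elution of the thiamin-phosphate hydrolyzing activity
# from thiamin- and DMHT-modified sorbents (specific activity: nmol
# phosphate/min per mg protein in the eluate; load specific activity not
# recorded).
bait	protein_applied_mg	step	eluant	eluted_mg	eluted_pct	specific_activity
Thiamin	110	1	1 M NaCl	1.5	1.4	200
Thiamin	110	2	2 M urea	1.1	1.3	3.2
DMHT	90	1	1 M NaCl	0.3	0.4	92
DMHT	90	2	2 M urea	1.1	1.2	27
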