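bin	pi_pisc	pi_ins	dxy
fst_gt_0.5	0.000557	0.00224	0.00216
fst_gt_0.4	0.000719	0.00241	0.00205
fst_gt_0.3	0.00108	0.00255	0.00205
fst_gt_0.2	0.00151	0.00269	0.00209
genome_wide	0.00209	0.00289	0.00218
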