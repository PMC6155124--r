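quantity	value
genes_up	3901
genes_down	3405
diff_genes_tss_within_5kb	566
diff_genes_tss_within_500kb	4615
patients_screened	50
patients_with_mutations	4
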