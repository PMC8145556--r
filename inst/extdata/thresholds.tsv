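taxon	rank	metric	low	high	critical
global	global	q30_fraction	0.8		TRUE
global	global	taxonomy_purity	0.95		TRUE
global	global	mlst_duplicated		0	FALSE
global	global	core_duplicated		1	FALSE
global	global	core_unique_percent	95		FALSE
Salmonella enterica	species	coverage	30		TRUE
Listeria monocytogenes	species	coverage	20		TRUE
Escherichia coli	species	coverage	40		TRUE
Campylobacter	genus	coverage	20		TRUE
Salmonella enterica	species	assembly_length	4500000	5100000	TRUE
Listeria monocytogenes	species	assembly_length	2800000	3200000	TRUE
Escherichia coli	species	assembly_length	4500000	5600000	TRUE
Campylobacter	genus	assembly_length	1400000	2000000	TRUE
Salmonella enterica	species	n_contigs	42	216	FALSE
Listeria monocytogenes	species	n_contigs	18	212	FALSE
Escherichia coli	species	n_contigs	116	618	FALSE
Campylobacter	genus	n_contigs	15	112	FALSE
Salmonella enterica	species	gc_percent	48.1	56.1	FALSE
Listeria monocytogenes	species	gc_percent	33.9	41.9	FALSE
Escherichia coli	species	gc_percent	42.6	54.6	FALSE
Campylobacter	genus	gc_percent	26.4	35.3	FALSE
Salmonella enterica	species	core_unique_percent	95		FALSE
Listeria monocytogenes	species	core_unique_percent	95		FALSE
Escherichia coli	species	core_unique_percent	95		FALSE
Campylobacter	genus	core_unique_percent	79		FALSE
Salmonella enterica	species	n50	53000		FALSE
Listeria monocytogenes	species	n50	60000		FALSE
Escherichia coli	species	n50	71700		FALSE
Campylobacter	genus	n50	54200		FALSE
Salmonella enterica	species	duplication_ratio		1.002	FALSE
Listeria monocytogenes	species	duplication_ratio		1.005	FALSE
Escherichia coli	species	duplication_ratio		1.015	FALSE
Campylobacter	genus	duplication_ratio		1.009	FALSE
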