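key	value
bins_assessed	54614
removed_tax	561804
removed_mobile	39289
removed_outlier	436143
contigs_removed	1000417
bins_discarded	2289
n_representatives	8466
n_unassigned_species	6256
n_exclusive_clusters	4806
n_superior_quality	1971
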