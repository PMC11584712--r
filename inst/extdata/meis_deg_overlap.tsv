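# Published MEIS1/MEIS2 DEG-set sizes and tested-gene universe.
# Intersection sizes are reconstructed: the unique integer jointly consistent
# with the published Jaccard index and Fisher odds ratio for each direction
# (the published values are rounded summaries, not raw set listings).
direction	n_tf1	n_tf2	n_intersect	universe_size
up	155	54	14	19689
down	34	65	11	19689
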