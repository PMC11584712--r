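# Published observed and bootstrap-expected Jaccard indices for the
# MEIS1/MEIS2 target-set comparison in human neural stem cells.
# Inputs for observed/expected ratio computation.
direction	observed_j	expected_j_tf1	expected_j_tf2
up	0.072	0.511	0.493
down	0.126	0.226	0.303
all	0.092	0.414	0.368
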