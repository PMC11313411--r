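movement_matrix_silver.csv / movement_matrix_bighead.csv
Published posterior-mean monthly movement probabilities (survival x battery
retention x pool transition) for silver and bighead carp among the six
navigation pools of the lower Illinois Waterway, ordered downstream to
upstream (Alton ... Dresden Island); destination in rows, origin in columns.
Used only to exercise the movement-matrix summary operations, never as
model input.
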