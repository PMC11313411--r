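to,Alton,La Grange,Peoria,Starved Rock,Marseilles,Dresden Island
Alton,0.783,0.074,0.001,0.001,0.060,0.102
La Grange,0.015,0.768,0.021,0.015,0.120,0.000
Peoria,0.001,0.008,0.806,0.206,0.000,0.057
Starved Rock,0.001,0.001,0.073,0.695,0.020,0.003
Marseilles,0.040,0.087,0.001,0.021,0.721,0.017
Dresden Island,0.097,0.000,0.036,0.000,0.016,0.758
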