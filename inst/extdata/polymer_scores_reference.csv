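polymer,harmfulness_score,base_score,frequency_weight,confidence,sentiment_component,impact_component,centrality_component,paper_count,frequency_percentage,eigenvector_centrality,betweenness_centrality
PS,0.790,0.857,0.744,0.997,0.770,0.874,1,7594,7.540,0.910,0.720
PE,0.771,0.772,1,0.998,0.737,0.694,1,10205,10.133,0.880,0.690
PP,0.663,0.771,0.545,0.996,0.709,0.719,1,5560,5.521,0.790,0.650
PET,0.629,0.757,0.449,0.996,0.748,0.644,1,4582,4.550,0.740,0.590
PA,0.618,0.809,0.236,0.992,0.804,0.718,1,2403,2.386,0.690,0.520
PVC,0.608,0.796,0.236,0.992,0.756,0.734,1,2405,2.388,0.680,0.510
PUR,0.598,0.848,0.076,0.975,0.942,0.679,1,780,0.775,0.590,0.480
PLA,0.573,0.781,0.147,0.987,0.974,0.478,1,1497,1.486,0.550,0.450
PC,0.568,0.809,0.070,0.973,0.828,0.696,1,718,0.713,0.520,0.430
PMMA,0.556,0.824,0.037,0.949,0.829,0.731,1,374,0.371,0.510,0.410
ABS,0.531,0.799,0.030,0.938,0.749,0.747,1,301,0.299,0.480,0.380
PTFE,0.520,0.804,0.021,0.916,0.864,0.730,1,217,0.216,0.450,0.350
EVA,0.519,0.850,0.013,0.868,0.708,1,1,131,0.130,0.440,0.330
HDPE,0.503,0.712,0.078,0.976,0.683,0.598,1,796,0.790,0.430,0.320
LDPE,0.495,0.692,0.100,0.981,0.682,0.548,1,1019,1.012,0.420,0.310
POM,0.484,0.775,0.015,0.887,1,0.438,1,157,0.156,0.380,0.280
PBT,0.468,0.831,0.008,0.802,0.791,0.869,1,81,0.080,0.360,0.250
PEEK,0.229,0.638,0.002,0.512,0.972,0.456,1,21,0.021,0.190,0.120
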