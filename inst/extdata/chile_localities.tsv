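locality	lat	lon	n_coi	n_rbcl	region
Pichicuy	-32.345533	-71.460019	10	8	central
Montemar	-32.957586	-71.551019	10	10	central
Cartagena	-33.550850	-71.616697	6	NA	central
Matanzas	-33.765908	-71.770744	5	NA	central
Pichilemu	-34.393831	-72.026139	6	NA	central
Duao	-34.886769	-72.168650	7	NA	central
Constitucion	-35.328106	-72.433169	6	9	central
Dichato	-36.494967	-72.910072	6	NA	central
Tumbes	-36.615400	-73.108261	8	9	central
Lebu	-37.595000	-73.669167	5	NA	central
Tirua	-38.345158	-73.508408	4	NA	central
Queule	-39.387961	-73.240722	5	NA	central
Punta Loncoyen	-39.824469	-73.405189	9	9	central
Bahia Mansa	-40.592836	-73.750361	5	NA	central
Pumillahue	-41.945831	-74.039450	8	NA	central
Cucao	-42.668900	-74.121819	10	9	central
Isla Guafo	-43.554783	-74.715469	5	NA	central
Puerto Barrientos	-43.912331	-74.002031	6	NA	central
Isla Betecoi	-43.985450	-73.873139	9	NA	central
49S	-49.156928	-75.296942	7	10	patagonia
50S	-50.149100	-74.664600	10	10	patagonia
51S	-51.778806	-73.716833	6	NA	patagonia
53S	-53.655314	-72.258061	7	NA	patagonia
Cape Horn	-55.992075	-67.270828	4	4	patagonia
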