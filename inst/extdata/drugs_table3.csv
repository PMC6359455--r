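name,Vx,E,S,A,B,M_kg_mol,sigma_d,gamma_d_mJ_m2
Carvedilol,3.10,3.08,3.19,0.50,1.45,0.40647,19.75,47.83
Cyclosporine A,10.02,4.23,7.72,0.70,4.50,1.20264,18.04,13.19
Ketoconazole,3.72,3.14,2.75,0.00,0.70,0.53144,19.52,45.86
Loratadine,2.87,2.19,2.96,0.00,0.60,0.38289,19.11,41.60
Simvastatin,3.43,1.35,4.28,0.20,0.70,0.41857,17.82,57.36
Zafirlukast,4.23,3.64,4.66,0.71,2.10,0.57558,19.60,49.43
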