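name,M_kg_mol,p0_Pa,B11_m3_mol,V1_m3_mol
n-Heptane,0.10020,7780,-2.60e-3,1.475e-4
n-Octane,0.11423,2470,-3.70e-3,1.639e-4
n-Nonane,0.12825,790,-5.00e-3,1.801e-4
n-Decane,0.14229,250,-6.60e-3,1.962e-4
Acetone,0.05808,37700,-1.65e-3,7.44e-5
Acetonitrile,0.04105,12200,-4.50e-3,5.31e-5
Ethyl acetate,0.08811,15900,-1.85e-3,9.86e-5
Dichloromethane,0.08493,70000,-0.85e-3,6.45e-5
Methanol,0.03204,21900,-1.55e-3,4.09e-5
Ethanol,0.04607,10500,-2.10e-3,5.87e-5
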